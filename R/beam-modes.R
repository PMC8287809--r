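#' Clamped-free beam eigenvalues
#'
#' Eigenvalues \eqn{q_n} of the clamped-free (cantilever) Euler-Bernoulli
#' beam, the roots of \eqn{\cos(q)\cosh(q) = -1}. Two conventions are
#' offered: `"printed"` returns the rounded constants in common use
#' (1.875, 4.695, 7.855 for n = 1..3 and \eqn{(n - 1/2)\pi} for n >= 4),
#' `"exact"` solves the characteristic equation numerically.
#'
#' Note that the printed constant for n = 2 (4.695) differs from the exact
#' root (4.69409...) in the third decimal; the discrepancy is retained
#' under `convention = "printed"` rather than corrected, so results match
#' analyses that use the rounded constants.
#'
#' @param n Mode index (positive integer), vectorised.
#' @param convention `"printed"` (default) or `"exact"`.
#' @return Numeric vector of eigenvalues (dimensionless).
#' @examples
#' beam_eigenvalue(1:4)
#' beam_eigenvalue(2, "exact")
#' @export
beam_eigenvalue <- function(n, convention = c("printed", "exact")) {
  convention <- match.arg(convention)
  if (length(n) == 0L || any(!is.finite(n)) || any(n < 1) ||
      any(n != floor(n))) {
    stop("'n' must consist of positive integers", call. = FALSE)
  }
  if (convention == "printed") {
    q <- (n - 0.5) * pi
    # literal rounded constants, never recomputed
    q[n == 1] <- 1.875
    q[n == 2] <- 4.695
    q[n == 3] <- 7.855
    return(q)
  }
  vapply(n, exact_eigenvalue, numeric(1))
}

# Root of cos(q)cosh(q) = -1 in ((n-1)*pi, n*pi).  Solved as
# cos(q) + sech(q) = 0, which stays bounded for large q where
# cosh overflows.
exact_eigenvalue <- function(n) {
  f <- function(q) cos(q) + 1 / cosh(q)
  lo <- (n - 1) * pi + 1e-9
  hi <- n * pi
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Construct a clamped-free beam mode basis
#'
#' A `mode_basis` bundles the eigenvalues \eqn{q_n} (under the chosen
#' convention) for modes 1..`n_modes`, and is consumed by both the
#' fluctuation simulator and the rigidity estimator.
#'
#' @param n_modes Number of modes (default 20; evaluation is guarded
#'   against hyperbolic overflow up to n = 25, beyond which the mode
#'   shapes lose precision).
#' @param convention Eigenvalue convention, see [beam_eigenvalue()].
#' @return An object of class `mode_basis` with elements `n_modes`,
#'   `eigenvalues` and `convention`.
#' @examples
#' b <- mode_basis(4)
#' b$eigenvalues
#' @export
mode_basis <- function(n_modes = 20L, convention = c("printed", "exact")) {
  convention <- match.arg(convention)
  if (!is.numeric(n_modes) || length(n_modes) != 1L || n_modes < 1 ||
      n_modes != floor(n_modes)) {
    stop("'n_modes' must be a single positive integer", call. = FALSE)
  }
  if (n_modes > 25) {
    warning("mode shapes beyond n = 25 approach hyperbolic overflow; ",
            "results may lose precision")
  }
  structure(
    list(n_modes = as.integer(n_modes),
         eigenvalues = beam_eigenvalue(seq_len(n_modes), convention),
         convention = convention),
    class = "mode_basis"
  )
}

#' @export
print.mode_basis <- function(x, ...) {
  cat("Clamped-free beam mode basis (", x$convention, " eigenvalues)\n",
      sep = "")
  cat("  modes: 1..", x$n_modes, "\n", sep = "")
  qs <- signif(utils::head(x$eigenvalues, 5), 6)
  cat("  q_n:   ", paste(qs, collapse = ", "),
      if (x$n_modes > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Evaluate a clamped-free beam mode shape
#'
#' Evaluates the normalised cantilever mode shape
#' \deqn{W_n(u) = \frac{-\cosh q_n - \cos q_n}{\sin q_n + \sinh q_n}
#'   \left(\sin(q_n u) - \sinh(q_n u)\right) + \cos(q_n u) - \cosh(q_n u)}
#' at relative arc position \eqn{u = s/L \in [0, 1]}. The modes satisfy
#' \eqn{W_n(0) = W_n'(0) = 0} (clamped end) and \eqn{|W_n(1)| = 2}
#' (free end), and are orthonormal on \[0, 1\].
#'
#' For large \eqn{q_n} the leading coefficient tends to -1 and the
#' sinh/cosh terms cancel catastrophically in the naive form; the
#' evaluation therefore uses the algebraically equivalent rearrangement
#' \eqn{W_n(u) = C\sin(q_n u) + \cos(q_n u) - e^{-q_n u} -
#' \epsilon\,\sinh(q_n u)} with \eqn{C = -1 + \epsilon} and
#' \eqn{\epsilon} computed without forming the cancelling difference.
#'
#' @param n Mode index (single positive integer, at most `basis$n_modes`).
#' @param u Relative arc position(s) in \[0, 1\]; vectorised.
#' @param basis A [mode_basis()].
#' @return Numeric vector `W_n(u)` (dimensionless).
#' @examples
#' mode_shape(1, c(0, 0.5, 1), mode_basis(4))
#' @export
mode_shape <- function(n, u, basis = mode_basis()) {
  stopifnot(inherits(basis, "mode_basis"))
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop("'n' must be a single positive integer", call. = FALSE)
  }
  if (n > basis$n_modes) {
    stop("mode index exceeds basis n_modes (", basis$n_modes, ")",
         call. = FALSE)
  }
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("'u' must lie in [0, 1]", call. = FALSE)
  }
  mode_shape_eval(basis$eigenvalues[n], u)
}

# Stable evaluation of W(u) for eigenvalue q; u may be a vector or matrix.
# C = -(cosh q + cos q)/(sinh q + sin q) = -1 + eps with
# eps = (sin q - cos q - exp(-q))/(sinh q + sin q), and
# -C sinh(qu) - cosh(qu) = -exp(-qu) - eps sinh(qu).
mode_shape_eval <- function(q, u) {
  eps <- (sin(q) - cos(q) - exp(-q)) / (sinh(q) + sin(q))
  C <- -1 + eps
  qu <- q * u
  C * sin(qu) + cos(qu) - exp(-qu) - eps * sinh(qu)
}
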