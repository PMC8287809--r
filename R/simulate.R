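# Boltzmann constant, J/K
.kB <- 1.380649e-23

#' Simulation configuration for cantilevered filament fluctuations
#'
#' Collects the physical and numerical parameters of the thermal
#' fluctuation simulator. All quantities are strict SI (metres, newton
#' square metres, kelvin); the I/O layer converts to nm for file output.
#'
#' @param length Contour length L of the free segment, metres
#'   (study values 5e-6, 10e-6, 30e-6).
#' @param kappa True flexural rigidity \eqn{\kappa_{set}}, N m^2
#'   (study values 0.03e-23, 0.3e-23, 3e-23).
#' @param temperature Absolute temperature, kelvin (default 298).
#' @param n_frames Number of independent frames (default 500).
#' @param n_modes Number of modes superposed in synthesis (default 20;
#'   amplitudes fall as \eqn{q_n^{-4}} so mode 20 contributes under
#'   1e-5 of the tip variance). Must be at least twice the analysis
#'   mode cutoff to avoid inversion bias.
#' @param spacing Arc-length spacing of sampled points, metres
#'   (default 100e-9, about one camera pixel).
#' @param precision Localization precision \eqn{\delta}, metres;
#'   coordinates are rounded to the nearest multiple of \eqn{\delta}.
#'   0 (default) disables quantization. Study values 1e-9, 10e-9, 100e-9.
#' @param seed Integer seed controlling the amplitude draws.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(length = 10e-6, kappa = 0.3e-23, seed = 1)
#' @export
sim_config <- function(length = 10e-6, kappa = 0.3e-23, temperature = 298,
                       n_frames = 500L, n_modes = 20L, spacing = 100e-9,
                       precision = 0, seed = 1L) {
  stopifnot(is.numeric(length), length > 0,
            is.numeric(kappa), kappa > 0,
            is.numeric(temperature), temperature > 0,
            n_frames >= 1, n_frames == floor(n_frames),
            n_modes >= 1, n_modes == floor(n_modes),
            is.numeric(precision), precision >= 0)
  if (spacing <= 0 || spacing >= length) {
    stop("'spacing' must be positive and smaller than 'length'",
         call. = FALSE)
  }
  structure(
    list(length = length, kappa = kappa, temperature = temperature,
         n_frames = as.integer(n_frames), n_modes = as.integer(n_modes),
         spacing = spacing, precision = precision, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Cantilever fluctuation simulation config\n")
  cat(sprintf("  L = %g um, kappa = %g x 1e-23 N m^2, T = %g K\n",
              x$length * 1e6, x$kappa * 1e23, x$temperature))
  cat(sprintf("  %d frames, %d modes, spacing %g nm, precision %g nm, seed %d\n",
              x$n_frames, x$n_modes, x$spacing * 1e9, x$precision * 1e9,
              x$seed))
  invisible(x)
}

#' Equipartition variance of a thermal mode amplitude
#'
#' The thermal variance of the n-th cantilever mode amplitude,
#' \deqn{\mathrm{var}(a_n) = \frac{k_B T}{\kappa}
#'   \left(\frac{L}{q_n}\right)^4,}
#' the equipartition relation between thermal energy and bending energy.
#' Units: m^3 (amplitudes carry m^{3/2} under the \eqn{\sqrt{1/L}}
#' normalisation of the shape expansion).
#'
#' @param kappa Flexural rigidity, N m^2.
#' @param length Contour length L, metres.
#' @param temperature Absolute temperature, kelvin.
#' @param n Mode index (vectorised).
#' @param basis A [mode_basis()].
#' @return Numeric vector of variances, m^3.
#' @examples
#' mode_variance(0.3e-23, 10e-6, 298, 1:4)
#' @export
mode_variance <- function(kappa, length, temperature, n,
                          basis = mode_basis()) {
  if (!is.numeric(kappa) || kappa <= 0) {
    stop("'kappa' must be positive", call. = FALSE)
  }
  if (!is.numeric(length) || length <= 0) {
    stop("'length' must be positive", call. = FALSE)
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("'temperature' must be positive", call. = FALSE)
  }
  q <- basis$eigenvalues[n]
  (.kB * temperature / kappa) * (length / q)^4
}

#' Draw Gaussian mode amplitudes for an ensemble
#'
#' Each amplitude \eqn{a_{f,n}} is drawn independently from a zero-mean
#' Gaussian with the equipartition variance of mode n. Frames are
#' mutually independent. Draws are made frame by frame so that
#' increasing `n_frames` extends the table without reshuffling the
#' earlier frames.
#'
#' @param config A [sim_config()].
#' @param basis A [mode_basis()] with at least `config$n_modes` modes.
#' @return Matrix (`n_frames` x `n_modes`) of amplitudes, m^{3/2}.
#' @export
sample_amplitudes <- function(config, basis = mode_basis(config$n_modes)) {
  stopifnot(inherits(config, "sim_config"))
  if (basis$n_modes < config$n_modes) {
    stop("basis has fewer modes than config$n_modes", call. = FALSE)
  }
  sd_n <- sqrt(mode_variance(config$kappa, config$length,
                             config$temperature, seq_len(config$n_modes),
                             basis))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  z <- matrix(stats::rnorm(config$n_frames * config$n_modes),
              nrow = config$n_frames, ncol = config$n_modes, byrow = TRUE)
  sweep(z, 2L, sd_n, `*`)
}

# Set the RNG seed, returning the previous .Random.seed (or NULL) for
# restoration, so simulation calls don't disturb the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Synthesize one filament shape from mode amplitudes
#'
#' Superposes the cantilever modes,
#' \eqn{y(s) = \sum_n \sqrt{1/L}\, a_n W_n(s/L)}, at arc positions
#' \eqn{s_k = k \cdot \mathrm{spacing}} for k = 0..floor(L/spacing).
#' The filament is inextensible, so points are placed along the contour:
#' \eqn{x_0 = 0} and \eqn{x_{k+1} = x_k + \sqrt{h^2 - (\Delta y_k)^2}}
#' with h the arc spacing, which makes consecutive point separations
#' equal the arc spacing and the reconstructed contour length equal L.
#' (Placing points at \eqn{x_k = s_k} instead would inflate the
#' reconstructed arc length whenever fluctuations are not tiny and bias
#' the rigidity estimate downward in error; see the methods vignette.)
#' In the rare event that a transverse step exceeds the arc spacing
#' (soft filaments far outside the small-deflection regime) the x-step
#' is clamped at zero.
#'
#' @param amplitudes Numeric vector of amplitudes for modes
#'   1..`config$n_modes`, m^{3/2}.
#' @param config A [sim_config()].
#' @param basis A [mode_basis()].
#' @return Matrix with columns `x`, `y` (metres), first row (0, 0).
#' @export
synthesize_shape <- function(amplitudes, config,
                             basis = mode_basis(config$n_modes)) {
  stopifnot(inherits(config, "sim_config"))
  if (length(amplitudes) != config$n_modes) {
    stop("'amplitudes' must cover modes 1..n_modes", call. = FALSE)
  }
  s <- arc_positions(config)
  W <- mode_shape_matrix(s / config$length, config$n_modes, basis)
  y <- drop(W %*% (sqrt(1 / config$length) * amplitudes))
  cbind(x = contour_x(y, config$spacing), y = y)
}

# x-positions placing points along the contour: each consecutive
# separation equals the arc spacing h (clamped when |dy| > h).
contour_x <- function(y, h) {
  dy <- diff(y)
  c(0, cumsum(sqrt(pmax(h^2 - dy^2, 0))))
}

arc_positions <- function(config) {
  # tolerant count so an exact-multiple length keeps its last point
  # under floating-point round-off
  n_seg <- floor(config$length / config$spacing + 1e-9)
  seq(0, by = config$spacing, length.out = n_seg + 1L)
}

# (points x modes) matrix of W_n(u)
mode_shape_matrix <- function(u, n_modes, basis) {
  vapply(seq_len(n_modes),
         function(n) mode_shape_eval(basis$eigenvalues[n], u),
         numeric(length(u)))
}

#' Digitize coordinates at a localization precision
#'
#' Rounds every x and y coordinate to the nearest integer multiple of
#' the localization precision \eqn{\delta}, emulating the granularity
#' of tracked positions. Half-way cases round away from zero.
#' \eqn{\delta = 0} returns the input unchanged.
#'
#' @param shape Matrix with columns `x`, `y` (metres), or a
#'   `shape_ensemble` (every frame is quantized).
#' @param precision \eqn{\delta}, metres (non-negative).
#' @return Object of the same form with quantized coordinates.
#' @examples
#' quantize_points(cbind(x = 0, y = 236.8e-9), 1e-9)   # -> 237 nm
#' quantize_points(cbind(x = 0, y = 236.8e-9), 10e-9)  # -> 240 nm
#' quantize_points(cbind(x = 0, y = 236.8e-9), 100e-9) # -> 200 nm
#' @export
quantize_points <- function(shape, precision) {
  if (!is.numeric(precision) || length(precision) != 1L || precision < 0) {
    stop("'precision' must be a single non-negative number", call. = FALSE)
  }
  if (inherits(shape, "shape_ensemble")) {
    shape$frames <- lapply(shape$frames, quantize_points, precision)
    shape$precision <- precision
    return(shape)
  }
  if (precision == 0) {
    return(shape)
  }
  shape[] <- round_half_away(shape / precision) * precision
  shape
}

# round-half-away-from-zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Simulate an ensemble of fluctuating filament shapes
#'
#' Generates `n_frames` independent thermal shapes of a cantilevered
#' filament with defined rigidity, then digitizes the coordinates at the
#' configured localization precision. Frames are i.i.d. draws from the
#' equilibrium shape distribution (no temporal correlation).
#'
#' @param config A [sim_config()].
#' @param basis A [mode_basis()].
#' @return A `shape_ensemble`: list with `frames` (list of x/y matrices,
#'   metres), `config`, `precision`, and `provenance = "simulated"`.
#' @examples
#' ens <- simulate_ensemble(sim_config(n_frames = 50, seed = 7))
#' ens
#' @export
simulate_ensemble <- function(config, basis = mode_basis(config$n_modes)) {
  stopifnot(inherits(config, "sim_config"))
  a <- sample_amplitudes(config, basis)
  s <- arc_positions(config)
  W <- mode_shape_matrix(s / config$length, config$n_modes, basis)
  Y <- a %*% t(W) * sqrt(1 / config$length)       # frames x points
  np <- ncol(Y)
  dY <- Y[, -1, drop = FALSE] - Y[, -np, drop = FALSE]
  dX <- sqrt(pmax(config$spacing^2 - dY^2, 0))
  X <- cbind(0, t(apply(dX, 1L, cumsum)))         # contour placement
  if (config$precision > 0) {
    Y[] <- round_half_away(Y / config$precision) * config$precision
    X[] <- round_half_away(X / config$precision) * config$precision
  }
  frames <- lapply(seq_len(config$n_frames),
                   function(f) cbind(x = X[f, ], y = Y[f, ]))
  structure(
    list(frames = frames, config = config, precision = config$precision,
         provenance = "simulated"),
    class = "shape_ensemble"
  )
}

#' Construct a shape ensemble from frame coordinate matrices
#'
#' @param frames List of numeric matrices, each with columns `x`, `y`
#'   in metres and at least 3 points, ordered from the clamped origin
#'   outward.
#' @param config Optional `sim_config` metadata.
#' @param provenance `"simulated"` or `"external"`.
#' @return A `shape_ensemble`.
#' @export
shape_ensemble <- function(frames, config = NULL, provenance = "external") {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("'frames' must be a non-empty list of coordinate matrices",
         call. = FALSE)
  }
  npts <- vapply(frames, nrow, integer(1))
  if (any(npts < 3L)) {
    stop("every frame needs at least 3 points (frame ",
         which(npts < 3L)[1], " has ", min(npts), ")", call. = FALSE)
  }
  structure(
    list(frames = frames, config = config,
         precision = if (!is.null(config)) config$precision else NA_real_,
         provenance = provenance),
    class = "shape_ensemble"
  )
}

#' @export
print.shape_ensemble <- function(x, ...) {
  npts <- vapply(x$frames, nrow, integer(1))
  cat("Shape ensemble (", x$provenance, "): ", length(x$frames),
      " frames, ", sep = "")
  if (length(unique(npts)) == 1L) {
    cat(npts[1], "points per frame\n")
  } else {
    cat("point counts ", min(npts), "-", max(npts), "\n", sep = "")
  }
  if (!is.null(x$config)) print(x$config)
  invisible(x)
}
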