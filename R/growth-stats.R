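#' Generate synthetic tip-position growth traces
#'
#' Emulates tip-position time series of elongating filaments: position
#' grows linearly at `rate` with independent Gaussian localization noise
#' per sample. A stand-in for kymograph-derived tip traces, used to
#' exercise the growth-rate fitting and group statistics.
#'
#' @param rate Growth rate, um/min (non-negative).
#' @param noise_sd Per-sample Gaussian noise, um.
#' @param duration Trace duration, seconds.
#' @param dt Sampling interval, seconds.
#' @param n_traces Number of traces.
#' @param seed Integer seed.
#' @param label Optional group label attached to every trace.
#' @return List of `growth_trace` objects, each a list with `times`
#'   (seconds), `positions` (um), `label`.
#' @examples
#' tr <- generate_growth_traces(10.10, 0.05, duration = 60, dt = 2,
#'                              n_traces = 3, seed = 1)
#' fit_growth_rate(tr[[1]])
#' @export
generate_growth_traces <- function(rate, noise_sd = 0.05, duration = 120,
                                   dt = 0.4, n_traces = 1L, seed = 1L,
                                   label = NULL) {
  if (!is.numeric(rate) || rate < 0) {
    stop("'rate' must be non-negative", call. = FALSE)
  }
  if (duration <= 0 || dt <= 0) {
    stop("'duration' and 'dt' must be positive", call. = FALSE)
  }
  times <- seq(0, duration, by = dt)
  if (length(times) < 3L) {
    stop("fewer than 3 samples; decrease 'dt' or increase 'duration'",
         call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lapply(seq_len(n_traces), function(i) {
    pos <- rate * times / 60 + stats::rnorm(length(times), 0, noise_sd)
    structure(list(times = times, positions = pos, label = label),
              class = "growth_trace")
  })
}

#' Fit a growth rate to a tip-position trace
#'
#' Ordinary least-squares slope of tip position against time, converted
#' to um/min, with its standard error from the residuals.
#'
#' @param trace A `growth_trace`, or any list with numeric `times`
#'   (seconds, strictly increasing, >= 3 samples) and `positions` (um).
#' @return List with `rate` (um/min), `se` (um/min), `n`.
#' @export
fit_growth_rate <- function(trace) {
  t <- trace$times
  p <- trace$positions
  if (length(t) < 3L || length(p) != length(t)) {
    stop("need at least 3 (time, position) samples", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(p ~ t)
  sm <- summary(fit)$coefficients
  list(rate = unname(sm["t", "Estimate"]) * 60,
       se = unname(sm["t", "Std. Error"]) * 60,
       n = length(t))
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' Rank-based multiple comparison of k groups controlling the
#' family-wise error rate. For each pair of groups the two samples are
#' pooled and ranked with midranks for ties; the rank sum R of the first
#' group is standardized with its tie-corrected null moments,
#' \deqn{t = \frac{R - n_i(N+1)/2}{\sqrt{\frac{n_i n_j}{N(N-1)}
#'   \left(\sum_r r^2 - \frac{N(N+1)^2}{4}\right)}},}
#' and referred to the studentized-range distribution with k groups and
#' infinite degrees of freedom: \eqn{p = P(Q_{k,\infty} \ge \sqrt{2}|t|)}
#' (the classical large-sample Steel-Dwass form).
#'
#' @param groups Named list of numeric vectors (k >= 2 groups, each with
#'   >= 2 values), or a formula `value ~ group` with `data`.
#' @param data Data frame for the formula interface.
#' @param alpha Significance threshold recorded on the result
#'   (default 0.05).
#' @return Object of class `steel_dwass`: list with `pairs` (data frame
#'   of group1, group2, statistic, p_value), `labels`, `k`, `alpha`.
#' @examples
#' g <- list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13))
#' steel_dwass(g)
#' @export
steel_dwass <- function(groups, data = NULL, alpha = 0.05) {
  if (inherits(groups, "formula")) {
    mf <- stats::model.frame(groups, data = data)
    groups <- split(mf[[1]], mf[[2]], drop = TRUE)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values (group ",
         which(sizes < 2L)[1], " has ", min(sizes), ")", call. = FALSE)
  }
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_along(groups))
  k <- length(groups)
  idx <- utils::combn(k, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(idx)), function(c2) {
    i <- idx[1, c2]; j <- idx[2, c2]
    t_ij <- sd_pair_statistic(groups[[i]], groups[[j]])
    p <- stats::ptukey(sqrt(2) * abs(t_ij), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    data.frame(group1 = labels[i], group2 = labels[j],
               statistic = t_ij, p_value = p)
  }))
  structure(list(pairs = pairs, labels = labels, k = k, alpha = alpha),
            class = "steel_dwass")
}

# Standardized pairwise rank-sum with midranks and tie-corrected
# variance; returns the z-like statistic t.
sd_pair_statistic <- function(x, y) {
  ni <- length(x)
  nj <- length(y)
  N <- ni + nj
  r <- rank(c(x, y))            # midranks for ties
  R <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)         # all values tied
  (R - E) / sqrt(V)
}

#' @export
print.steel_dwass <- function(x, ...) {
  cat("Steel-Dwass all-pairs comparison (", x$k, " groups, alpha = ",
      x$alpha, ")\n", sep = "")
  p <- x$pairs
  p$statistic <- signif(p$statistic, 4)
  p$p_value <- signif(p$p_value, 4)
  p$sig <- ifelse(x$pairs$p_value < x$alpha, "*", "")
  print(p, row.names = FALSE)
  invisible(x)
}

#' Segment ordered groups into statistically indistinguishable phases
#'
#' Given groups with a meaningful order (for example ascending tubulin
#' concentration) and their all-pairs comparison, partitions them into
#' contiguous blocks by a greedy left-to-right merge: the current block
#' is extended while the candidate group is indistinguishable
#' (p > alpha) from every group already in the block, and a new block is
#' started otherwise.
#'
#' A monotonically rising regime — where every group differs
#' significantly from its neighbours — comes out of that rule as a run
#' of singleton blocks, even though such a run is naturally read as one
#' "rising" phase between two plateaus (a plateau / rising / plateau
#' pattern has three phases, not two plus a singleton per step). With
#' `transitions = TRUE`, maximal runs of two or more consecutive
#' singleton blocks are collapsed into a single transition phase after
#' the greedy merge.
#'
#' @param labels Group labels in their meaningful order (must all appear
#'   in the comparison).
#' @param comparison A [steel_dwass()] result.
#' @param alpha Significance threshold (default: the comparison's).
#' @param transitions If `TRUE`, collapse runs of consecutive singleton
#'   blocks into one transition phase (default `FALSE`).
#' @return List of character vectors, the ordered blocks.
#' @export
phase_partition <- function(labels, comparison, alpha = comparison$alpha,
                            transitions = FALSE) {
  stopifnot(inherits(comparison, "steel_dwass"))
  if (!all(labels %in% comparison$labels) ||
      length(labels) != comparison$k) {
    stop("'labels' must be a permutation of the comparison's groups",
         call. = FALSE)
  }
  p_of <- function(a, b) {
    pr <- comparison$pairs
    hit <- (pr$group1 == a & pr$group2 == b) |
           (pr$group1 == b & pr$group2 == a)
    pr$p_value[hit][1]
  }
  blocks <- list(labels[1])
  for (lab in labels[-1]) {
    cur <- blocks[[length(blocks)]]
    sep <- any(vapply(cur, function(m) p_of(lab, m) <= alpha, logical(1)))
    if (sep) {
      blocks[[length(blocks) + 1L]] <- lab
    } else {
      blocks[[length(blocks)]] <- c(cur, lab)
    }
  }
  if (transitions) blocks <- collapse_singleton_runs(blocks)
  blocks
}

# merge maximal runs of >= 2 consecutive singleton blocks into one
collapse_singleton_runs <- function(blocks) {
  out <- list()
  i <- 1L
  while (i <= length(blocks)) {
    j <- i
    while (j <= length(blocks) && length(blocks[[j]]) == 1L) j <- j + 1L
    if (j - i >= 2L) {
      out[[length(out) + 1L]] <- unlist(blocks[i:(j - 1L)])
      i <- j
    } else {
      out[[length(out) + 1L]] <- blocks[[i]]
      i <- i + 1L
    }
  }
  out
}
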