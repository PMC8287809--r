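test_that("trace generation and rate fitting invert each other", {
  # noiseless traces are exactly linear at the set rate
  tr <- generate_growth_traces(10.10, noise_sd = 0, duration = 60, dt = 2,
                               n_traces = 2, seed = 1)
  expect_length(tr, 2L)
  expect_equal(suppressWarnings(fit_growth_rate(tr[[1]])$rate), 10.10)
  flat <- generate_growth_traces(0, noise_sd = 0, duration = 60, dt = 2,
                                 seed = 1)[[1]]
  expect_true(all(flat$positions == 0))
  expect_equal(suppressWarnings(fit_growth_rate(flat)$rate), 0)
  # reproducible by seed
  expect_identical(
    generate_growth_traces(1.37, 0.05, 60, 2, 3, seed = 8),
    generate_growth_traces(1.37, 0.05, 60, 2, 3, seed = 8))
  expect_error(generate_growth_traces(-1, 0.05, 60, 2), "non-negative")
  expect_error(generate_growth_traces(1, 0.05, 0, 2), "positive")
  expect_error(fit_growth_rate(list(times = c(0, 1), positions = c(0, 1))),
               "3")
  expect_error(fit_growth_rate(list(times = c(0, 1, 1),
                                    positions = c(0, 1, 2))),
               "increasing")
})

test_that("noisy rate estimates are unbiased with calibrated intervals", {
  tr <- generate_growth_traces(1.37, noise_sd = 0.05, duration = 120,
                               dt = 0.4, n_traces = 100, seed = 3)
  fits <- lapply(tr, fit_growth_rate)
  rates <- vapply(fits, `[[`, numeric(1), "rate")
  se_mean <- sd(rates) / sqrt(100)
  expect_lt(abs(mean(rates) - 1.37), 3 * se_mean)
  # 95% CI coverage of the true slope over many traces
  tr2 <- generate_growth_traces(10.10, noise_sd = 0.1, duration = 60,
                                dt = 1, n_traces = 1000, seed = 5)
  covered <- vapply(tr2, function(x) {
    f <- fit_growth_rate(x)
    abs(f$rate - 10.10) < qt(0.975, f$n - 2) * f$se
  }, logical(1))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("Steel-Dwass matches a full permutation enumeration oracle", {
  g <- list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13))
  res <- steel_dwass(g)
  expect_equal(nrow(res$pairs), 1L)
  # oracle: enumerate all C(8,4) = 70 assignments of the pooled values
  pooled <- c(g$a, g$b)
  tstat <- function(idx) {
    r <- rank(pooled)
    R <- sum(r[idx])
    E <- 4 * 9 / 2
    V <- 16 / (8 * 7) * (sum(r^2) - 8 * 81 / 4)
    (R - E) / sqrt(V)
  }
  combos <- combn(8, 4)
  t_all <- apply(combos, 2, tstat)
  t_obs <- tstat(1:4)
  p_perm <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
  expect_equal(res$pairs$p_value, p_perm, tolerance = 0.02 / p_perm)
  expect_equal(res$pairs$statistic, t_obs)
})

test_that("Steel-Dwass handles ties, symmetry and identical groups", {
  # two identical groups: statistic 0, p near 1
  g <- list(x = c(3, 1, 4, 1, 5), y = c(3, 1, 4, 1, 5))
  res <- steel_dwass(g)
  expect_equal(res$pairs$statistic, 0)
  expect_gt(res$pairs$p_value, 0.99)
  # invariant to within-group order and to swapping the pair
  g2 <- list(x = rev(g$x), y = sample(g$y))
  expect_equal(steel_dwass(g2)$pairs$p_value, res$pairs$p_value)
  gs <- steel_dwass(list(x = g$y, y = g$x))
  expect_equal(abs(gs$pairs$statistic), abs(res$pairs$statistic))
  # all values tied across groups
  allt <- steel_dwass(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(allt$pairs$statistic, 0)
  # formula interface
  d <- data.frame(value = c(g$x, g$y), group = rep(c("x", "y"), each = 5))
  expect_equal(steel_dwass(value ~ group, data = d)$pairs$p_value,
               res$pairs$p_value)
  expect_error(steel_dwass(list(a = 1, b = c(1, 2))), "at least 2")
  expect_error(steel_dwass(list(a = c(1, 2))), "2 groups")
})

test_that("the studentized-range reference is conservative for k > 2", {
  set.seed(11)
  gs <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 2))
  res <- steel_dwass(gs)
  expect_equal(nrow(res$pairs), 3L)
  for (i in 1:3) {
    t_i <- res$pairs$statistic[i]
    p_normal <- 2 * pnorm(abs(t_i), lower.tail = FALSE)
    expect_gte(res$pairs$p_value[i], p_normal)
  }
})

test_that("family-wise error under the null stays near the nominal level", {
  set.seed(29)
  hits <- vapply(1:2000, function(i) {
    gs <- split(rnorm(40), rep(1:4, each = 10))
    any(steel_dwass(gs)$pairs$p_value < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.06)
})

test_that("phase partition merges indistinguishable neighbours", {
  mk_cmp <- function(p) {
    # synthetic comparison over 3 ordered groups with fixed p-values
    structure(list(
      pairs = data.frame(group1 = c("a", "a", "b"),
                         group2 = c("b", "c", "c"),
                         statistic = 0, p_value = p),
      labels = c("a", "b", "c"), k = 3L, alpha = 0.05),
      class = "steel_dwass")
  }
  expect_equal(phase_partition(c("a", "b", "c"), mk_cmp(rep(0.001, 3))),
               list("a", "b", "c"))
  expect_equal(phase_partition(c("a", "b", "c"), mk_cmp(rep(0.5, 3))),
               list(c("a", "b", "c")))
  # block extension requires indistinguishability from every member
  expect_equal(
    phase_partition(c("a", "b", "c"), mk_cmp(c(0.5, 0.001, 0.5))),
    list(c("a", "b"), "c"))
  expect_error(phase_partition(c("a", "z", "c"), mk_cmp(rep(0.5, 3))),
               "permutation")
})

test_that("a plateau-rising-plateau series yields its regime structure", {
  rates <- three_regime_rates(seed = 17)
  cmp <- steel_dwass(rates)
  strict <- phase_partition(names(rates), cmp)
  # the rising regime's groups differ pairwise, so the pure
  # indistinguishability rule isolates each of them
  expect_equal(strict, list(c("c1", "c2"), "c3", "c4", "c5",
                            c("c6", "c7")))
  phases <- phase_partition(names(rates), cmp, transitions = TRUE)
  expect_equal(phases, list(c("c1", "c2"), c("c3", "c4", "c5"),
                            c("c6", "c7")))
})
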