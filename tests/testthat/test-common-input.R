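# fine-timescale synchrony testing against the interval-jitter null

test_that("bin_events applies half-open 1 ms bins with collapse", {
  b0 <- bin_events(data.frame(trial = integer(), t_ms = numeric()), 100,
                   trials = 1:4)
  expect_equal(sum(lengths(b0$bins)), 0L)
  expect_equal(dim(as.matrix(b0)), c(4L, 100L))

  b1 <- bin_events(data.frame(trial = 1L, t_ms = c(3.2, 3.9)), 100, trials = 1L)
  expect_equal(b1$bins[[1]], 3L)            # both events in bin [3, 4)
  b2 <- bin_events(data.frame(trial = 1L, t_ms = 4.0), 100, trials = 1L)
  expect_equal(b2$bins[[1]], 4L)            # exact boundary joins later bin

  expect_error(bin_events(data.frame(trial = 1L, t_ms = 101), 100), "outside")
  expect_error(bin_events(data.frame(trial = 1L, t_ms = 1), 100.5), "divide")
})

test_that("synchrony_statistic counts lag -1/0/+1 coincidences", {
  mk <- function(bins, n_bins = 300) {
    ev <- data.frame(trial = rep(1L, length(bins)), t_ms = bins + 0.5)
    bin_events(ev, n_bins, trials = 1L)
  }
  a <- mk(c(100, 200)); b <- mk(c(100, 201))
  expect_equal(synchrony_statistic(a, b), 2L)   # lag 0 at 100, lag +1 at 200/201
  expect_equal(synchrony_statistic(a, mk(numeric(0))), 0L)

  # autocorrelation identity: a = b with k isolated ones gives k
  k <- 7
  iso <- mk(seq(10, 10 + 3 * (k - 1), by = 3))
  expect_equal(synchrony_statistic(iso, iso), k)

  # symmetry over random trains
  set.seed(6)
  for (i in 1:10) {
    x <- mk(sort(sample(0:299, 12)))
    y <- mk(sort(sample(0:299, 9)))
    expect_identical(synchrony_statistic(x, y), synchrony_statistic(y, x))
  }
  expect_error(synchrony_statistic(a, bin_events(data.frame(trial = 1L, t_ms = 1),
                                                 200, trials = 1L)), "shape")
})

test_that("jitter_null conserves windows, is deterministic, and matches the R engine", {
  mk <- function(bins, trials, n_bins = 100, tr = 1:2) {
    bin_events(data.frame(trial = trials, t_ms = bins + 0.5), n_bins, trials = tr)
  }
  empty <- mk(numeric(0), integer(0))
  expect_true(all(jitter_null(empty, empty, n_resamples = 200, seed = 1) == 0))

  # fixed-partition property: an event in window [10, 20) can never reach a
  # bin in another window, and can reach any bin inside its own
  b <- mk(13, 1L)
  a_out <- mk(25, 1L)              # other window: no coincidence, ever
  expect_true(all(jitter_null(a_out, b, delta_ms = 10, n_resamples = 500,
                              seed = 2, jitter = "b_only") == 0))
  a_in <- mk(19, 1L)               # same window: sometimes lands adjacent
  nn <- jitter_null(a_in, b, delta_ms = 10, n_resamples = 500, seed = 3,
                    jitter = "b_only")
  expect_true(any(nn > 0) && any(nn == 0))

  # determinism given seed, for both engines
  set.seed(7)
  x <- mk(sort(sample(0:99, 8)), rep(1:2, 4))
  y <- mk(sort(sample(0:99, 8)), rep(1:2, 4))
  expect_identical(jitter_null(x, y, n_resamples = 300, seed = 11),
                   jitter_null(x, y, n_resamples = 300, seed = 11))
  # compiled and reference implementations draw the same null distribution
  n_cpp <- jitter_null(x, y, n_resamples = 2000, seed = 12, engine = "cpp")
  n_r <- jitter_null(x, y, n_resamples = 2000, seed = 13, engine = "r")
  expect_lt(abs(mean(n_cpp) - mean(n_r)), 0.25)
  expect_lt(suppressWarnings(ks.test(n_cpp, n_r)$statistic), 0.08)

  expect_error(jitter_null(x, y, delta_ms = 1, n_resamples = 200), "2 bins")
  expect_error(jitter_null(x, y, delta_ms = 10.5, n_resamples = 200), "multiple")
})

test_that("common_input_pvalue uses the +1 Monte Carlo correction", {
  expect_equal(common_input_pvalue(10, rep(0, 1999)), 1 / 2000)  # = 0.0005
  expect_equal(common_input_pvalue(0, rep(0, 999)), 1)
  nul <- 1:1000
  expect_equal(common_input_pvalue(500, nul), (1 + 501) / 1001, tolerance = 1e-9)
  expect_error(common_input_pvalue(1, numeric()), "empty")
})

test_that("shared-source synchrony survives partition-phase shifts", {
  # a diverging source stays detectable when all events shift by delta/2
  set.seed(8)
  hits <- 0L
  for (i in 1:10) {
    s <- sim_site_trains(shared = TRUE)
    shift <- function(bt) {
      bt$bins <- lapply(bt$bins, function(b) pmin(b + 5L, bt$n_bins - 1L))
      bt
    }
    a <- shift(s$a); b <- shift(s$b)
    p <- common_input_pvalue(synchrony_statistic(a, b),
                             jitter_null(a, b, n_resamples = 999, seed = i))
    hits <- hits + (p <= 0.01)
  }
  expect_gte(hits, 9L)
})

test_that("detect_common_inputs pools candidates under BH", {
  one <- data.frame(pair_id = "p", site = 1L, statistic = 9L, p_value = 0.0005)
  expect_true(detect_common_inputs(one, q = 0.05)$common)
  empty <- one[0, ]
  expect_equal(nrow(detect_common_inputs(empty)), 0L)

  # independent-source candidates: flagged fraction stays near/below q
  set.seed(9)
  ps <- replicate(60, {
    s <- sim_site_trains(shared = FALSE)
    common_input_pvalue(synchrony_statistic(s$a, s$b),
                        jitter_null(s$a, s$b, n_resamples = 499,
                                    seed = sample.int(1e6, 1)))
  })
  flags <- detect_common_inputs(data.frame(pair_id = "x", site = seq_along(ps),
                                           statistic = 0L, p_value = ps), q = 0.05)
  expect_lte(mean(flags$common), 0.05)
})

test_that("pair_summary does the set arithmetic", {
  ps <- pair_summary(c("a", "b", "c"), c("b", "c", "d"), "b")
  expect_equal(ps$common_input_probability, 1 / 4)
  expect_equal(pair_summary(1:3, 4:6, integer())$common_input_probability, 0)
  expect_equal(pair_summary(1:3, 1:3, 1:3)$common_input_probability, 1)
  expect_equal(pair_summary(integer(), integer(), integer())$common_input_probability, 0)
  expect_error(pair_summary(1:3, 4:6, 1L), "intersection")
})
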