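# per-site evoked-input statistics and charge-map operations

test_that("background_rate counts ITI-tail events", {
  ses <- make_session(spacing_um = 40, n_trials_per_site = 1)   # 100 trials
  no_ev <- event_table <- data.frame(cell_id = character(), trial = integer(),
                                     t_ms = numeric())
  expect_equal(length(background_rate(no_ev, ses)), 0L)

  # 10 events in the 25 ms tails of 100 ITIs: 10 / 2.5 s = 4 Hz
  ev <- data.frame(cell_id = "c1", trial = 1:10, t_ms = ses$trial_len - 10)
  expect_equal(unname(background_rate(ev, ses)["c1"]), 4)
  # events outside the tail do not count
  ev2 <- rbind(ev, data.frame(cell_id = "c1", trial = 11:20, t_ms = 50))
  expect_equal(unname(background_rate(ev2, ses)["c1"]), 4)

  short <- make_session(spacing_um = 40, n_trials_per_site = 1, iti = 20)
  expect_error(background_rate(ev, short), "shorter")

  # simulated 5 Hz background recovered within 3 SE
  circ0 <- make_circuit(0, c(L4 = 1), "exclusive", seed = 1)
  big <- make_session(spacing_um = 20, n_trials_per_site = 10)
  evs <- simulate_mapping_session(circ0, big, background_rate = 5, seed = 2)
  est <- unname(background_rate(evs, big)[1])
  tail_s <- length(big$trial_order) * 25 / 1000
  expect_lt(abs(est - 5), 3 * sqrt(5 / tail_s))
})

test_that("site_pvalue is a Poisson upper tail with sane degeneracies", {
  expect_equal(site_pvalue(0, 10, 10), 1)
  # expected count 1.0, observed 5: 1 - sum_{k<5} e^-1/k!
  p_oracle <- 1 - sum(exp(-1) / factorial(0:4))
  expect_equal(site_pvalue(5, background = 1000 / 30, n_trials = 1), p_oracle)
  expect_equal(round(p_oracle, 5), 0.00366)

  # monotone: decreasing in observed count, increasing in background
  p_by_obs <- vapply(1:10, site_pvalue, numeric(1), background = 10, n_trials = 5)
  expect_true(all(diff(p_by_obs) < 0))
  p_by_bg <- vapply(c(1, 2, 5, 10, 20), function(b)
    site_pvalue(5, b, n_trials = 5), numeric(1))
  expect_true(all(diff(p_by_bg) > 0))

  # zero background with observed > 0 uses the configured floor, never p = 0
  p0 <- site_pvalue(3, 0, 10, rate_floor = 0.1)
  expect_gt(p0, 0)
  expect_lt(p0, 1e-4)
})

test_that("bh_fdr implements the step-up procedure", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.8), q = 0.1),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.1), rep(FALSE, 5))
  expect_true(bh_fdr(0.04, 0.05))
  expect_equal(bh_fdr(numeric(), 0.1), logical())
})

test_that("detect_input_sites composes the pipeline correctly", {
  ses <- make_session(n_trials_per_site = 10)
  circ0 <- make_circuit(0, c(L4 = 1), "exclusive", seed = 1)

  # zero events everywhere: zero flagged sites
  ev0 <- data.frame(cell_id = "pc_L4_1", trial = 1L, t_ms = numeric(1))[0, ]
  s0 <- detect_input_sites(rbind(ev0,
    data.frame(cell_id = "pc_L4_1", trial = 1L, t_ms = 50)), ses)
  expect_equal(sum(s0$significant), 0L)

  # evoked deviation bookkeeping
  ev <- simulate_mapping_session(circ0, ses, background_rate = 5, seed = 3)
  s <- detect_input_sites(ev, ses)
  bg <- unname(background_rate(ev, ses)[1])
  i <- which.max(s$observed_events)
  expect_equal(s$evoked_deviation[i],
               s$observed_events[i] / s$n_trials[i] - bg * 30 / 1000)
  expect_true(all(s$p_value > 0 & s$p_value <= 1))
})

test_that("binarize_charge_map flags only genuinely extreme sites", {
  xs <- seq(20, 100, by = 20); ds <- seq(20, 120, by = 20)
  base <- c(0.1, 0.2, 0.15, 0.12, 0.18, 0.22, 0.09, 0.16, 0.2, 0.11)
  # null map: charges drawn from the baseline distribution
  set.seed(4)
  m0 <- charge_map(matrix(sample(base, 30, replace = TRUE), 6, 5), xs, ds,
                   boundaries = c(10, 40, 80, 100, 130))
  f0 <- binarize_charge_map(m0, base, n_perm = 2000, alpha = 0.05, seed = 1)
  expect_equal(sum(f0), 0L)   # Bonferroni kills everything under the null
  p0 <- attr(f0, "p")
  expect_true(mean(p0 <= 0.5) > 0.2)  # but raw p-values spread over (0, 1]

  # one site far above every baseline value: minimal p, flagged
  ch <- matrix(0.15, 6, 5); ch[3, 3] <- 50
  m1 <- charge_map(ch, xs, ds, boundaries = c(10, 40, 80, 100, 130))
  f1 <- binarize_charge_map(m1, base, n_perm = 2000, alpha = 0.05, seed = 2)
  expect_true(f1[3, 3])
  expect_equal(attr(f1, "p")[3, 3], 1 / 2001)

  expect_error(binarize_charge_map(m1, 0.1), "baseline")
})

test_that("align_and_average_maps registers and averages correctly", {
  xs <- seq(-200, 200, by = 20); ds <- seq(-300, 300, by = 20)
  set.seed(5)
  ch <- matrix(runif(length(ds) * length(xs)), length(ds), length(xs))
  m <- charge_map(ch, xs, ds, boundaries = c(-250, -150, 0, 150, 290),
                  soma_xy = c(0, 100), home_x = 0)

  # already-aligned single map: output equals cropped input
  avg <- align_and_average_maps(list(m), "home_column")
  ri <- match(avg$row_depths, ds); ci <- match(avg$col_x, xs)
  ok <- !is.na(ri) & any(!is.na(ci))
  expect_equal(avg$charge[which(!is.na(ri)), which(!is.na(ci))],
               ch[ri[!is.na(ri)], ci[!is.na(ci)]], tolerance = 1e-10,
               ignore_attr = TRUE)

  # idempotence: aligning an aligned map changes nothing where both defined
  avg2 <- align_and_average_maps(list(avg), "home_column")
  ri2 <- match(avg$row_depths, avg2$row_depths)
  ci2 <- match(avg$col_x, avg2$col_x)
  re <- avg2$charge[ri2[!is.na(ri2)], ci2[!is.na(ci2)]]
  orig <- avg$charge[!is.na(ri2), !is.na(ci2)]
  both <- !is.na(re) & !is.na(orig)
  expect_gt(sum(both), 100)
  expect_lt(max(abs(re[both] - orig[both])), 1e-10)

  # two identical maps offset vertically by one row: average equals either
  m_up <- charge_map(ch, xs, ds + 20, boundaries = c(-250, -150, 0, 150, 290) + 20,
                     soma_xy = c(0, 120), home_x = 0)
  avg3 <- align_and_average_maps(list(m, m_up), "home_column")
  ri3 <- match(ds, avg3$row_depths)
  expect_equal(avg3$charge[ri3[!is.na(ri3)], match(xs, avg3$col_x)],
               ch[!is.na(ri3), ], tolerance = 1e-10, ignore_attr = TRUE)

  # all-zero maps average to zero
  z <- charge_map(matrix(0, length(ds), length(xs)), xs, ds,
                  boundaries = c(-250, -150, 0, 150, 290), home_x = 0)
  expect_equal(max(abs(align_and_average_maps(list(z, z))$charge), na.rm = TRUE), 0)

  m_bad <- m; m_bad$l45_points <- NULL
  expect_error(align_and_average_maps(list(m_bad)), "annotation")
})

test_that("layer_charge_proportion partitions charge by laminar depth", {
  xs <- seq(20, 100, by = 20)
  ds <- seq(10, 790, by = 20)   # rows spanning 0-800 um
  b <- c(0, 200, 400, 600, 800)
  mk <- function(f) {
    ch <- matrix(0, length(ds), length(xs))
    for (i in seq_along(ds)) ch[i, ] <- f(ds[i])
    charge_map(ch, xs, ds, boundaries = b)
  }
  expect_equal(layer_charge_proportion(mk(function(d) as.numeric(d > 200 & d < 400))), 1)
  expect_equal(layer_charge_proportion(mk(function(d) 1)), 0.5)
  expect_equal(layer_charge_proportion(mk(function(d) as.numeric(d < 200))), 0)

  # invariant under uniform rescaling of all charges
  m1 <- mk(function(d) d / 800)
  m2 <- m1; m2$charge <- m2$charge * 37
  expect_equal(layer_charge_proportion(m1), layer_charge_proportion(m2))

  expect_warning(p <- layer_charge_proportion(mk(function(d) 0)), "zero")
  expect_true(is.na(p))
})
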