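# generators: determinism, structural invariants, and agreement with simple
# counting oracles

test_that("make_circuit enforces divergence structure and determinism", {
  expect_equal(nrow(make_circuit(0, c(L4 = 3), "exclusive", seed = 1)$connections), 0L)

  # exclusive mode: no SST cell targets both L4 and L5, for every seed
  for (s in 1:10) {
    circ <- make_circuit(20, c(L4 = 4, L5 = 4), "exclusive", seed = s)
    layers <- split(circ$pc$layer[match(circ$connections$pc_id, circ$pc$id)],
                    circ$connections$sst_id)
    expect_true(all(vapply(layers, function(l)
      length(intersect(unique(l), c("L4", "L5"))) <= 1L, logical(1))))
  }

  # mixed mode with fraction 1: every SST diverges onto both layers
  circ <- make_circuit(15, c(L4 = 3, L5 = 3), "mixed", seed = 2, mixed_fraction = 1)
  layers <- split(circ$pc$layer[match(circ$connections$pc_id, circ$pc$id)],
                  circ$connections$sst_id)
  expect_true(all(vapply(layers, function(l) all(c("L4", "L5") %in% l), logical(1))))

  expect_identical(make_circuit(12, c(L4 = 2, L5 = 2), "exclusive", seed = 7),
                   make_circuit(12, c(L4 = 2, L5 = 2), "exclusive", seed = 7))
  expect_error(make_circuit(5, c(L4 = 2), "banana"), "arg")
  expect_error(make_circuit(5, c(L7 = 2), "exclusive"), "layer")
})

test_that("simulate_mapping_session: empty, forced, and Poisson-rate cases", {
  ses <- make_session(spacing_um = 40, n_trials_per_site = 4)
  circ0 <- make_circuit(0, c(L4 = 1), "exclusive", seed = 1)

  ev0 <- simulate_mapping_session(circ0, ses, background_rate = 0, seed = 1)
  expect_equal(nrow(ev0), 0L)
  expect_error(simulate_mapping_session(circ0, ses, background_rate = -1), "background")

  # deterministic synapse, soma-targeted stimulation: an IPSC on every trial
  circ <- make_circuit(1, c(L4 = 1), "exclusive", seed = 3)
  circ$sst$x <- 40; circ$sst$y <- 40
  circ$connections$failure_prob <- 0
  prof <- excitation_profile(p_soma = 1)
  ev <- simulate_mapping_session(circ, ses, prof, background_rate = 0, seed = 4)
  soma_site <- ses$grid$site[ses$grid$x == 40 & ses$grid$y == 40]
  soma_trials <- which(ses$trial_order == soma_site)
  expect_true(all(soma_trials %in% ev$trial))
  # all evoked events fall within stimulus onset + latency truncation + delay
  expect_true(all(ev$t_ms < ses$stim_onset + prof$truncation + 5))

  # background-only empirical rate within 3 SE of lambda (Poisson counting)
  lambda <- 5
  ev_bg <- simulate_mapping_session(circ0, ses, background_rate = lambda, seed = 5)
  total_s <- length(ses$trial_order) * ses$trial_len / 1000
  se <- sqrt(lambda / total_s)
  expect_lt(abs(nrow(ev_bg) / total_s - lambda), 3 * se)

  # event trains sorted and within trial bounds for a spread of seeds
  for (s in 1:5) {
    e <- simulate_mapping_session(circ, ses, prof, background_rate = 10, seed = s)
    expect_true(all(e$t_ms >= 0 & e$t_ms < ses$trial_len))
    expect_true(all(unlist(tapply(e$t_ms, paste(e$cell_id, e$trial),
                                  function(x) diff(x) >= 0))))
  }
  expect_identical(simulate_mapping_session(circ, ses, prof, 5, seed = 11),
                   simulate_mapping_session(circ, ses, prof, 5, seed = 11))
})

test_that("background-only sessions pass Poisson goodness-of-fit", {
  # chi-square GOF on per-trial counts, alpha = 0.01, >= 95% of 100 seeded runs
  ses <- make_session(spacing_um = 40, n_trials_per_site = 4)
  circ0 <- make_circuit(0, c(L4 = 1), "exclusive", seed = 1)
  lambda <- 5 * ses$trial_len / 1000       # mean count per trial
  n_tr <- length(ses$trial_order)
  pass <- logical(100)
  for (s in 1:100) {
    ev <- simulate_mapping_session(circ0, ses, background_rate = 5, seed = 1000 + s)
    counts <- tabulate(ev$trial, nbins = n_tr)
    obs <- c(sum(counts == 0), sum(counts == 1), sum(counts >= 2))
    p <- c(dpois(0:1, lambda), ppois(1, lambda, lower.tail = FALSE))
    stat <- sum((obs - n_tr * p)^2 / (n_tr * p))
    pass[s] <- stat <= qchisq(0.99, df = 2)
  }
  expect_gte(mean(pass), 0.95)
})

test_that("simulate_paired_dataset reproduces hierarchy and rates", {
  str0 <- list(MC = c(2, 3, 1), NMC = c(4, 2))
  d0 <- simulate_paired_dataset(str0, c(MC = 0, NMC = 0), seed = 1)
  expect_true(all(d0$outcome == 0))
  d1 <- simulate_paired_dataset(str0, c(MC = 1, NMC = 1), seed = 1)
  expect_true(all(d1$outcome == 1))
  # hierarchy preserved exactly as given
  cnt <- vapply(split(d1$connection_id, d1$cell_id), length, integer(1))
  expect_equal(unname(cnt[sprintf("MC_cell%02d", 1:3)]), c(2L, 3L, 1L))
  expect_equal(unname(cnt[sprintf("NMC_cell%02d", 1:2)]), c(4L, 2L))

  # pooled empirical rate near 0.5 over 10,000 connections (binomial bound)
  d <- simulate_paired_dataset(list(G = rep(4L, 2500)), c(G = 0.5), seed = 2)
  expect_true(mean(d$outcome) > 0.48 && mean(d$outcome) < 0.52)

  expect_error(simulate_paired_dataset(list(A = 1), c(B = 0.5)), "names")
  expect_error(simulate_paired_dataset(list(A = 1), c(A = 1.5)), "0, 1")
})

test_that("simulate_step_protocol obeys Ohm's law and the spike schedule", {
  np <- neuron_params(v_rest = -65, r_in = 20, v_thresh = -40, membrane_tau = 10)
  sw <- simulate_step_protocol(np, step_amplitudes = c(-100), seed = 1,
                               noise_sd_mv = 0)
  s <- sw$sweeps[[1]]
  steady <- mean(s$v[s$t >= 1000 & s$t < 1200])
  expect_equal(steady, -65 - 2, tolerance = 0.01)   # -100 pA x 20 MOhm = -2 mV

  # amplitude below rheobase: no spikes
  np2 <- neuron_params(r_in = 100)   # rheobase 250 pA
  sw2 <- simulate_step_protocol(np2, step_amplitudes = c(200), seed = 1)
  expect_equal(length(sw2$truth$spike_onsets[[1]]), 0L)

  # zero adaptation increment: all ISIs equal
  np3 <- neuron_params(adaptation_increment = 0)
  sw3 <- simulate_step_protocol(np3, step_amplitudes = c(400), seed = 1)
  isis <- diff(sw3$truth$spike_onsets[[1]])
  expect_lt(diff(range(isis)), 1e-9)

  expect_identical(simulate_step_protocol(np3, seed = 5),
                   simulate_step_protocol(np3, seed = 5))
})

test_that("simulate_invivo_units produces calibrated Poisson counts", {
  tt <- make_trial_table(120, seed = 1)
  expect_error(simulate_invivo_units(2, 10, 1, trial_table = data.frame()), "trial")

  units <- simulate_invivo_units(3, base_rate_hz = 20, light_effect = 1,
                                 trial_table = tt, seed = 2)
  u <- units[[1]]
  counts <- trial_count(u$spike_times, tt$t_motor_onset)
  # 20 Hz x 0.75 s window: mean count 15 per trial, light effect 1 => no split
  expect_equal(mean(counts), 15, tolerance = 0.8)
  expect_equal(abs(mean(counts[tt$light == 1]) - mean(counts[tt$light == 0])) <
                 4 * sqrt(15 * (1 / sum(tt$light) + 1 / sum(!tt$light))), TRUE)

  halved <- simulate_invivo_units(1, 20, 0.5, tt, seed = 3)[[1]]
  ch <- trial_count(halved$spike_times, tt$t_motor_onset)
  expect_lt(mean(ch[tt$light == 1]), mean(ch[tt$light == 0]))

  expect_identical(simulate_invivo_units(2, 10, 0.8, tt, seed = 9),
                   simulate_invivo_units(2, 10, 0.8, tt, seed = 9))

  # waveform latencies straddle the 0.36/0.38 classification boundary
  many <- simulate_invivo_units(60, 5, 1, make_trial_table(5, seed = 1), seed = 4)
  ttp <- vapply(many, `[[`, numeric(1), "trough_to_peak")
  expect_true(any(ttp < 0.36) && any(ttp > 0.38))
})
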