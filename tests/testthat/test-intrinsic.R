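# intrinsic-electrophysiology feature extraction and subtype classification

test_that("detect_spike_onsets finds thresholds in phase space", {
  rate <- 20
  # subthreshold trace: no spikes, no error
  sub <- trace(-65 + 3 * (1 - exp(-(0:4000) / 400)), rate)
  expect_equal(nrow(detect_spike_onsets(sub)), 0L)

  # exponential take-off at V0 = -42: slow depolarizing ramp, then
  # dV/dt growing linearly with V above V0 (constant phase-space slope)
  t <- seq(0, 30, by = 1 / rate)
  v <- -60 + 1.2 * t                      # 1.2 mV/ms ramp
  i_on <- which(v >= -42)[1]
  tau_up <- 0.2
  rest <- seq(i_on, length(t))
  grow <- -42 + 3 * (exp((t[rest] - t[i_on]) / tau_up) - 1)
  i_pk <- rest[which(grow >= 20)[1]]
  v[i_on:i_pk] <- grow[seq_len(i_pk - i_on + 1L)]
  # repolarize linearly over 2 ms, then rest
  n_dn <- min(2 * rate, length(t) - i_pk)
  v[i_pk + seq_len(n_dn)] <- seq(v[i_pk], -60, length.out = n_dn)
  if (i_pk + n_dn < length(t)) v[(i_pk + n_dn + 1L):length(t)] <- -60
  tr <- trace(v, rate)
  on <- detect_spike_onsets(tr)
  expect_equal(nrow(on), 1L)
  expect_lt(abs(on$v_thresh - (-42)), 1)

  # two identical spikes give identical thresholds (determinism)
  y <- triangle_spike_trace()$y
  two <- trace(c(y, y), rate)
  on2 <- detect_spike_onsets(two)
  expect_equal(nrow(on2), 2L)
  expect_equal(on2$v_thresh[1], on2$v_thresh[2])
})

test_that("spike_width measures full width at half height", {
  # symmetric triangle, threshold -40, peak 0, base 1 ms: width 0.5 ms
  tr <- triangle_spike_trace(v_th = -40, v_peak = 0, base_ms = 1)
  on <- detect_spike_onsets(tr)
  w <- spike_width(tr, on[1, ])
  expect_equal(w, 0.5, tolerance = 0.05)

  # invariant to adding a constant to the whole trace
  tr2 <- tr; tr2$y <- tr2$y + 12
  on2 <- detect_spike_onsets(tr2)
  expect_equal(spike_width(tr2, on2[1, ]), w, tolerance = 1e-6)

  # halving the time base halves the width
  tr3 <- triangle_spike_trace(v_th = -40, v_peak = 0, base_ms = 0.5)
  on3 <- detect_spike_onsets(tr3)
  expect_equal(spike_width(tr3, on3[1, ]), w / 2, tolerance = 0.03)
})

test_that("adaptation_index matches the normalized successive-ISI formula", {
  expect_equal(adaptation_index(c(0, 10, 20, 30, 40)), 0)
  # ISIs 10, 20, 30: (1/2) (10/30 + 10/50) = 0.2667
  expect_equal(adaptation_index(c(0, 10, 30, 60)), 1 / 2 * (10 / 30 + 10 / 50))
  expect_equal(round(adaptation_index(c(0, 10, 30, 60)), 4), 0.2667)
  # reversing the ISI sequence flips the sign
  expect_equal(adaptation_index(c(0, 30, 50, 60)), -adaptation_index(c(0, 10, 30, 60)))
  expect_true(is.na(adaptation_index(c(0, 10))))
  # bounded in [-1, 1] for arbitrary positive ISI sequences
  set.seed(11)
  for (i in 1:20) {
    ai <- adaptation_index(cumsum(rexp(10) + 0.01))
    expect_true(ai >= -1 && ai <= 1)
  }
})

test_that("passive_properties applies Ohm's law", {
  np <- neuron_params(v_rest = -65, r_in = 20, v_thresh = -40)
  sw <- simulate_step_protocol(np, step_amplitudes = c(-100), seed = 1,
                               noise_sd_mv = 0)
  pp <- passive_properties(sw)
  expect_equal(pp$v_rest, -65, tolerance = 0.01)
  expect_equal(pp$r_in, 20, tolerance = 0.2)    # -2 mV / -100 pA

  np2 <- neuron_params(r_in = 150)
  sw2 <- simulate_step_protocol(np2, seed = 2)
  expect_lt(abs(passive_properties(sw2)$r_in - 150) / 150, 0.05)
})

test_that("estimate_rheobase averages the F-I fit and Ohm's law", {
  # Ohm's-law estimate alone: rest -70, 100 MOhm, threshold -40 -> 300 pA
  no_supra <- data.frame(i_inj = c(100, 200), n_spikes = c(0, 0),
                         rate_hz = c(0, 0))
  r <- estimate_rheobase(no_supra, v_rest = -70, r_in = 100, mean_thresh = -40)
  expect_equal(r$rheobase_pa, 300)
  expect_true(r$flagged)

  # collinear F-I points (250,0), (300,5), (350,10): fitted crossing at 250
  fi <- data.frame(i_inj = c(250, 300, 350), n_spikes = c(0, 5, 10),
                   rate_hz = c(0, 5, 10))
  r2 <- estimate_rheobase(fi, v_rest = -70, r_in = 100, mean_thresh = -45)
  expect_equal(r2$est_fi_pa, 250, tolerance = 1e-6)
  expect_equal(r2$rheobase_pa, (250 + 250) / 2, tolerance = 1e-6)
})

test_that("classify_subtype separates and cross-validates", {
  set.seed(12)
  # well-separated synthetic clusters: MC broad spike/low rheobase,
  # NMC narrow spike/high rheobase
  n <- 30
  feats <- rbind(cbind(rnorm(n, 1.1, 0.08), rnorm(n, 120, 25)),
                 cbind(rnorm(n, 0.45, 0.06), rnorm(n, 330, 40)))
  colnames(feats) <- c("spike_width", "rheobase")
  labs <- rep(c("MC", "NMC"), each = n)
  m <- classify_subtype(feats, labs, folds = 10, seed = 1)
  expect_equal(m$cv_accuracy, 1)
  expect_equal(as.character(predict(m, feats[c(1, n + 1), ])), c("MC", "NMC"))

  # shuffled labels: chance-level accuracy (binomial CI around 0.5)
  m0 <- classify_subtype(feats, sample(labs), folds = 10, seed = 2)
  expect_gt(m0$cv_accuracy, 0.5 - 3 * sqrt(0.25 / (2 * n)))
  expect_lt(m0$cv_accuracy, 0.5 + 3 * sqrt(0.25 / (2 * n)))

  # same seed: identical folds and accuracy
  expect_identical(classify_subtype(feats, labs, seed = 5)$cv_accuracy,
                   classify_subtype(feats, labs, seed = 5)$cv_accuracy)
  expect_error(classify_subtype(feats, rep("MC", 2 * n)), "two classes")
  expect_error(classify_subtype(feats[1:5, ], labs[c(1, 1, 1, 31, 31)],
                                folds = 10), "folds")
})
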