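# shared fixtures, all generated in code

# bi-exponential template matching the detector's default shape
biexp_template <- function(rate_khz = 20, tau_rise = 0.5, tau_decay = 4,
                           length_ms = 20) {
  tt <- seq(0, length_ms, by = 1 / rate_khz)
  w <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  w / max(w)
}

# inject template events of given amplitude into a signal vector (in place)
inject_events <- function(y, times_ms, amp, rate_khz = 20, w = biexp_template(rate_khz)) {
  for (t0 in times_ms) {
    i0 <- round(t0 * rate_khz) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    keep <- idx <= length(y)
    y[idx[keep]] <- y[idx[keep]] + amp * w[keep]
  }
  y
}

# two-cell event trains at one stimulation site: either a single presynaptic
# source diverging onto both cells (shared latency per trial, fine jitter per
# connection) or two co-activated sources with independent latencies
sim_site_trains <- function(shared, n_trials = 10, trial_len = 110,
                            conn_jitter_sd = 0.3, latency_sd = 3.5,
                            background_hz = 5, bin_ms = 1) {
  rlat <- function(n) {
    m <- 8; s <- latency_sd
    x <- rgamma(n, shape = (m / s)^2, rate = m / s^2)
    pmin(x, 19.9)
  }
  mk <- function(lat) {
    ev <- data.frame(trial = integer(), t_ms = numeric())
    for (k in seq_len(n_trials)) {
      ts <- lat[k] + pmax(1.5 + rnorm(1, 0, conn_jitter_sd), 0.1)
      ts <- c(ts, runif(rpois(1, background_hz * trial_len / 1000), 0, trial_len))
      ts <- ts[ts >= 0 & ts < trial_len]
      if (length(ts)) ev <- rbind(ev, data.frame(trial = k, t_ms = ts))
    }
    bin_events(ev, floor(trial_len / bin_ms) * bin_ms, bin_ms,
               trials = seq_len(n_trials))
  }
  if (shared) {
    lat <- rlat(n_trials)
    list(a = mk(lat), b = mk(lat))
  } else {
    list(a = mk(rlat(n_trials)), b = mk(rlat(n_trials)))
  }
}

# noiseless triangular spike with a slow depolarizing approach up to
# threshold (so the phase-space onset is a genuine kink, not a discontinuity)
triangle_spike_trace <- function(v_base = -65, v_th = -40, v_peak = 0,
                                 base_ms = 1, rate_khz = 20, pad_ms = 5,
                                 approach_ms = 2) {
  half <- base_ms / 2
  t <- seq(0, 2 * pad_ms + approach_ms + base_ms, by = 1 / rate_khz)
  v <- rep(v_base, length(t))
  a0 <- pad_ms
  s <- pad_ms + approach_ms
  appr <- t >= a0 & t < s
  v[appr] <- v_base + (v_th - v_base) * (t[appr] - a0) / approach_ms
  up <- t >= s & t < s + half
  v[up] <- v_th + (v_peak - v_th) * (t[up] - s) / half
  dn <- t >= s + half & t <= s + base_ms
  v[dn] <- v_peak - (v_peak - v_th) * (t[dn] - s - half) / half
  trace(v, rate_khz)
}
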