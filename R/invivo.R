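# In vivo unit pipeline: inclusion criteria, fast-/regular-spiking
# classification from waveform trough-to-peak latency, running-trial
# selection, windowed firing rates, z-scored PSTHs, and the per-unit
# optogenetic modulation test.

#' Fraction of inter-spike intervals violating a refractory period
#'
#' \code{#\{ISIs < refractory\} / #spikes}. Units with more than 3% of their
#' waveforms violating a 2 ms refractory period are conventionally excluded
#' (burst-firing units may be kept by an explicit override; see
#' \code{\link{unit_inclusion}}).
#'
#' @param spike_times sorted spike times; same unit as \code{refractory}
#'   (ms by default).
#' @param refractory refractory period (default 2 ms).
#' @return Proportion in [0, 1]; fewer than 2 spikes gives 0, flagged with
#'   attribute \code{"flagged"}.
#' @examples
#' refractory_violation_fraction(c(0, 1, 10))  # 1 violation over 3 spikes
#' @export
refractory_violation_fraction <- function(spike_times, refractory = 2) {
  check_number(refractory, "refractory", lower = 0)
  if (length(spike_times) < 2L)
    return(structure(0, flagged = TRUE))
  isi <- diff(sort(spike_times))
  sum(isi < refractory) / length(spike_times)
}

#' Unit inclusion by the refractory-violation criterion
#'
#' @param spike_times_s spike times in seconds.
#' @param max_fraction maximum tolerated violation fraction (default 0.03).
#' @param refractory_ms refractory period, ms.
#' @param burst_override keep the unit regardless (manual flag for
#'   burst-firing units, which violate the criterion by design).
#' @return Logical.
#' @export
unit_inclusion <- function(spike_times_s, max_fraction = 0.03, refractory_ms = 2,
                           burst_override = FALSE) {
  if (burst_override) return(TRUE)
  refractory_violation_fraction(spike_times_s * 1000, refractory_ms) <= max_fraction
}

#' Classify units as fast-spiking or regular-spiking
#'
#' Waveform trough-to-peak latency below 0.36 ms gives \code{"FS"}
#' (fast-spiking, putative parvalbumin interneuron), above 0.38 ms gives
#' \code{"RS"} (regular-spiking); intermediate latencies are
#' \code{"excluded"}.
#'
#' @param trough_to_peak_ms latency or vector of latencies, ms (> 0).
#' @return Character vector over \code{c("FS", "RS", "excluded")}.
#' @examples
#' classify_unit(c(0.30, 0.37, 0.40))
#' @export
classify_unit <- function(trough_to_peak_ms) {
  if (any(trough_to_peak_ms <= 0)) stop_config("latencies must be positive")
  ifelse(trough_to_peak_ms < 0.36, "FS",
         ifelse(trough_to_peak_ms > 0.38, "RS", "excluded"))
}

#' Select steady running trials
#'
#' Keeps trials on which the animal was moving (speed at least
#' \code{min_speed}) and not accelerating or decelerating abruptly: the
#' trial's mean speed must lie within \code{sd_bound} standard deviations of
#' the animal's mean running speed (mean and SD over all its trials). With
#' zero speed variance the deviation is zero and the bound is satisfied.
#'
#' @param trial_table \code{data.frame} with a \code{mean_speed} column, cm/s.
#' @param min_speed minimum speed, cm/s (default 1).
#' @param sd_bound allowed deviation, in SDs (default 1.5).
#' @return Logical mask over trials; empty table gives an empty mask.
#' @export
select_trials <- function(trial_table, min_speed = 1, sd_bound = 1.5) {
  if (!"mean_speed" %in% names(trial_table))
    stop_config("trial table needs a mean_speed column")
  sp <- trial_table$mean_speed
  if (!length(sp)) return(logical())
  if (any(!is.finite(sp))) stop_config("speeds must be finite")
  mu <- mean(sp)
  s <- sd(sp)
  if (!is.finite(s)) s <- 0
  sp >= min_speed & abs(sp - mu) <= sd_bound * s
}

#' Windowed per-trial firing rate
#'
#' Counts spikes in the analysis window of each trial — by default 750 ms
#' starting 500 ms after motor onset, coinciding with the LED period on
#' light trials — and converts to Hz. The window is half-open: a spike at
#' the exact window end is not counted.
#'
#' @param spike_times_s sorted unit spike times, s.
#' @param t_motor_onset_s motor-onset time(s), s (vectorized).
#' @param window_start_s,window_len_s window offset and length, s.
#' @return Firing rate(s) in Hz, one per onset.
#' @export
trial_rate <- function(spike_times_s, t_motor_onset_s, window_start_s = 0.5,
                       window_len_s = 0.75) {
  trial_count(spike_times_s, t_motor_onset_s, window_start_s, window_len_s) /
    window_len_s
}

#' @rdname trial_rate
#' @export
trial_count <- function(spike_times_s, t_motor_onset_s, window_start_s = 0.5,
                        window_len_s = 0.75) {
  st <- sort(spike_times_s)
  lo <- t_motor_onset_s + window_start_s
  hi <- lo + window_len_s
  findInterval(hi, st, left.open = TRUE) - findInterval(lo, st, left.open = TRUE)
}

#' Per-unit optogenetic modulation test
#'
#' Poisson regression of per-trial spike counts on the light indicator with
#' the window length as exposure: \code{count ~ light + offset(log(exposure))}.
#' The effect is the multiplicative rate change under light,
#' \code{exp(coefficient)}. The default test of the light coefficient is the
#' likelihood-ratio test of the Poisson model; \code{method = "ftest"} uses
#' the quasi-Poisson F-test instead (robust to overdispersion).
#'
#' @param counts per-trial spike counts in the analysis window.
#' @param light per-trial 0/1 light flags; both conditions must be present.
#' @param exposure_s window length, s (default 0.75).
#' @param method \code{"lrt"} or \code{"ftest"}.
#' @return List: \code{effect} (rate ratio light/control), \code{p},
#'   \code{rate_control_hz}, \code{rate_light_hz}. All-zero counts give NA
#'   effect and p (degenerate model), flagged.
#' @export
modulation_test <- function(counts, light, exposure_s = 0.75,
                            method = c("lrt", "ftest")) {
  method <- match.arg(method)
  if (length(counts) != length(light)) stop_config("counts/light length mismatch")
  light <- as.integer(light)
  if (length(unique(light)) < 2L)
    stop_config("both light conditions must be present")
  out <- list(rate_control_hz = mean(counts[light == 0L]) / exposure_s,
              rate_light_hz = mean(counts[light == 1L]) / exposure_s)
  if (all(counts == 0)) {
    out$effect <- NA_real_
    out$p <- NA_real_
    out$flagged <- TRUE
    return(out)
  }
  off <- rep(log(exposure_s), length(counts))
  if (method == "lrt") {
    fit <- glm(counts ~ light + offset(off), family = poisson())
    fit0 <- glm(counts ~ 1 + offset(off), family = poisson())
    out$p <- as.numeric(pchisq(fit0$deviance - fit$deviance, df = 1,
                               lower.tail = FALSE))
  } else {
    fit <- glm(counts ~ light + offset(off), family = stats::quasipoisson())
    out$p <- anova(fit, test = "F")["light", "Pr(>F)"]
  }
  out$effect <- unname(exp(coef(fit)["light"]))
  out$flagged <- FALSE
  out
}

#' Run the full modulation analysis for one unit
#'
#' Applies trial selection, computes windowed counts, and runs the
#' modulation test; also reports the unit's waveform class and inclusion
#' flag.
#'
#' @param unit a \code{"unit_recording"} (see
#'   \code{\link{simulate_invivo_units}}).
#' @param window_start_s,window_len_s analysis window.
#' @param method test method, see \code{\link{modulation_test}}.
#' @param burst_override keep the unit despite refractory violations.
#' @return One-row \code{data.frame}: unit id, class, inclusion, control and
#'   light rates, effect, p.
#' @export
unit_modulation <- function(unit, window_start_s = 0.5, window_len_s = 0.75,
                            method = "lrt", burst_override = FALSE) {
  keep <- select_trials(unit$trial_table)
  tt <- unit$trial_table[keep, , drop = FALSE]
  res <- data.frame(unit_id = unit$unit_id,
                    class = classify_unit(unit$trough_to_peak),
                    included = unit_inclusion(unit$spike_times,
                                              burst_override = burst_override),
                    n_trials = nrow(tt), rate_control_hz = NA_real_,
                    rate_light_hz = NA_real_, effect = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(tt) && length(unique(tt$light)) == 2L) {
    counts <- trial_count(unit$spike_times, tt$t_motor_onset,
                          window_start_s, window_len_s)
    m <- modulation_test(counts, tt$light, exposure_s = window_len_s,
                         method = method)
    res$rate_control_hz <- m$rate_control_hz
    res$rate_light_hz <- m$rate_light_hz
    res$effect <- m$effect
    res$p <- m$p
  }
  res
}

#' Causal alpha kernel
#'
#' \code{a(t) = (t / tau^2) exp(-t / tau)} for t >= 0, discretized at
#' \code{dt_ms} and normalized to unit integral so convolution conserves
#' rate on constant input.
#'
#' @param tau_ms kernel time constant, ms (default 100).
#' @param dt_ms sample interval, ms.
#' @param length_tau kernel support in multiples of tau.
#' @return Numeric vector of kernel weights summing to \code{1 / dt_ms}.
#' @export
alpha_kernel <- function(tau_ms = 100, dt_ms = 1, length_tau = 8) {
  check_number(tau_ms, "tau_ms", lower = 1e-9)
  tt <- seq(0, length_tau * tau_ms, by = dt_ms)
  k <- (tt / tau_ms^2) * exp(-tt / tau_ms)
  k / (sum(k) * dt_ms)
}

#' Trial-averaged z-scored PSTH
#'
#' Builds the peristimulus time histogram of a unit over aligned trials,
#' smooths it with a causal alpha kernel (default 100 ms), downsamples to
#' \code{out_rate_hz} (default 50 Hz, block averaging), and z-scores the
#' result against the pre-stimulus baseline (default the second preceding
#' alignment, i.e. t in [-1, 0)).
#'
#' @param spike_times_s unit spike times, s.
#' @param align_times_s per-trial alignment (e.g. motor-onset) times, s.
#' @param pre_s,post_s window before/after alignment, s.
#' @param kernel_tau_ms alpha-kernel time constant, ms.
#' @param out_rate_hz output sample rate, Hz.
#' @param baseline_s baseline window relative to alignment, s (two values).
#' @return \code{data.frame} with \code{t_s} (window centre relative to
#'   alignment), \code{rate_hz} (smoothed trial-averaged rate) and \code{z};
#'   z is NA (flagged by attribute) when baseline variance is zero.
#' @export
zscore_psth <- function(spike_times_s, align_times_s, pre_s = 1, post_s = 2.5,
                        kernel_tau_ms = 100, out_rate_hz = 50,
                        baseline_s = c(-1, 0)) {
  if (!length(align_times_s)) stop_config("at least one trial is required")
  dt_ms <- 1
  edges <- seq(-pre_s * 1000, post_s * 1000, by = dt_ms)
  mids <- head(edges, -1) + dt_ms / 2
  counts <- numeric(length(mids))
  for (a in align_times_s) {
    rel <- (spike_times_s - a) * 1000
    rel <- rel[rel >= edges[1] & rel < edges[length(edges)]]
    if (length(rel))
      counts <- counts + tabulate(floor((rel - edges[1]) / dt_ms) + 1L,
                                  nbins = length(mids))
  }
  rate <- counts / length(align_times_s) / (dt_ms / 1000)   # Hz
  # causal smoothing: sample i gets sum_j w[j] rate[i-j+1], weights sum to 1
  w <- alpha_kernel(kernel_tau_ms, dt_ms) * dt_ms
  p <- length(w)
  padded <- c(numeric(p - 1L), rate)
  sm <- as.numeric(stats::filter(padded, w, method = "convolution", sides = 1))
  sm <- sm[p:(p - 1L + length(rate))]
  block <- round(1000 / out_rate_hz / dt_ms)
  n_out <- floor(length(sm) / block)
  idx <- rep(seq_len(n_out), each = block)
  rate_out <- as.numeric(tapply(sm[seq_len(n_out * block)], idx, mean))
  t_out <- as.numeric(tapply(mids[seq_len(n_out * block)], idx, mean)) / 1000
  base <- t_out >= baseline_s[1] & t_out < baseline_s[2]
  mu <- mean(rate_out[base])
  s <- sd(rate_out[base])
  out <- data.frame(t_s = t_out, rate_hz = rate_out)
  if (!is.finite(s) || s == 0) {
    out$z <- NA_real_
    attr(out, "flagged") <- TRUE
  } else {
    out$z <- (rate_out - mu) / s
  }
  out
}
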