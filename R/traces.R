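# Continuous-trace utilities: baseline detrending, charge integration, and a
# deterministic matched-filter event detector standing in for Bayesian
# posterior event inference (downstream statistics are detector-agnostic:
# they consume event times only).

#' Construct a uniformly sampled trace
#'
#' @param y signal samples (pA for currents, mV for voltages).
#' @param rate_khz sampling rate in kHz (samples per ms); recordings are
#'   typically digitized at 20 kHz.
#' @param t0_ms time of the first sample, ms.
#' @return Object of class \code{"trace"} with fields \code{t}, \code{y},
#'   \code{rate}.
#' @export
trace <- function(y, rate_khz = 20, t0_ms = 0) {
  check_number(rate_khz, "rate_khz", lower = 1e-9)
  if (any(!is.finite(y))) stop_config("trace values must be finite")
  structure(list(t = t0_ms + (seq_along(y) - 1) / rate_khz,
                 y = as.numeric(y), rate = rate_khz),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("Trace: %d samples at %g kHz (%.1f ms)\n",
              length(x$y), x$rate, length(x$y) / x$rate))
  invisible(x)
}

#' Remove baseline offset and slow drift from a trace
#'
#' Subtracts a down-sampled and median-filtered version of the recording from
#' itself: the trace is decimated by \code{downsample_factor}, median-filtered
#' with a running window of \code{median_window_ms}, linearly interpolated
#' back onto the original time base, and subtracted. Fast transients (synaptic
#' events) pass through nearly unchanged; offsets and slow fluctuations are
#' removed.
#'
#' @param raw a \code{\link{trace}}.
#' @param downsample_factor decimation factor (default 100).
#' @param median_window_ms running-median window in ms (default 200); must
#'   span at least 3 downsampled samples.
#' @return A \code{\link{trace}} with the same length and time base.
#' @export
preprocess_trace <- function(raw, downsample_factor = 100, median_window_ms = 200) {
  if (!inherits(raw, "trace")) stop_config("'raw' must be a trace")
  downsample_factor <- check_count(downsample_factor, "downsample_factor", min = 1L)
  check_number(median_window_ms, "median_window_ms", lower = 1e-9)
  idx <- seq(1L, length(raw$y), by = downsample_factor)
  k <- round(median_window_ms * raw$rate / downsample_factor)
  if (k < 3) stop_config("median window must span at least 3 downsampled samples")
  if (k %% 2 == 0) k <- k + 1
  ds <- raw$y[idx]
  if (length(ds) < 3L) stop_config("trace too short for the requested downsampling")
  k <- min(k, if (length(ds) %% 2) length(ds) else length(ds) - 1L)
  med <- stats::runmed(ds, k, endrule = "median")
  baseline <- approx(raw$t[idx], med, xout = raw$t, rule = 2)$y
  out <- raw
  out$y <- raw$y - baseline
  out
}

#' Charge transfer during and after a stimulus
#'
#' Trapezoidal integral of the (preprocessed) current over the window from
#' stimulus onset to stimulus offset plus 25 ms. The sign convention is
#' selected by \code{polarity}: \code{"positive"} for outward/upward
#' deflections (IPSCs at depolarized holding potentials), \code{"negative"}
#' for inward currents (EPSCs at -70 mV), so that reported charge from a
#' genuine response is non-negative. The integral is linear in the trace.
#'
#' @param x a \code{\link{trace}} holding current in pA.
#' @param stim_onset_ms,stim_duration_ms stimulus onset and duration, ms.
#' @param tail_ms integration continues this long past stimulus offset
#'   (default 25 ms).
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @return Charge in pC (pA * ms / 1000).
#' @examples
#' tr <- trace(rep(0, 2000), rate_khz = 20)
#' charge_transfer(tr, 10, 10)  # 0
#' @export
charge_transfer <- function(x, stim_onset_ms, stim_duration_ms, tail_ms = 25,
                            polarity = c("positive", "negative")) {
  if (!inherits(x, "trace")) stop_config("'x' must be a trace")
  polarity <- match.arg(polarity)
  from <- stim_onset_ms
  to <- stim_onset_ms + stim_duration_ms + tail_ms
  if (from < x$t[1] || to > x$t[length(x$t)] + 1 / x$rate)
    stop_config("integration window [%g, %g) lies outside the trace", from, to)
  keep <- x$t >= from & x$t < to
  tt <- x$t[keep]
  yy <- x$y[keep]
  if (length(tt) < 2L) return(0)
  s <- if (polarity == "positive") 1 else -1
  q_pa_ms <- sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
  s * q_pa_ms / 1000
}

# bi-exponential synaptic template, unit peak, starting at its onset
event_template <- function(tau_rise, tau_decay, rate_khz, length_ms = NULL) {
  if (tau_rise >= tau_decay) stop_config("template rise time must be below decay time")
  if (is.null(length_ms)) length_ms <- 5 * tau_decay
  tt <- seq(0, length_ms, by = 1 / rate_khz)
  w <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  w / max(w)
}

#' Detect synaptic events by matched filtering
#'
#' Correlates a preprocessed current trace with a bi-exponential synaptic
#' template and estimates the noise level of the filtered signal robustly
#' (median absolute deviation scaled by 1.4826). Events are then extracted
#' greedily (matching pursuit): the strongest correlation peak above
#' \code{threshold_sd} noise SDs is accepted, the fitted template is
#' subtracted from the correlation signal so that secondary maxima on its
#' shoulders cannot fire, and the search repeats; a minimum inter-event
#' separation of \code{min_separation_ms} is enforced. The reported onset is
#' the template onset of the accepted fit.
#'
#' This detector deliberately replaces posterior-sampling event inference:
#' all downstream statistics consume event times and are agnostic to how they
#' were estimated.
#'
#' @param x a preprocessed \code{\link{trace}} (events as positive
#'   deflections; flip the sign for inward currents).
#' @param template_tau_rise,template_tau_decay template time constants, ms
#'   (rise < decay).
#' @param threshold_sd detection threshold in robust noise SDs (default 4).
#' @param min_separation_ms minimum separation between reported events
#'   (default 2 ms).
#' @return List of class \code{"detected_events"} with sorted \code{onsets}
#'   (ms) and matched-filter \code{scores}.
#' @export
detect_events <- function(x, template_tau_rise = 0.5, template_tau_decay = 4,
                          threshold_sd = 4, min_separation_ms = 2) {
  if (!inherits(x, "trace")) stop_config("'x' must be a trace")
  check_number(threshold_sd, "threshold_sd", lower = 0)
  w <- event_template(template_tau_rise, template_tau_decay, x$rate)
  nw <- length(w)
  n <- length(x$y)
  if (n < nw) stop_config("trace shorter than the template")
  # correlation score for template onset at each sample:
  # cc[i] = sum_j w[j] * y[i + j - 1]
  filt <- stats::filter(c(x$y, rep(0, nw - 1)), rev(w), method = "convolution",
                        sides = 1)
  cc <- as.numeric(filt[nw:n])
  noise <- mad(cc, na.rm = TRUE)
  if (!is.finite(noise) || noise == 0) noise <- sd(cc)
  thr <- threshold_sd * noise
  if (!is.finite(thr)) thr <- Inf

  # template autocorrelation, for subtracting accepted fits from the score
  ac <- vapply(-(nw - 1L):(nw - 1L), function(d) {
    j <- seq_len(nw)
    keep <- j + d >= 1L & j + d <= nw
    sum(w[j[keep]] * w[j[keep] + d])
  }, numeric(1))
  w2 <- sum(w^2)
  m <- length(cc)
  min_gap <- max(1L, round(min_separation_ms * x$rate))
  is_peak <- c(FALSE, cc[2:(m - 1)] > cc[1:(m - 2)] & cc[2:(m - 1)] >= cc[3:m], FALSE)
  cand <- which(is_peak & cc > thr)
  kept <- integer()
  amps <- numeric()
  scores <- numeric()
  for (i in cand[order(cc[cand], decreasing = TRUE)]) {
    if (length(kept) && any(abs(kept - i) < min_gap)) next
    near <- which(abs(kept - i) < nw)
    adj <- cc[i] - sum(amps[near] * ac[i - kept[near] + nw])
    if (adj <= thr) next
    kept <- c(kept, i)
    amps <- c(amps, adj / w2)
    scores <- c(scores, adj)
  }
  o <- order(kept)
  structure(list(onsets = x$t[kept[o]], scores = scores[o]),
            class = "detected_events")
}

#' @export
print.detected_events <- function(x, ...) {
  cat(sprintf("Detected events: %d onsets\n", length(x$onsets)))
  invisible(x)
}
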