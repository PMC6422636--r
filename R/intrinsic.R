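# Intrinsic electrophysiology: spike detection in current-clamp sweeps via
# the phase-space (dV/dt vs V) maximum-slope criterion, spike width at half
# height, passive properties, rheobase estimation, the adaptation index, and
# the two-feature maximum-margin subtype classifier.

#' Detect action potentials and their onsets in a voltage trace
#'
#' Spikes are first segmented by an upward crossing of a dV/dt pre-detector
#' threshold; within each segment the onset is the point of maximum positive
#' slope in the phase space of the membrane potential and its first
#' derivative, i.e. the sample maximizing d(dV/dt)/dV along the trajectory.
#' The action-potential threshold is the voltage at that point. Derivatives
#' are computed on a lightly smoothed copy of the trace (default 3-sample
#' boxcar) to tame discretization noise.
#'
#' @param x a \code{\link{trace}} of membrane potential (mV).
#' @param dvdt_thresh_mv_ms pre-detector threshold on dV/dt (default
#'   20 mV/ms, above passive charging slopes but well below any upstroke).
#' @param smooth_samples boxcar width for the smoothed derivative (odd).
#' @param lookback_ms how far before the pre-detector crossing the onset is
#'   searched (default 2 ms).
#' @param min_dv_mv phase-space slope is evaluated only over voltage
#'   increments exceeding this (default 0.25 mV), taming discretization
#'   noise where the trajectory is nearly flat.
#' @return \code{data.frame} with one row per spike: \code{t_onset},
#'   \code{v_thresh}, \code{t_peak}, \code{v_peak}. A subthreshold trace
#'   yields zero rows (not an error).
#' @export
detect_spike_onsets <- function(x, dvdt_thresh_mv_ms = 20, smooth_samples = 3,
                                lookback_ms = 2, min_dv_mv = 0.25) {
  if (!inherits(x, "trace")) stop_config("'x' must be a trace")
  n <- length(x$y)
  empty <- data.frame(t_onset = numeric(), v_thresh = numeric(),
                      t_peak = numeric(), v_peak = numeric())
  if (n < 5L) return(empty)
  v <- x$y
  if (smooth_samples > 1L) {
    k <- rep(1 / smooth_samples, smooth_samples)
    vs <- as.numeric(stats::filter(v, k, sides = 2))
    vs[is.na(vs)] <- v[is.na(vs)]
  } else vs <- v
  # central-difference dV/dt, mV/ms
  g <- c(0, (vs[-(1:2)] - vs[seq_len(n - 2L)]) / 2, 0) * x$rate

  up <- which(g[-1] > dvdt_thresh_mv_ms & g[-n] <= dvdt_thresh_mv_ms) + 1L
  if (!length(up)) return(empty)

  look <- round(lookback_ms * x$rate)
  out <- empty
  prev_end <- 0L
  for (c0 in up) {
    if (c0 <= prev_end) next              # still inside the previous spike
    # peak: first local max of v after the crossing
    i <- c0
    while (i < n && vs[i + 1L] >= vs[i]) i <- i + 1L
    peak <- i
    lo <- max(prev_end + 1L, c0 - look)
    hi <- max(peak - 1L, lo)
    seg <- lo:hi
    dv <- vs[pmin(seg + 1L, n)] - vs[seg]
    dg <- g[pmin(seg + 1L, n)] - g[seg]
    ratio <- ifelse(dv > min_dv_mv, dg / dv, -Inf)
    if (all(!is.finite(ratio))) next
    onset <- seg[which.max(ratio)]
    out <- rbind(out, data.frame(t_onset = x$t[onset], v_thresh = v[onset],
                                 t_peak = x$t[peak], v_peak = v[peak]))
    prev_end <- peak
  }
  rownames(out) <- NULL
  out
}

#' Spike full width at half height
#'
#' Width of a spike at the voltage halfway between its action-potential
#' threshold and its peak: time between the up- and down-crossings of
#' \code{(v_thresh + v_peak) / 2}, linearly interpolated between samples.
#'
#' @param x a \code{\link{trace}}.
#' @param onset one row of \code{\link{detect_spike_onsets}} output.
#' @param t_limit_ms optional time before which the down-crossing must occur
#'   (e.g. the next spike's onset); default end of trace.
#' @return Width in ms, or NA when no down-crossing is found before
#'   \code{t_limit_ms}.
#' @export
spike_width <- function(x, onset, t_limit_ms = NULL) {
  if (!inherits(x, "trace")) stop_config("'x' must be a trace")
  v_half <- (onset$v_thresh + onset$v_peak) / 2
  if (is.null(t_limit_ms)) t_limit_ms <- x$t[length(x$t)]
  i_on <- which.min(abs(x$t - onset$t_onset))
  i_pk <- which.min(abs(x$t - onset$t_peak))
  if (i_on >= i_pk) stop_config("onset must precede peak")
  cross_time <- function(i) {
    # linear interpolation of the half-height crossing in [t_i, t_{i+1}]
    x$t[i] + (v_half - x$y[i]) / (x$y[i + 1L] - x$y[i]) * (x$t[i + 1L] - x$t[i])
  }
  seg_up <- i_on:(i_pk - 1L)
  up <- seg_up[x$y[seg_up] <= v_half & x$y[seg_up + 1L] > v_half]
  if (!length(up)) return(NA_real_)
  t_up <- cross_time(up[length(up)])
  i_max <- max(which(x$t <= t_limit_ms))
  if (i_pk >= i_max) return(NA_real_)
  seg_dn <- i_pk:(i_max - 1L)
  dn <- seg_dn[x$y[seg_dn] >= v_half & x$y[seg_dn + 1L] < v_half]
  if (!length(dn)) return(NA_real_)
  t_dn <- cross_time(dn[1L])
  t_dn - t_up
}

#' Spike-frequency adaptation index
#'
#' Normalized mean successive-ISI contrast over the spikes of one current
#' step: with inter-spike intervals s_1..s_m,
#' \code{mean((s[n+1] - s[n]) / (s[n+1] + s[n]))} over n = 1..m-1. Positive
#' for lengthening ISIs (accommodation), bounded in [-1, 1], zero for a
#' perfectly regular train.
#'
#' @param spike_times spike times of one current step, ms (>= 3 spikes).
#' @return Dimensionless index, or NA (flagged) for fewer than 3 spikes.
#' @examples
#' adaptation_index(c(0, 10, 30, 60))  # ISIs 10, 20, 30 -> 0.2667
#' @export
adaptation_index <- function(spike_times) {
  if (length(spike_times) < 3L) return(NA_real_)
  isi <- diff(sort(spike_times))
  if (any(isi <= 0)) stop_config("spike times must be strictly increasing")
  mean(diff(isi) / (isi[-1] + isi[-length(isi)]))
}

#' Passive membrane properties from a sweep set
#'
#' Resting potential is the median membrane potential over the baseline
#' window of all sweeps; input resistance is Ohm's law applied to each
#' subthreshold (spike-free, non-zero current) sweep — the steady-state
#' voltage deflection near the end of the step divided by the injected
#' current — averaged across those sweeps.
#'
#' @param sweeps a \code{\link{simulate_step_protocol}} sweep set (or a list
#'   with the same fields).
#' @param steady_frac final fraction of the step used as the steady-state
#'   window (default 0.2).
#' @return List with \code{v_rest} (mV) and \code{r_in} (MOhm; NA flagged
#'   when no subthreshold sweep exists).
#' @export
passive_properties <- function(sweeps, steady_frac = 0.2) {
  sw <- sweeps$sweeps
  if (!length(sw)) stop_config("empty sweep set")
  base_w <- sweeps$baseline_window
  step_w <- sweeps$step_window
  rate <- sweeps$rate
  base_v <- unlist(lapply(sw, function(s) s$v[s$t >= base_w[1] & s$t < base_w[2]]))
  v_rest <- median(base_v)
  steady_lo <- step_w[2] - steady_frac * diff(step_w)
  ratios <- c()
  for (s in sw) {
    if (s$i_inj == 0) next
    tr <- trace(s$v, rate_khz = rate, t0_ms = s$t[1])
    if (nrow(detect_spike_onsets(tr)) > 0L) next
    v_base <- median(s$v[s$t >= base_w[1] & s$t < base_w[2]])
    v_steady <- mean(s$v[s$t >= steady_lo & s$t < step_w[2]])
    ratios <- c(ratios, (v_steady - v_base) / s$i_inj * 1000)   # mV/pA -> MOhm
  }
  list(v_rest = v_rest, r_in = if (length(ratios)) mean(ratios) else NA_real_)
}

#' F-I curve of a sweep set
#'
#' Counts spikes within the step window of every sweep and converts to a
#' firing rate over the step duration.
#'
#' @param sweeps a sweep set (see \code{\link{passive_properties}}).
#' @return \code{data.frame} with \code{i_inj} (pA), \code{n_spikes},
#'   \code{rate_hz}, sorted by current.
#' @export
fi_curve <- function(sweeps) {
  step_w <- sweeps$step_window
  dur_s <- diff(step_w) / 1000
  rows <- lapply(sweeps$sweeps, function(s) {
    tr <- trace(s$v, rate_khz = sweeps$rate, t0_ms = s$t[1])
    on <- detect_spike_onsets(tr)
    k <- sum(on$t_onset >= step_w[1] & on$t_onset < step_w[2])
    data.frame(i_inj = s$i_inj, n_spikes = k, rate_hz = k / dur_s)
  })
  out <- do.call(rbind, rows)
  out[order(out$i_inj), , drop = FALSE]
}

# two-variable nonnegative least squares for f = slope * I - intercept,
# slope >= 0, intercept >= 0 (so the zero-rate crossing is at positive current)
nnls_fi <- function(I, f) {
  X <- cbind(I, -1)
  sse <- function(b) sum((X %*% b - f)^2)
  cands <- list()
  b_free <- tryCatch(qr.solve(X, f), error = function(e) NULL)
  if (!is.null(b_free) && all(b_free >= 0)) cands <- c(cands, list(b_free))
  b1 <- max(0, sum(I * f) / sum(I^2))          # intercept pinned at 0
  cands <- c(cands, list(c(b1, 0)))
  cands <- c(cands, list(c(0, max(0, -mean(f)))))  # slope pinned at 0
  best <- unname(cands[[which.min(vapply(cands, sse, numeric(1)))]])
  list(slope = best[1], intercept = best[2])
}

#' Estimate rheobase
#'
#' Average of two estimators: (1) the zero-frequency crossing of a
#' nonnegative-coefficient linear fit to the F-I relation over the last
#' subthreshold step and the first few suprathreshold steps, and (2) the
#' current needed to reach threshold by Ohm's law,
#' \code{(mean_thresh - v_rest) / r_in}. When the F-I fit is degenerate
#' (zero slope) the Ohm's-law estimate is returned alone, flagged.
#'
#' @param fi \code{data.frame} from \code{\link{fi_curve}}.
#' @param v_rest,r_in passive properties (mV, MOhm).
#' @param mean_thresh mean action-potential threshold, mV.
#' @param k_supra number of suprathreshold F-I points used (default 3).
#' @return List: \code{rheobase_pa}, \code{est_fi_pa}, \code{est_ohm_pa},
#'   \code{flagged}.
#' @export
estimate_rheobase <- function(fi, v_rest, r_in, mean_thresh, k_supra = 3) {
  est_ohm <- (mean_thresh - v_rest) / r_in * 1000    # mV / MOhm -> pA
  supra <- fi[fi$n_spikes > 0 & fi$i_inj > 0, , drop = FALSE]
  if (nrow(supra) == 0L)
    return(list(rheobase_pa = est_ohm, est_fi_pa = NA_real_,
                est_ohm_pa = est_ohm, flagged = TRUE))
  first_supra <- min(supra$i_inj)
  sub <- fi[fi$n_spikes == 0 & fi$i_inj > 0 & fi$i_inj < first_supra, , drop = FALSE]
  pts <- rbind(if (nrow(sub)) sub[which.max(sub$i_inj), ] else NULL,
               head(supra[order(supra$i_inj), ], k_supra))
  fit <- nnls_fi(pts$i_inj, pts$rate_hz)
  if (fit$slope <= 0)
    return(list(rheobase_pa = est_ohm, est_fi_pa = NA_real_,
                est_ohm_pa = est_ohm, flagged = TRUE))
  est_fi <- fit$intercept / fit$slope
  list(rheobase_pa = (est_fi + est_ohm) / 2, est_fi_pa = est_fi,
       est_ohm_pa = est_ohm, flagged = FALSE)
}

#' Extract the full intrinsic-feature set from a sweep set
#'
#' Runs spike detection over every sweep and assembles the per-cell feature
#' set: resting potential, input resistance, mean action-potential threshold
#' (first spike of each suprathreshold step), median spike width at half
#' height, rheobase, adaptation index (median over steps with at least three
#' spikes), and the F-I curve.
#'
#' @param sweeps a sweep set.
#' @param k_supra suprathreshold points for the rheobase fit.
#' @return List of class \code{"feature_set"}.
#' @export
extract_features <- function(sweeps, k_supra = 3) {
  pp <- passive_properties(sweeps)
  step_w <- sweeps$step_window
  widths <- c(); threshs <- c(); adapt <- c()
  fi_rows <- list()
  dur_s <- diff(step_w) / 1000
  for (s in sweeps$sweeps) {
    tr <- trace(s$v, rate_khz = sweeps$rate, t0_ms = s$t[1])
    on <- detect_spike_onsets(tr)
    on <- on[on$t_onset >= step_w[1] & on$t_onset < step_w[2], , drop = FALSE]
    k <- nrow(on)
    fi_rows[[length(fi_rows) + 1L]] <-
      data.frame(i_inj = s$i_inj, n_spikes = k, rate_hz = k / dur_s)
    if (k > 0L && s$i_inj > 0) {
      threshs <- c(threshs, on$v_thresh[1])
      lim <- c(on$t_onset[-1], step_w[2])
      for (j in seq_len(k))
        widths <- c(widths, spike_width(tr, on[j, ], t_limit_ms = lim[j]))
      if (k >= 3L) adapt <- c(adapt, adaptation_index(on$t_onset))
    }
  }
  fi <- do.call(rbind, fi_rows)
  fi <- fi[order(fi$i_inj), , drop = FALSE]
  mean_thresh <- if (length(threshs)) mean(threshs) else NA_real_
  rheo <- if (is.finite(mean_thresh) && is.finite(pp$r_in))
    estimate_rheobase(fi, pp$v_rest, pp$r_in, mean_thresh, k_supra)
  else list(rheobase_pa = NA_real_, flagged = TRUE)
  structure(list(v_rest = pp$v_rest, r_in = pp$r_in,
                 v_thresh = mean_thresh,
                 spike_width = if (length(widths)) median(widths, na.rm = TRUE)
                 else NA_real_,
                 rheobase = rheo$rheobase_pa,
                 adaptation_index = if (length(adapt)) median(adapt, na.rm = TRUE)
                 else NA_real_,
                 fi_curve = fi, rheobase_detail = rheo),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(paste0("Intrinsic features: Vrest %.1f mV, Rin %.0f MOhm, ",
                     "thresh %.1f mV,\n  width %.2f ms, rheobase %.0f pA, ",
                     "adaptation %.3f\n"),
              x$v_rest, x$r_in, x$v_thresh, x$spike_width, x$rheobase,
              x$adaptation_index))
  invisible(x)
}

# full-batch subgradient descent on the L2-regularized hinge loss
# (Pegasos-style schedule); deterministic given the data
svm_fit <- function(X, y, lambda = 0.01, iters = 2000) {
  n <- nrow(X)
  w <- rep(0, ncol(X))
  b <- 0
  for (t in seq_len(iters)) {
    eta <- 1 / (lambda * t)
    margin <- y * (X %*% w + b)
    viol <- margin < 1
    gw <- lambda * w - colSums(X[viol, , drop = FALSE] * y[viol]) / n
    gb <- -sum(y[viol]) / n
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b)
}

#' Classify cell subtype from spike width and rheobase
#'
#' Fits a maximum-margin linear classifier (soft-margin SVM on standardized
#' features, trained by full-batch subgradient descent on the regularized
#' hinge loss) separating two cell classes — e.g. Martinotti (broad spike,
#' low rheobase) from non-Martinotti (narrow spike, high rheobase)
#' somatostatin cells — and reports stratified k-fold cross-validated
#' accuracy. The fitted model predicts labels for unlabeled cells via
#' \code{predict}.
#'
#' @param features \code{data.frame} (or matrix) of numeric features, one row
#'   per cell; typically columns \code{spike_width} and \code{rheobase}.
#' @param labels factor (or vector) of two class labels, one per cell.
#' @param folds number of CV folds (default 10; requires n >= folds).
#' @param seed integer seed controlling fold assignment.
#' @param lambda regularization strength (fixed, never tuned on test folds).
#' @param iters optimization iterations.
#' @return Object of class \code{"subtype_classifier"}: \code{cv_accuracy},
#'   \code{levels}, fitted weights and standardization constants.
#' @export
classify_subtype <- function(features, labels, folds = 10, seed = NULL,
                             lambda = 0.01, iters = 2000) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop_config("features must be numeric")
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop_config("exactly two classes are required (got %d)", nlevels(labels))
  n <- nrow(X)
  folds <- check_count(folds, "folds", min = 2L)
  if (n < folds) stop_config("need at least as many cells as folds")
  if (min(table(labels)) < 2L) stop_config("each class needs >= 2 cells")
  seed_rng(seed)
  y <- ifelse(labels == levels(labels)[2L], 1, -1)

  # stratified fold assignment
  fold_id <- integer(n)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }

  standardize <- function(X, center, scale) sweep(sweep(X, 2, center), 2, scale, "/")
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L) next
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, sd)
    scl[scl == 0] <- 1
    m <- svm_fit(standardize(X[tr, , drop = FALSE], ctr, scl), y[tr],
                 lambda, iters)
    pred <- sign(standardize(X[!tr, , drop = FALSE], ctr, scl) %*% m$w + m$b)
    pred[pred == 0] <- 1
    correct <- correct + sum(pred == y[!tr])
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  m <- svm_fit(standardize(X, ctr, scl), y, lambda, iters)
  structure(list(w = m$w, b = m$b, center = ctr, scale = scl,
                 levels = levels(labels), cv_accuracy = correct / n,
                 folds = folds, lambda = lambda, seed = seed),
            class = "subtype_classifier")
}

#' @export
predict.subtype_classifier <- function(object, newdata, ...) {
  X <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  s <- as.numeric(X %*% object$w + object$b)
  factor(object$levels[ifelse(s >= 0, 2L, 1L)], levels = object$levels)
}

#' @export
print.subtype_classifier <- function(x, ...) {
  cat(sprintf("Linear subtype classifier (%s vs %s): %d-fold CV accuracy %.3f\n",
              x$levels[1], x$levels[2], x$folds, x$cv_accuracy))
  invisible(x)
}
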