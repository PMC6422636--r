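# Fine-timescale common-input (synchrony) testing: do IPSCs evoked in two
# simultaneously recorded cells at one stimulation site arise from a single
# presynaptic neuron diverging onto both, or from two neighbouring neurons
# co-activated on the same trials? The null preserves all structure coarser
# than a chosen timescale (interval-jitter resampling) so that only
# synchrony finer than that timescale rejects it.

#' Bin event times into a binary trial-by-bin train
#'
#' Bins per-trial event times at \code{bin_ms} resolution (default 1 ms,
#' half-open bins): bin \code{[b, b+1)} of a trial is 1 iff at least one
#' event falls inside it; multiple events in a bin collapse to 1.
#'
#' @param events event table (\code{trial}, \code{t_ms}) for one cell; a
#'   \code{cell_id} column, if present, must contain a single value.
#' @param trial_window_ms trial length, ms; \code{bin_ms} must divide it and
#'   every event must lie in \code{[0, trial_window_ms)}.
#' @param bin_ms bin width, ms.
#' @param trials integer vector fixing the trial set (and row order); defaults
#'   to the trials present in \code{events}. Pass the full session trial set
#'   so that two simultaneously recorded cells share the same rows.
#' @return Object of class \code{"binned_train"}: list of sorted 0-based
#'   occupied-bin vectors per trial, plus shape metadata.
#' @export
bin_events <- function(events, trial_window_ms, bin_ms = 1, trials = NULL) {
  if (!all(c("trial", "t_ms") %in% names(events)))
    stop_config("event table must have columns trial, t_ms")
  if ("cell_id" %in% names(events) && nrow(events) &&
      length(unique(events$cell_id)) > 1L)
    stop_config("bin_events expects events from a single cell")
  check_number(trial_window_ms, "trial_window_ms", lower = 1e-9)
  check_number(bin_ms, "bin_ms", lower = 1e-9)
  n_bins <- trial_window_ms / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop_config("bin width must divide the trial window")
  n_bins <- as.integer(round(n_bins))
  if (nrow(events) && any(events$t_ms < 0 | events$t_ms >= trial_window_ms))
    stop_config("events outside [0, trial window)")
  if (is.null(trials)) trials <- sort(unique(events$trial))
  trials <- as.integer(trials)
  bins <- lapply(trials, function(tr) {
    tt <- events$t_ms[events$trial == tr]
    sort(unique(as.integer(floor(tt / bin_ms))))
  })
  structure(list(bins = bins, trials = trials, n_trials = length(trials),
                 n_bins = n_bins, bin_ms = bin_ms),
            class = "binned_train")
}

#' @export
as.matrix.binned_train <- function(x, ...) {
  m <- matrix(0L, x$n_trials, x$n_bins)
  for (i in seq_len(x$n_trials)) m[i, x$bins[[i]] + 1L] <- 1L
  rownames(m) <- x$trials
  m
}

#' @export
print.binned_train <- function(x, ...) {
  cat(sprintf("Binned train: %d trials x %d bins of %g ms, %d occupied bins\n",
              x$n_trials, x$n_bins, x$bin_ms, sum(lengths(x$bins))))
  invisible(x)
}

#' Paired-cell synchrony statistic
#'
#' The sum of the centre and the two flanking bins of the cross-correlation
#' of the two binary event trains, accumulated across trials: the number of
#' (occupied bin in A, occupied bin in B) pairs within +/- 1 bin of each
#' other in the same trial. Symmetric in its arguments.
#'
#' @param a,b \code{\link{bin_events}} objects of identical shape.
#' @return Non-negative integer count.
#' @export
synchrony_statistic <- function(a, b) {
  if (!inherits(a, "binned_train") || !inherits(b, "binned_train"))
    stop_config("arguments must be binned_train objects")
  if (a$n_trials != b$n_trials || a$n_bins != b$n_bins)
    stop_config("trains must have the same shape")
  stat <- 0L
  for (i in seq_len(a$n_trials)) {
    ba <- a$bins[[i]]
    bb <- b$bins[[i]]
    if (length(ba) && length(bb))
      stat <- stat + sum(abs(outer(ba, bb, "-")) <= 1L)
  }
  stat
}

#' Interval-jitter null distribution of the synchrony statistic
#'
#' Builds the null in which all synchrony is the product of processes at
#' timescales coarser than \code{delta_ms}: each trial's time axis is
#' partitioned into fixed, contiguous \code{delta_ms}-wide windows (anchored
#' at time 0, i.e. stimulus onset), and every event is re-placed uniformly at
#' random among the bins of its own window, independently per event, per
#' trial and per cell. Per-window event counts are conserved exactly by
#' construction. The synchrony statistic is recomputed for each resample.
#'
#' @param a,b \code{\link{bin_events}} objects of identical shape.
#' @param delta_ms null timescale, ms; must be a multiple of the bin width
#'   and span at least 2 bins. Default 10 ms, matched to the spread of
#'   evoked-event latencies.
#' @param n_resamples number of resamples (>= 100; default 1999, making the
#'   smallest attainable p-value 1/2000 = 0.0005).
#' @param seed integer seed; the null is deterministic given the seed.
#' @param jitter \code{"both"} (symmetric null, default) or \code{"b_only"}.
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference
#'   implementation, for cross-checking).
#' @return Integer vector of \code{n_resamples} null statistics.
#' @export
jitter_null <- function(a, b, delta_ms = 10, n_resamples = 1999, seed = NULL,
                        jitter = c("both", "b_only"), engine = c("cpp", "r")) {
  jitter <- match.arg(jitter)
  engine <- match.arg(engine)
  if (!inherits(a, "binned_train") || !inherits(b, "binned_train"))
    stop_config("arguments must be binned_train objects")
  if (a$n_trials != b$n_trials || a$n_bins != b$n_bins)
    stop_config("trains must have the same shape")
  n_resamples <- check_count(n_resamples, "n_resamples", min = 100L)
  delta_bins <- delta_ms / a$bin_ms
  if (abs(delta_bins - round(delta_bins)) > 1e-9)
    stop_config("delta must be a multiple of the bin width")
  delta_bins <- as.integer(round(delta_bins))
  if (delta_bins < 2L) stop_config("delta must span at least 2 bins")
  seed_rng(seed)

  flat <- function(x) {
    k <- lengths(x$bins)
    list(bins = as.integer(unlist(x$bins, use.names = FALSE)),
         trials = rep(seq_len(x$n_trials) - 1L, k))
  }
  fa <- flat(a)
  fb <- flat(b)
  if (engine == "cpp") {
    .jitter_null_stats(fa$bins, fa$trials, fb$bins, fb$trials,
                       a$n_trials, a$n_bins, delta_bins, n_resamples,
                       jitter != "b_only", TRUE)
  } else {
    jit <- function(bins) {
      w0 <- (bins %/% delta_bins) * delta_bins
      wlen <- pmin(delta_bins, a$n_bins - w0)
      w0 + floor(runif(length(bins)) * wlen)
    }
    rebuild <- function(f, bins, n_trials) {
      out <- rep(list(integer()), n_trials)
      if (length(bins)) {
        sp <- split(as.integer(bins), f$trials)
        for (nm in names(sp)) out[[as.integer(nm) + 1L]] <- sort(unique(sp[[nm]]))
      }
      out
    }
    vapply(seq_len(n_resamples), function(r) {
      ba <- if (jitter == "b_only") fa$bins else jit(fa$bins)
      bb <- jit(fb$bins)
      aa <- a; aa$bins <- rebuild(fa, ba, a$n_trials)
      bbn <- b; bbn$bins <- rebuild(fb, bb, b$n_trials)
      as.integer(synchrony_statistic(aa, bbn))
    }, integer(1))
  }
}

#' One-tailed Monte Carlo p-value against a resampled null
#'
#' \code{p = (1 + #\{null >= observed\}) / (1 + n_resamples)}; with 1999
#' resamples the smallest attainable p-value is 0.0005.
#'
#' @param observed observed synchrony statistic.
#' @param null_samples vector of null statistics from \code{\link{jitter_null}}.
#' @return p-value in (0, 1].
#' @export
common_input_pvalue <- function(observed, null_samples) {
  if (!length(null_samples)) stop_config("null sample vector is empty")
  (1 + sum(null_samples >= observed)) / (1 + length(null_samples))
}

#' Synchrony test at one stimulation site for a recorded pair
#'
#' Convenience wrapper running the full per-site synchrony test: bins the two
#' cells' events over the trials of one site, computes the observed synchrony
#' statistic, the interval-jitter null, and the Monte Carlo p-value.
#'
#' @param events event table containing both cells.
#' @param cell_a,cell_b cell identifiers.
#' @param session a \code{\link{make_session}} object.
#' @param site grid site index.
#' @param delta_ms,n_resamples,seed passed to \code{\link{jitter_null}}.
#' @param bin_ms bin width (default 1 ms).
#' @return List of class \code{"synchrony_result"}: \code{site},
#'   \code{statistic}, \code{null_samples}, \code{p_value}.
#' @export
site_synchrony <- function(events, cell_a, cell_b, session, site, delta_ms = 10,
                           n_resamples = 1999, seed = NULL, bin_ms = 1) {
  trials <- which(session$trial_order == site)
  if (!length(trials)) stop_config("site %s has no trials", site)
  win <- floor(session$trial_len / bin_ms) * bin_ms
  pick <- function(cell) {
    ev <- events[events$cell_id == cell & events$trial %in% trials &
                   events$t_ms < win, c("trial", "t_ms")]
    bin_events(ev, win, bin_ms, trials = trials)
  }
  a <- pick(cell_a)
  b <- pick(cell_b)
  stat <- synchrony_statistic(a, b)
  nul <- jitter_null(a, b, delta_ms = delta_ms, n_resamples = n_resamples,
                     seed = seed)
  structure(list(site = site, statistic = stat, null_samples = nul,
                 p_value = common_input_pvalue(stat, nul)),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("Site %s: synchrony statistic %d, p = %.4g (%d resamples)\n",
              format(x$site), x$statistic, x$p_value, length(x$null_samples)))
  invisible(x)
}

#' Flag common-input sites by pooled BH-FDR
#'
#' Applies the Benjamini-Hochberg step-up procedure at level \code{q}
#' (default 0.05) to synchrony-test p-values pooled across all candidate
#' sites of all simultaneously recorded pairs, and writes the flags back.
#'
#' @param sync_results \code{data.frame} with at least a \code{p_value}
#'   column (one row per candidate site, typically also \code{pair_id} and
#'   \code{site}).
#' @param q FDR level.
#' @return The input with a logical \code{common} column appended; an empty
#'   input is returned unchanged with the column added.
#' @export
detect_common_inputs <- function(sync_results, q = 0.05) {
  if (!is.data.frame(sync_results) || !"p_value" %in% names(sync_results))
    stop_config("'sync_results' must be a data.frame with a p_value column")
  sync_results$common <- if (nrow(sync_results))
    bh_fdr(sync_results$p_value, q) else logical()
  sync_results
}

#' Run the two-stage common-input analysis for one recorded pair
#'
#' Stage one detects each cell's input sites (Poisson test, BH-FDR at
#' \code{q_sites}); stage two runs the interval-jitter synchrony test at
#' every candidate site where both cells receive input. P-values are returned
#' un-thresholded so they can be pooled across pairs before FDR control with
#' \code{\link{detect_common_inputs}}.
#'
#' @param events event table containing both cells of the pair.
#' @param cell_a,cell_b cell identifiers.
#' @param session a \code{\link{make_session}}.
#' @param pair_id label attached to the output rows.
#' @param q_sites FDR level of the input-site stage (default 0.1).
#' @param delta_ms,n_resamples passed to \code{\link{jitter_null}}.
#' @param seed integer seed (per-site seeds are derived from it).
#' @return List: \code{sites} (per-cell site results), \code{input_a},
#'   \code{input_b} (detected site indices), \code{sync} (data.frame
#'   \code{pair_id}, \code{site}, \code{statistic}, \code{p_value} over
#'   candidates).
#' @export
pair_common_input <- function(events, cell_a, cell_b, session, pair_id = "pair",
                              q_sites = 0.1, delta_ms = 10, n_resamples = 1999,
                              seed = NULL) {
  sites <- detect_input_sites(events[events$cell_id %in% c(cell_a, cell_b), ,
                                     drop = FALSE], session, q = q_sites)
  input_a <- sites$site[sites$cell_id == cell_a & sites$significant]
  input_b <- sites$site[sites$cell_id == cell_b & sites$significant]
  cand <- intersect(input_a, input_b)
  if (!is.null(seed)) seed_rng(seed)
  site_seeds <- if (length(cand)) sample.int(.Machine$integer.max, length(cand))
                else integer()
  sync <- data.frame(pair_id = character(), site = integer(),
                     statistic = integer(), p_value = numeric(),
                     stringsAsFactors = FALSE)
  for (i in seq_along(cand)) {
    r <- site_synchrony(events, cell_a, cell_b, session, cand[i],
                        delta_ms = delta_ms, n_resamples = n_resamples,
                        seed = site_seeds[i])
    sync <- rbind(sync, data.frame(pair_id = pair_id, site = cand[i],
                                   statistic = r$statistic, p_value = r$p_value,
                                   stringsAsFactors = FALSE))
  }
  list(sites = sites, input_a = input_a, input_b = input_b, sync = sync)
}

#' Summarize common input for a simultaneously recorded pair
#'
#' Computes the pair's input-site sets, the flagged common sites, and the
#' common-input probability: the number of detected common-input sites
#' divided by the number of unique detected input sites of the pair (the
#' cardinality of the union; 0 when the union is empty).
#'
#' @param input_a,input_b detected input-site indices of the two cells.
#' @param common_sites flagged common-input site indices (must be a subset of
#'   the intersection).
#' @param pair_id,layer_a,layer_b optional labels.
#' @return List of class \code{"pair_summary"}.
#' @export
pair_summary <- function(input_a, input_b, common_sites, pair_id = "pair",
                         layer_a = NA, layer_b = NA) {
  common_sites <- unique(common_sites)
  if (!all(common_sites %in% intersect(input_a, input_b)))
    stop_config("common sites must lie in the intersection of the input sets")
  union_n <- length(union(input_a, input_b))
  structure(list(pair_id = pair_id, layer_a = layer_a, layer_b = layer_b,
                 input_sites_a = sort(unique(input_a)),
                 input_sites_b = sort(unique(input_b)),
                 common_sites = sort(common_sites),
                 common_input_probability = if (union_n == 0L) 0 else
                   length(common_sites) / union_n),
            class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat(sprintf("Pair %s: |A|=%d, |B|=%d, common=%d, P(common)=%.3f\n",
              x$pair_id, length(x$input_sites_a), length(x$input_sites_b),
              length(x$common_sites), x$common_input_probability))
  invisible(x)
}
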