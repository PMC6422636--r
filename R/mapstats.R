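# Per-site evoked-input detection: background-rate estimation from ITI tails,
# a Poisson upper-tail test on the per-site event count, and BH-FDR control
# across the grid sites of each recorded cell.

#' Background event rate from inter-trial intervals
#'
#' Estimates the spontaneous (background) event rate of each recorded cell
#' from the last \code{tail_ms} of every inter-trial interval: total events
#' falling in those windows divided by the total time they span.
#'
#' @param events event table (\code{cell_id}, \code{trial}, \code{t_ms}).
#' @param session a \code{\link{make_session}} object; its ITI must be at
#'   least \code{tail_ms} long.
#' @param tail_ms length of the ITI tail used (default 25 ms).
#' @return Named numeric vector of rates in Hz, one per cell appearing in
#'   \code{events}. Cells with no events get 0.
#' @export
background_rate <- function(events, session, tail_ms = 25) {
  validate_events(events)
  if (!inherits(session, "stim_session")) stop_config("'session' must be a stim_session")
  n_trials <- length(session$trial_order)
  if (n_trials == 0L) stop_config("session has no trials")
  if (session$iti < tail_ms)
    stop_config("inter-trial interval (%g ms) shorter than the %g ms tail",
                session$iti, tail_ms)
  win_lo <- session$trial_len - tail_ms
  total_s <- n_trials * tail_ms / 1000
  cells <- unique(events$cell_id)
  in_tail <- events$t_ms >= win_lo & events$t_ms < session$trial_len
  counts <- table(factor(events$cell_id[in_tail], levels = cells))
  setNames(as.numeric(counts) / total_s, cells)
}

#' Poisson upper-tail p-value for a per-site evoked count
#'
#' Tests the null hypothesis that a stimulation site evokes no input: the
#' number of events observed in the evoked windows of that site's trials is
#' compared against a Poisson null with mean
#' \code{background * window * n_trials}. The p-value is
#' \code{P(X >= observed)}; an observed count of zero always gives p = 1.
#' A background rate of exactly zero with a positive count is floored at
#' \code{rate_floor} (one pseudo-event over the total background-estimation
#' time), so the p-value never degenerates to 0.
#'
#' @param observed total event count over the site's evoked windows.
#' @param background background rate, Hz.
#' @param n_trials number of trials at the site.
#' @param window_ms evoked-window length, ms (default 30).
#' @param rate_floor floor applied to a zero background rate, Hz.
#' @return p-value in (0, 1].
#' @examples
#' site_pvalue(5, background = 1000 / 30, n_trials = 1)  # expected count 1
#' @export
site_pvalue <- function(observed, background, n_trials, window_ms = 30,
                        rate_floor = 0.1) {
  observed <- check_count(observed, "observed")
  check_number(background, "background", lower = 0)
  n_trials <- check_count(n_trials, "n_trials", min = 1L)
  if (observed == 0L) return(1)
  rate <- if (background > 0) background else rate_floor
  lambda <- rate * (window_ms / 1000) * n_trials
  ppois(observed - 1L, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR flags
#'
#' Standard BH procedure at level \code{q}: with ordered p-values p(1) <= ...
#' <= p(m), all hypotheses up to the largest i with p(i) <= i q / m are
#' rejected.
#'
#' @param pvals numeric vector of p-values.
#' @param q FDR level in (0, 1).
#' @return Logical vector of rejection flags, same length/order as
#'   \code{pvals}; empty input gives an empty vector.
#' @export
bh_fdr <- function(pvals, q = 0.1) {
  check_number(q, "q", lower = 1e-12, upper = 1 - 1e-12)
  if (length(pvals) == 0L) return(logical())
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Detect photostimulation sites with evoked input
#'
#' Composes the full per-cell site-detection pipeline: background rate from
#' ITI tails, per-site event counts in the evoked window (default
#' \code{[stim onset + 5, stim onset + 35)} ms, half-open), Poisson
#' upper-tail p-values, and BH-FDR control at level \code{q} across the grid
#' sites of each recorded cell.
#'
#' @param events event table for one session (possibly several cells).
#' @param session a \code{\link{make_session}} object.
#' @param q FDR level (default 0.1).
#' @param window_ms,offset_ms evoked window length and offset after stimulus
#'   onset, ms.
#' @return \code{data.frame} with one row per (cell, site): \code{cell_id},
#'   \code{site}, \code{n_trials}, \code{observed_events},
#'   \code{expected_events}, \code{evoked_deviation} (events/trial above
#'   background), \code{p_value}, \code{significant}.
#' @export
detect_input_sites <- function(events, session, q = 0.1, window_ms = 30,
                               offset_ms = 5) {
  validate_events(events)
  if (!inherits(session, "stim_session")) stop_config("'session' must be a stim_session")
  win_lo <- session$stim_onset + offset_ms
  win_hi <- win_lo + window_ms
  if (win_hi > session$trial_len)
    stop_config("evoked window extends past the trial")
  bg <- background_rate(events, session)
  # floor for degenerate zero-background cells: one pseudo-event over the
  # total background-estimation time
  total_bg_s <- length(session$trial_order) * 25 / 1000
  floor_hz <- 1 / total_bg_s

  sites <- session$grid$site
  trials_per_site <- table(factor(session$trial_order, levels = sites))
  site_of_trial <- session$trial_order

  out <- list()
  for (cell in names(bg)) {
    ev <- events[events$cell_id == cell, , drop = FALSE]
    in_win <- ev$t_ms >= win_lo & ev$t_ms < win_hi
    ev_site <- site_of_trial[ev$trial[in_win]]
    observed <- as.integer(table(factor(ev_site, levels = sites)))
    n_tr <- as.integer(trials_per_site)
    lambda_rate <- if (bg[[cell]] > 0) bg[[cell]] else floor_hz
    expected <- lambda_rate * (window_ms / 1000) * n_tr
    p <- ifelse(observed == 0L, 1,
                ppois(observed - 1L, expected, lower.tail = FALSE))
    keep <- n_tr > 0L
    res <- data.frame(cell_id = cell, site = sites, n_trials = n_tr,
                      observed_events = observed, expected_events = expected,
                      evoked_deviation = ifelse(keep, observed / pmax(n_tr, 1L) -
                                                  bg[[cell]] * window_ms / 1000, NA),
                      p_value = p, stringsAsFactors = FALSE)[keep, , drop = FALSE]
    res$significant <- bh_fdr(res$p_value, q)
    out[[cell]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
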