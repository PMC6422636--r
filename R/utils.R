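# internal helpers shared across modules

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    stop_config("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_config("'%s' must be in [%s, %s]", name, format(lower), format(upper))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, lower = min)
  if (x != floor(x)) stop_config("'%s' must be an integer", name)
  invisible(as.integer(x))
}

# seed every generator call; NULL leaves the RNG stream untouched
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# event tables: one row per detected/generated event
event_table <- function(cell_id, trial, t_ms) {
  data.frame(cell_id = cell_id, trial = as.integer(trial), t_ms = as.numeric(t_ms),
             stringsAsFactors = FALSE)
}

# sort within (cell, trial) and drop duplicates at sample resolution
canonicalize_events <- function(events, resolution = 1e-6) {
  if (nrow(events) == 0L) return(events)
  o <- order(events$cell_id, events$trial, events$t_ms)
  events <- events[o, , drop = FALSE]
  key <- paste(events$cell_id, events$trial, round(events$t_ms / resolution))
  events <- events[!duplicated(key), , drop = FALSE]
  rownames(events) <- NULL
  events
}

validate_events <- function(events, trial_len = NULL) {
  need <- c("cell_id", "trial", "t_ms")
  if (!all(need %in% names(events)))
    stop_config("event table must have columns %s", paste(need, collapse = ", "))
  if (nrow(events) > 0L) {
    if (any(!is.finite(events$t_ms))) stop_config("event times must be finite")
    if (!is.null(trial_len) && any(events$t_ms < 0 | events$t_ms >= trial_len))
      stop_config("event times must lie within [0, trial length)")
  }
  invisible(events)
}
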