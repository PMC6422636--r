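# Plain-text I/O: event tables, session descriptions, connectivity tallies,
# traces and sweep sets. All formats are TSV or JSON so that datasets can be
# inspected and versioned as text.

#' Read and write event tables
#'
#' Event TSVs have columns \code{cell_id}, \code{trial}, \code{t_ms}.
#'
#' @param path file path.
#' @param events event table.
#' @return \code{read_events_tsv} returns the event table.
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  validate_events(ev)
  canonicalize_events(ev)
}

#' @rdname read_events_tsv
#' @export
write_events_tsv <- function(events, path) {
  validate_events(events)
  write.table(events[, c("cell_id", "trial", "t_ms")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write stimulation sessions as JSON
#'
#' @param session a \code{\link{make_session}} object.
#' @param path file path.
#' @export
write_session_json <- function(session, path) {
  if (!inherits(session, "stim_session")) stop_config("'session' must be a stim_session")
  jsonlite::write_json(unclass(session), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_session(spacing_um = s$spacing,
               extent_um = max(s$grid$x) + s$spacing,
               n_trials_per_site = s$n_trials_per_site,
               stim_onset = s$stim_onset, stim_duration = s$stim_duration,
               iti = s$iti, trial_order = s$trial_order)
}

#' Read and write connectivity tallies
#'
#' Tally TSVs have columns \code{group}, \code{cell_id},
#' \code{connection_id}, \code{direction}, \code{outcome}.
#'
#' @param data connectivity dataset.
#' @param path file path.
#' @export
read_tallies_tsv <- function(path) {
  validate_tallies(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_tallies_tsv
#' @export
write_tallies_tsv <- function(data, path) {
  validate_tallies(data)
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write traces as TSV
#'
#' Trace TSVs have columns \code{t_ms} and \code{value}; the sampling rate is
#' recovered from the time base, which must be uniform.
#'
#' @param x a \code{\link{trace}}.
#' @param path file path.
#' @export
write_trace_tsv <- function(x, path) {
  if (!inherits(x, "trace")) stop_config("'x' must be a trace")
  write.table(data.frame(t_ms = x$t, value = x$y), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  d <- read.delim(path)
  dt <- diff(d$t_ms)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)))
    stop_config("trace time base must be uniform and increasing")
  trace(d$value, rate_khz = 1 / mean(dt), t0_ms = d$t_ms[1])
}

#' Write and read a sweep set as a directory of TSVs
#'
#' One TSV per current step (columns \code{t_ms}, \code{v_mV}, \code{i_pA})
#' plus a \code{manifest.json} holding the windows and sampling rate.
#'
#' @param sweeps a sweep set.
#' @param dir directory (created if absent).
#' @export
write_sweeps <- function(sweeps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(sweeps$sweeps))
  for (i in seq_along(sweeps$sweeps)) {
    s <- sweeps$sweeps[[i]]
    files[i] <- sprintf("sweep_%03d.tsv", i)
    write.table(data.frame(t_ms = s$t, v_mV = s$v, i_pA = s$i_inj),
                file.path(dir, files[i]), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  jsonlite::write_json(list(files = files,
                            i_inj = vapply(sweeps$sweeps, `[[`, numeric(1), "i_inj"),
                            baseline_window = sweeps$baseline_window,
                            step_window = sweeps$step_window,
                            rate = sweeps$rate),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  sweeps <- lapply(seq_along(man$files), function(i) {
    d <- read.delim(file.path(dir, man$files[i]))
    if (is.unsorted(d$t_ms, strictly = TRUE))
      stop_config("sweep %s has a non-monotone time base", man$files[i])
    list(i_inj = d$i_pA[1], t = d$t_ms, v = d$v_mV)
  })
  structure(list(sweeps = sweeps, baseline_window = man$baseline_window,
                 step_window = man$step_window, rate = man$rate, truth = NULL),
            class = "sweep_set")
}

#' Published connection tallies bundled with the package
#'
#' Loads the bundled summary table of paired-recording connection tallies
#' (connections detected / connections tested, by SST subtype and
#' direction, plus the rounded percentage as printed).
#'
#' @return \code{data.frame} with columns \code{direction}, \code{group},
#'   \code{connected}, \code{tested}, \code{n_cells}, \code{printed_pct}.
#' @export
published_tallies <- function() {
  read.delim(system.file("extdata", "connection_tallies.tsv",
                         package = "circuitmap"), stringsAsFactors = FALSE)
}
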