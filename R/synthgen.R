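# Synthetic-data generators: ground-truth circuits, photostimulation sessions,
# paired-recording tallies, current-step sweeps, and in vivo unit records.
# Every generator is a pure function of (parameters, seed).

#' Construct a ground-truth SST-to-PC circuit
#'
#' Builds a circuit of somatostatin (SST) interneurons with somata placed in the
#' photostimulation plane and pyramidal cells (PCs) labelled by cortical layer,
#' wired together by synaptic connections with per-connection latency, jitter
#' and failure probability. In \code{"exclusive"} mode no SST cell contacts PCs
#' in both L4 and L5 (each cell is assigned one output layer); in
#' \code{"mixed"} mode a fraction \code{mixed_fraction} of SST cells diverges
#' onto both layers.
#'
#' @param n_sst number of SST cells.
#' @param n_pc_per_layer named integer vector of PC counts, names among
#'   \code{"L2/3"}, \code{"L4"}, \code{"L5"}, \code{"L6"}.
#' @param divergence_mode \code{"exclusive"} or \code{"mixed"}.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param extent_um side length of the square region in which SST somata are
#'   placed (default 400, matching a 400 x 400 um stimulation grid).
#' @param targets_per_cell number of PC targets per SST cell per contacted
#'   layer (capped at the layer population).
#' @param mixed_fraction fraction of SST cells contacting both L4 and L5 in
#'   mixed mode.
#' @param latency_mean,latency_jitter_sd,failure_prob synaptic parameters
#'   given to every connection: mean conduction+release latency (ms), Gaussian
#'   jitter SD (ms), and release failure probability.
#' @return An object of class \code{"circuit"}: list with data frames
#'   \code{sst} (id, x, y), \code{pc} (id, layer) and \code{connections}
#'   (sst_id, pc_id, latency_mean, latency_jitter_sd, failure_prob).
#' @examples
#' circ <- make_circuit(8, c(L4 = 2, L5 = 2), "exclusive", seed = 1)
#' circ$connections
#' @export
make_circuit <- function(n_sst, n_pc_per_layer, divergence_mode = c("exclusive", "mixed"),
                         seed = NULL, extent_um = 400, targets_per_cell = 2,
                         mixed_fraction = 0.5, latency_mean = 1.5,
                         latency_jitter_sd = 0.3, failure_prob = 0.1) {
  divergence_mode <- match.arg(divergence_mode)
  n_sst <- check_count(n_sst, "n_sst")
  if (length(n_pc_per_layer) && is.null(names(n_pc_per_layer)))
    stop_config("'n_pc_per_layer' must be named by layer")
  bad <- setdiff(names(n_pc_per_layer), c("L2/3", "L4", "L5", "L6"))
  if (length(bad)) stop_config("unknown layer label(s): %s", paste(bad, collapse = ", "))
  check_number(failure_prob, "failure_prob", 0, 1)
  check_number(latency_mean, "latency_mean", lower = 1e-9)
  seed_rng(seed)

  sst <- data.frame(id = if (n_sst) paste0("sst", seq_len(n_sst)) else character(),
                    x = runif(n_sst, 0, extent_um), y = runif(n_sst, 0, extent_um),
                    stringsAsFactors = FALSE)
  pc <- data.frame(id = character(), layer = character(), stringsAsFactors = FALSE)
  for (ly in names(n_pc_per_layer)) {
    k <- as.integer(n_pc_per_layer[[ly]])
    if (k > 0L) {
      tag <- gsub("[^A-Za-z0-9]", "", ly)
      pc <- rbind(pc, data.frame(id = paste0("pc_", tag, "_", seq_len(k)), layer = ly,
                                 stringsAsFactors = FALSE))
    }
  }

  conns <- list()
  if (n_sst > 0L && nrow(pc) > 0L) {
    have <- intersect(c("L4", "L5"), unique(pc$layer))
    for (i in seq_len(n_sst)) {
      if (length(have) == 0L) break
      if (divergence_mode == "exclusive" || length(have) == 1L) {
        layers_i <- sample(have, 1L)
      } else {
        layers_i <- if (runif(1) < mixed_fraction) have else sample(have, 1L)
      }
      for (ly in layers_i) {
        pool <- pc$id[pc$layer == ly]
        k <- min(targets_per_cell, length(pool))
        if (k > 0L)
          conns[[length(conns) + 1L]] <- data.frame(
            sst_id = sst$id[i], pc_id = sample(pool, k),
            latency_mean = latency_mean, latency_jitter_sd = latency_jitter_sd,
            failure_prob = failure_prob, stringsAsFactors = FALSE)
      }
    }
  }
  connections <- if (length(conns)) do.call(rbind, conns) else
    data.frame(sst_id = character(), pc_id = character(), latency_mean = numeric(),
               latency_jitter_sd = numeric(), failure_prob = numeric(),
               stringsAsFactors = FALSE)
  rownames(connections) <- NULL
  structure(list(sst = sst, pc = pc, connections = connections,
                 divergence_mode = divergence_mode, seed = seed),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("Ground-truth circuit: %d SST cells, %d PCs, %d connections (%s mode)\n",
              nrow(x$sst), nrow(x$pc), nrow(x$connections), x$divergence_mode))
  invisible(x)
}

#' Describe a photostimulation session
#'
#' Defines the stimulation grid and trial structure of a mapping experiment:
#' a square grid of holographic targets (default 20 um spacing over
#' 400 x 400 um, i.e. 400 sites), one target per trial, a square light pulse at
#' \code{stim_onset} lasting \code{stim_duration}, and an inter-trial interval
#' of \code{iti} ms after the pulse. Each trial spans
#' \code{[0, stim_onset + stim_duration + iti)} ms.
#'
#' @param spacing_um grid spacing (um), must be positive.
#' @param extent_um grid side length (um).
#' @param n_trials_per_site trials per grid site.
#' @param stim_onset,stim_duration,iti stimulus onset, duration, and
#'   inter-trial interval, ms. Defaults: onset 0, 10 ms pulse, 100 ms ITI.
#' @param trial_order optional explicit sequence of site indices; default
#'   cycles through all sites \code{n_trials_per_site} times.
#' @return Object of class \code{"stim_session"}.
#' @export
make_session <- function(spacing_um = 20, extent_um = 400, n_trials_per_site = 10,
                         stim_onset = 0, stim_duration = 10, iti = 100,
                         trial_order = NULL) {
  check_number(spacing_um, "spacing_um", lower = 1e-9)
  check_number(iti, "iti", lower = 0)
  n_side <- floor(extent_um / spacing_um)
  xs <- (seq_len(n_side) - 1) * spacing_um
  grid <- expand.grid(x = xs, y = xs)
  grid <- data.frame(site = seq_len(nrow(grid)), x = grid$x, y = grid$y)
  trial_len <- stim_onset + stim_duration + iti
  if (stim_onset + stim_duration >= trial_len)
    stop_config("stimulus must end before the trial does")
  if (is.null(trial_order)) {
    trial_order <- rep(grid$site, times = n_trials_per_site)
  } else {
    trial_order <- as.integer(trial_order)
    if (any(trial_order < 1L | trial_order > nrow(grid)))
      stop_config("trial_order contains invalid site indices")
  }
  structure(list(grid = grid, spacing = spacing_um, trial_order = trial_order,
                 stim_onset = stim_onset, stim_duration = stim_duration, iti = iti,
                 n_trials_per_site = n_trials_per_site, trial_len = trial_len),
            class = "stim_session")
}

#' @export
print.stim_session <- function(x, ...) {
  cat(sprintf("Stimulation session: %d sites (%g um spacing), %d trials of %g ms\n",
              nrow(x$grid), x$spacing, length(x$trial_order), x$trial_len))
  invisible(x)
}

#' Photoexcitation profile of an opsin-expressing cell
#'
#' Spike probability falls off as a Gaussian of radial distance between the
#' stimulated target and the soma, with half-width \code{radial_halfwidth_um}
#' (probability drops to half its somatic value at that distance). The latency
#' from stimulus onset to the evoked spike is Gamma-distributed with the given
#' mean and SD, truncated at \code{truncation_ms}: most evoked spikes occur
#' within 20 ms of stimulus onset, and almost none within the first ~4 ms
#' (the evoked-rate analysis window opens 5 ms after stimulus onset for this
#' reason).
#'
#' @param radial_halfwidth_um half-width of the spike-probability falloff (um).
#' @param p_soma spike probability when the soma itself is targeted.
#' @param latency_mean_ms,latency_sd_ms,truncation_ms evoked spike latency
#'   distribution parameters (ms).
#' @return Object of class \code{"excitation_profile"}.
#' @export
excitation_profile <- function(radial_halfwidth_um = 15, p_soma = 0.95,
                               latency_mean_ms = 8, latency_sd_ms = 3.5,
                               truncation_ms = 20) {
  check_number(radial_halfwidth_um, "radial_halfwidth_um", lower = 1e-9)
  check_number(p_soma, "p_soma", 0, 1)
  check_number(latency_mean_ms, "latency_mean_ms", lower = 1e-9)
  structure(list(radial_halfwidth = radial_halfwidth_um, p_soma = p_soma,
                 latency_mean = latency_mean_ms, latency_sd = latency_sd_ms,
                 truncation = truncation_ms),
            class = "excitation_profile")
}

# spike probability at radial distance d (um); Gaussian falloff, half at halfwidth
profile_spike_prob <- function(profile, d) {
  sigma2 <- profile$radial_halfwidth^2 / (2 * log(2))
  profile$p_soma * exp(-d^2 / (2 * sigma2))
}

# truncated-Gamma latency sampler (rejection; truncation keeps >50% of mass
# for all sensible parameters)
sample_latency <- function(profile, n) {
  if (n == 0L) return(numeric())
  shape <- (profile$latency_mean / profile$latency_sd)^2
  rate <- profile$latency_mean / profile$latency_sd^2
  out <- rgamma(n, shape = shape, rate = rate)
  bad <- which(out >= profile$truncation)
  while (length(bad)) {
    out[bad] <- rgamma(length(bad), shape = shape, rate = rate)
    bad <- bad[out[bad] >= profile$truncation]
  }
  out
}

#' Simulate a photostimulation mapping session
#'
#' For every trial, each SST cell in the circuit spikes with the probability
#' given by the excitation profile at its distance from the stimulated target;
#' an evoked spike occurs at stimulus onset plus a truncated-Gamma latency.
#' Every spike propagates one IPSC event to each connected PC unless a release
#' failure is drawn; the synaptic event time is the spike time plus the
#' connection latency plus Gaussian jitter (delay floored at 0.1 ms).
#' Background IPSCs arrive as a homogeneous Poisson process in every recorded
#' PC throughout each trial.
#'
#' @param circuit a \code{\link{make_circuit}} object.
#' @param session a \code{\link{make_session}} object.
#' @param profile an \code{\link{excitation_profile}}.
#' @param background_rate background IPSC rate, Hz, per recorded PC (>= 0).
#' @param seed integer seed.
#' @return Event table (\code{cell_id}, \code{trial}, \code{t_ms}) with
#'   attributes \code{session}, \code{truth} (the SST spike table) and
#'   \code{seed}. Times are relative to trial start, sorted within cell/trial.
#' @export
simulate_mapping_session <- function(circuit, session, profile = excitation_profile(),
                                     background_rate = 5, seed = NULL) {
  if (!inherits(circuit, "circuit")) stop_config("'circuit' must be a circuit object")
  if (!inherits(session, "stim_session")) stop_config("'session' must be a stim_session")
  check_number(background_rate, "background_rate", lower = 0)
  seed_rng(seed)

  n_trials <- length(session$trial_order)
  trial_len <- session$trial_len
  targ <- session$grid[session$trial_order, c("x", "y")]

  spikes <- data.frame(sst_id = character(), trial = integer(), t_spike = numeric(),
                       stringsAsFactors = FALSE)
  if (nrow(circuit$sst) > 0L && n_trials > 0L) {
    # distance of every SST cell to every trial's target
    dx <- outer(circuit$sst$x, targ$x, "-")
    dy <- outer(circuit$sst$y, targ$y, "-")
    p <- profile_spike_prob(profile, sqrt(dx^2 + dy^2))
    fired <- which(matrix(runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
    if (nrow(fired)) {
      lat <- sample_latency(profile, nrow(fired))
      spikes <- data.frame(sst_id = circuit$sst$id[fired[, 1L]],
                           trial = as.integer(fired[, 2L]),
                           t_spike = session$stim_onset + lat,
                           stringsAsFactors = FALSE)
    }
  }

  evoked <- event_table(character(), integer(), numeric())
  if (nrow(spikes) && nrow(circuit$connections)) {
    idx <- split(seq_len(nrow(circuit$connections)), circuit$connections$sst_id)
    rows <- idx[spikes$sst_id]
    n_per <- lengths(rows)
    if (sum(n_per)) {
      conn_row <- unlist(rows, use.names = FALSE)
      spk_row <- rep(seq_len(nrow(spikes)), n_per)
      cc <- circuit$connections[conn_row, ]
      ok <- runif(length(conn_row)) >= cc$failure_prob
      delay <- pmax(cc$latency_mean + rnorm(length(conn_row), 0, cc$latency_jitter_sd), 0.1)
      t_ev <- spikes$t_spike[spk_row] + delay
      keep <- ok & t_ev < trial_len
      evoked <- event_table(cc$pc_id[keep], spikes$trial[spk_row][keep], t_ev[keep])
    }
  }

  bg <- event_table(character(), integer(), numeric())
  if (background_rate > 0 && nrow(circuit$pc) > 0L && n_trials > 0L) {
    total_ms <- n_trials * trial_len
    n_bg <- rpois(nrow(circuit$pc), background_rate * total_ms / 1000)
    if (sum(n_bg)) {
      t_abs <- runif(sum(n_bg), 0, total_ms)
      bg <- event_table(rep(circuit$pc$id, n_bg),
                        floor(t_abs / trial_len) + 1L,
                        t_abs %% trial_len)
    }
  }

  events <- canonicalize_events(rbind(evoked, bg))
  validate_events(events, trial_len)
  attr(events, "session") <- session
  attr(events, "truth") <- spikes
  attr(events, "seed") <- seed
  events
}

#' Simulate a hierarchical paired-recording connectivity dataset
#'
#' Generates binary connection-test outcomes with the observation hierarchy of
#' a paired-recording study: groups (e.g. Martinotti vs non-Martinotti SST
#' cells) contain cells, each of which was tested against a stated number of
#' candidate postsynaptic partners. Each tested connection is an independent
#' Bernoulli draw at its group's connection rate.
#'
#' @param structure named list, one element per group, each an integer vector
#'   giving the number of connections tested for each cell of that group.
#' @param rates named numeric vector of per-group connection probabilities;
#'   names must match \code{structure}.
#' @param seed integer seed.
#' @param direction connection-direction label stored with every record.
#' @return A \code{data.frame} with columns \code{group}, \code{cell_id},
#'   \code{connection_id}, \code{direction}, \code{outcome}.
#' @examples
#' d <- simulate_paired_dataset(list(MC = c(2, 3), NMC = c(1, 4)),
#'                              c(MC = 0.1, NMC = 0.5), seed = 1)
#' @export
simulate_paired_dataset <- function(structure, rates, seed = NULL,
                                    direction = "L5SST-L4PC") {
  if (!is.list(structure) || is.null(names(structure)))
    stop_config("'structure' must be a named list of per-cell connection counts")
  if (!setequal(names(structure), names(rates)))
    stop_config("'rates' names must match 'structure' names")
  if (any(rates < 0 | rates > 1)) stop_config("rates must lie in [0, 1]")
  seed_rng(seed)
  out <- list()
  for (g in names(structure)) {
    counts <- as.integer(structure[[g]])
    if (any(counts < 1L)) stop_config("every cell must have >= 1 tested connection")
    for (i in seq_along(counts)) {
      n <- counts[i]
      out[[length(out) + 1L]] <- data.frame(
        group = g, cell_id = sprintf("%s_cell%02d", g, i),
        connection_id = seq_len(n), direction = direction,
        outcome = rbinom(n, 1L, rates[[g]]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intrinsic parameters of a model neuron
#'
#' Parameters of the steady-state threshold neuron used to generate
#' current-step sweeps: resting potential, input resistance, spike threshold,
#' spike width, peak, membrane time constant, and a dimensionless adaptation
#' increment \code{a} under which successive inter-spike intervals grow
#' geometrically, \code{ISI[n+1] = ISI[n] (1+a)/(1-a)}, so that the
#' ground-truth adaptation index equals \code{a} exactly.
#'
#' @param v_rest resting potential, mV.
#' @param r_in input resistance, MOhm (> 0).
#' @param v_thresh spike threshold, mV (> \code{v_rest}).
#' @param spike_width_ms spike full width at half height, ms.
#' @param adaptation_increment dimensionless, in (-1, 1).
#' @param adaptation_sat_n number of inter-spike intervals over which
#'   adaptation accumulates before saturating (spike-frequency adaptation in
#'   cortical neurons builds up over the first few ISIs of a step and then
#'   plateaus; an ever-compounding ISI would collapse firing within a 1 s
#'   step).
#' @param membrane_tau membrane time constant, ms.
#' @param v_peak action-potential peak, mV.
#' @param fi_gain_hz_pa slope of the suprathreshold F-I relation, Hz/pA.
#' @return Object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(v_rest = -65, r_in = 150, v_thresh = -40,
                          spike_width_ms = 0.6, adaptation_increment = 0.05,
                          adaptation_sat_n = 5, membrane_tau = 15, v_peak = 30,
                          fi_gain_hz_pa = 0.3) {
  check_number(r_in, "r_in", lower = 1e-9)
  check_number(spike_width_ms, "spike_width_ms", lower = 1e-9)
  check_number(adaptation_increment, "adaptation_increment", -0.999, 0.999)
  check_number(fi_gain_hz_pa, "fi_gain_hz_pa", lower = 1e-9)
  adaptation_sat_n <- check_count(adaptation_sat_n, "adaptation_sat_n", min = 1L)
  if (v_thresh <= v_rest) stop_config("v_thresh must exceed v_rest")
  structure(list(v_rest = v_rest, r_in = r_in, v_thresh = v_thresh,
                 spike_width_ms = spike_width_ms,
                 adaptation_increment = adaptation_increment,
                 adaptation_sat_n = adaptation_sat_n,
                 membrane_tau = membrane_tau, v_peak = v_peak,
                 fi_gain = fi_gain_hz_pa),
            class = "neuron_params")
}

#' Simulate a current-step (F-I) protocol
#'
#' Generates voltage sweeps for a series of 1 s square current injections
#' (default -200, -100, then +50 to +500 pA in 50 pA increments, as in a
#' standard F-I protocol). Subthreshold steps settle exponentially to
#' \code{v_rest + I * r_in / 1000}; when the steady state would exceed
#' threshold, stereotyped triangular spikes (full width at half height equal
#' to \code{spike_width_ms}, peak \code{v_peak}) are emitted on a linear F-I
#' schedule — the base inter-spike interval is
#' \code{1000 / (fi_gain * (I - rheobase))} ms, with rheobase
#' \code{(v_thresh - v_rest) / r_in * 1000} pA — and successive intervals
#' lengthen by the geometric adaptation rule
#' \code{ISI[n+1] = ISI[n] (1+a)/(1-a)} — each adapting successive-ISI
#' contrast equals \code{a} exactly — until adaptation saturates after
#' \code{adaptation_sat_n} intervals. Between spikes the membrane relaxes from
#' rest toward the steady state, clipped at threshold. Gaussian sampling
#' noise is added to every sample. Ground-truth features travel with the
#' output.
#'
#' @param params a \code{\link{neuron_params}} object.
#' @param step_amplitudes injected-current amplitudes, pA.
#' @param seed integer seed (noise only; spike placement is deterministic).
#' @param sample_rate_khz sampling rate, kHz (default 20).
#' @param baseline_ms,step_ms,post_ms durations of the pre-step baseline, the
#'   step itself, and the post-step tail, ms.
#' @param noise_sd_mv sampling-noise SD, mV.
#' @return Object of class \code{"sweep_set"}: \code{sweeps} is a list of
#'   \code{list(i_inj, t, v)} entries (ms, mV); \code{truth} carries the
#'   generating parameters, true rheobase (pA) and per-sweep spike onset times.
#' @export
simulate_step_protocol <- function(params, step_amplitudes = c(-200, -100, seq(50, 500, 50)),
                                   seed = NULL, sample_rate_khz = 20,
                                   baseline_ms = 200, step_ms = 1000, post_ms = 200,
                                   noise_sd_mv = 0.1) {
  if (!inherits(params, "neuron_params")) stop_config("'params' must be neuron_params")
  if (any(!is.finite(step_amplitudes))) stop_config("step amplitudes must be finite")
  seed_rng(seed)
  dt <- 1 / sample_rate_khz
  t <- seq(0, baseline_ms + step_ms + post_ms - dt, by = dt)
  n <- length(t)
  t0 <- baseline_ms
  t1 <- baseline_ms + step_ms
  tau <- params$membrane_tau
  w <- params$spike_width_ms
  dv_th <- params$v_thresh - params$v_rest

  sweeps <- vector("list", length(step_amplitudes))
  spike_truth <- vector("list", length(step_amplitudes))
  for (k in seq_along(step_amplitudes)) {
    I <- step_amplitudes[k]
    dV <- I * params$r_in / 1000       # pA * MOhm -> mV
    v <- rep(params$v_rest, n)
    instep <- t >= t0 & t < t1
    poststep <- t >= t1
    v[instep] <- params$v_rest + dV * (1 - exp(-(t[instep] - t0) / tau))

    onsets <- numeric()
    rheo <- dv_th / params$r_in * 1000
    if (dV > dv_th) {
      # linear F-I schedule: base ISI set by the suprathreshold drive
      isi <- 1000 / (params$fi_gain * (I - rheo))
      ratio <- (1 + params$adaptation_increment) / (1 - params$adaptation_increment)
      t_on <- t0 + isi
      n_adapted <- 0L
      while (t_on + 2 * w <= t1) {
        onsets <- c(onsets, t_on)
        if (n_adapted < params$adaptation_sat_n) {
          isi <- isi * ratio
          n_adapted <- n_adapted + 1L
        }
        t_on <- t_on + isi
      }
      # clip the inter-spike trajectory at threshold, then paint spikes
      v[instep & v > params$v_thresh] <- params$v_thresh
      for (s in onsets) {
        seg <- t >= s & t < s + 2 * w
        ts <- t[seg]
        up <- ts < s + w
        vv <- numeric(sum(seg))
        vv[up] <- params$v_thresh + (params$v_peak - params$v_thresh) * (ts[up] - s) / w
        vv[!up] <- params$v_peak - (params$v_peak - params$v_thresh) * (ts[!up] - s - w) / w
        v[seg] <- vv
        # recharge from rest after the spike until the next event
        after <- t >= s + 2 * w & instep
        v[after] <- pmin(params$v_rest + dV * (1 - exp(-(t[after] - (s + 2 * w)) / tau)),
                         params$v_thresh)
      }
    }
    # post-step relaxation back to rest from the actual step-end potential
    v_end <- if (any(instep)) v[max(which(instep))] else params$v_rest
    v[poststep] <- params$v_rest + (v_end - params$v_rest) * exp(-(t[poststep] - t1) / tau)
    v <- v + rnorm(n, 0, noise_sd_mv)
    sweeps[[k]] <- list(i_inj = I, t = t, v = v)
    spike_truth[[k]] <- onsets
  }

  structure(list(sweeps = sweeps,
                 baseline_window = c(0, baseline_ms),
                 step_window = c(baseline_ms, baseline_ms + step_ms),
                 rate = sample_rate_khz,
                 truth = list(params = params,
                              rheobase_pa = dv_th / params$r_in * 1000,
                              spike_onsets = spike_truth),
                 seed = seed),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set: %d current steps at %g kHz (step window %g-%g ms)\n",
              length(x$sweeps), x$rate, x$step_window[1], x$step_window[2]))
  invisible(x)
}

#' Build an in vivo trial table
#'
#' Trials follow the in vivo protocol: 3 s trials separated by 1 s intervals,
#' motor (whisker stimulus) onset 1 s into each trial, LED light on a random
#' half of trials, eight stimulus positions plus a ninth non-contact position,
#' and per-trial mean running speed drawn from the population distribution
#' (41 +/- 25 cm/s, floored at 0).
#'
#' @param n_trials number of trials.
#' @param p_light fraction of light-on trials.
#' @param speed_mean,speed_sd running-speed distribution, cm/s.
#' @param seed integer seed.
#' @return \code{data.frame} with columns \code{t_motor_onset} (s),
#'   \code{light} (0/1), \code{stim_position} (1-9), \code{mean_speed} (cm/s).
#' @export
make_trial_table <- function(n_trials, p_light = 0.5, speed_mean = 41, speed_sd = 25,
                             seed = NULL) {
  n_trials <- check_count(n_trials, "n_trials", min = 1L)
  seed_rng(seed)
  data.frame(
    t_motor_onset = (seq_len(n_trials) - 1) * 4 + 1,
    light = as.integer(runif(n_trials) < p_light),
    stim_position = sample(9L, n_trials, replace = TRUE),
    mean_speed = pmax(rnorm(n_trials, speed_mean, speed_sd), 0))
}

#' Simulate in vivo unit recordings
#'
#' Each unit fires as a Poisson process at its base rate throughout the
#' recording; within the analysis window of light-on trials (750 ms starting
#' 500 ms after motor onset) the rate is multiplied by the unit's light
#' effect, so window spike counts are Poisson with mean
#' \code{rate * light_effect^light * window}. Waveform trough-to-peak
#' latencies are drawn from a bimodal mixture straddling the 0.36/0.38 ms
#' fast-/regular-spiking boundary.
#'
#' @param n_units number of units.
#' @param base_rate_hz per-unit baseline firing rate(s), Hz (recycled).
#' @param light_effect per-unit multiplicative rate factor under light
#'   (recycled; must be > 0).
#' @param trial_table a \code{\link{make_trial_table}} data frame.
#' @param seed integer seed.
#' @param window_start_s,window_len_s analysis window relative to motor onset.
#' @param p_fs fraction of narrow-waveform (fast-spiking) units.
#' @return List of \code{"unit_recording"} objects: \code{unit_id},
#'   \code{spike_times} (s, sorted), \code{trough_to_peak} (ms), \code{depth}
#'   (um), \code{trial_table}, and the generating truth.
#' @export
simulate_invivo_units <- function(n_units, base_rate_hz = 10, light_effect = 1,
                                  trial_table, seed = NULL,
                                  window_start_s = 0.5, window_len_s = 0.75,
                                  p_fs = 0.4) {
  n_units <- check_count(n_units, "n_units", min = 1L)
  if (missing(trial_table) || is.null(trial_table) || nrow(trial_table) == 0L)
    stop_config("'trial_table' must be a non-empty trial table")
  if (any(light_effect <= 0)) stop_config("light effects must be positive")
  seed_rng(seed)
  base_rate_hz <- rep_len(base_rate_hz, n_units)
  light_effect <- rep_len(light_effect, n_units)
  total_s <- max(trial_table$t_motor_onset) + 3
  win_on <- trial_table$t_motor_onset + window_start_s
  win_off <- win_on + window_len_s
  lit <- trial_table$light == 1L

  lapply(seq_len(n_units), function(u) {
    lambda <- base_rate_hz[u]
    eff <- light_effect[u]
    n_bg <- rpois(1L, lambda * total_s)
    st <- runif(n_bg, 0, total_s)
    if (any(lit) && eff != 1) {
      in_lit <- rep(FALSE, length(st))
      for (i in which(lit)) in_lit <- in_lit | (st >= win_on[i] & st < win_off[i])
      if (eff < 1) {
        drop <- in_lit & runif(length(st)) >= eff
        st <- st[!drop]
      } else {
        extra <- rpois(sum(lit), (eff - 1) * lambda * window_len_s)
        if (sum(extra)) {
          ii <- rep(which(lit), extra)
          st <- c(st, win_on[ii] + runif(length(ii), 0, window_len_s))
        }
      }
    }
    ttp <- if (runif(1) < p_fs) rnorm(1, 0.27, 0.04) else rnorm(1, 0.55, 0.08)
    structure(list(unit_id = sprintf("unit%03d", u),
                   spike_times = sort(st),
                   trough_to_peak = max(ttp, 0.05),
                   depth = runif(1, 100, 900),
                   trial_table = trial_table,
                   truth = list(base_rate_hz = lambda, light_effect = eff)),
              class = "unit_recording")
  })
}
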