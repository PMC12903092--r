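# Synthetic MEA spike-train generator. Network burst onsets follow a Gamma
# renewal process (independent control of mean inter-onset gap and its CoV:
# shape = 1/CoV^2, scale = mean * CoV^2); burst durations are log-normal;
# participating electrodes fire homogeneous Poisson trains inside the burst;
# background activity is Poisson over the whole recording. Optionally each
# main burst is trailed by a chain of short "fragment" bursts, emulating the
# fragmented synchronization regime. Every planted interval is returned as
# ground truth so detectors can be scored against it.

#' Simulation configuration for one experimental group
#'
#' @param background_rate Background (out-of-burst) firing rate per electrode,
#'   Hz. Default 0.5 Hz, sparse tonic firing typical of mature cultures
#'   between network bursts.
#' @param nb_rate Network bursts per minute. Default 3/min (~15 bursts per
#'   5-minute recording, a mid-range synchronization regime).
#' @param ibi_cov Target coefficient of variation of the inter-onset gaps
#'   (dimensionless). Default 0.3, a fairly regular rhythm.
#' @param nb_duration_mean,nb_duration_sd Mean and SD (natural scale, seconds)
#'   of the log-normal main-burst duration. Defaults 0.6 and 0.15 s keep main
#'   bursts safely above the 0.32 s main/fragment boundary.
#' @param participation_prob Probability that an electrode joins a given
#'   burst. Default 0.85.
#' @param in_burst_rate Firing rate of a participating electrode inside a
#'   burst, Hz. Default 40 Hz (in-burst ISI ~25 ms, well under the 0.1 s
#'   max-ISI rule).
#' @param frag_prob Probability that a main burst is trailed by fragments.
#'   Default 0 (no fragmentation; set > 0 to emulate the fragmented regime).
#' @param frag_count_mean Expected number of fragments per fragmenting burst
#'   (>= 1); the count is drawn as `1 + rpois(frag_count_mean - 1)` so the
#'   mean is exact.
#' @param frag_duration_range Fragment duration range, seconds; must lie
#'   strictly inside (0.1, 0.32) so fragments are detectable yet short.
#' @param frag_gap_range Gap from the end of the preceding burst in the chain
#'   to the fragment onset, seconds; must lie in (0, 1.1].
#' @param duration Recording duration, seconds (default 300).
#' @param n_electrodes Electrodes per well (default 16).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(background_rate = 0.5,
                              nb_rate = 3,
                              ibi_cov = 0.3,
                              nb_duration_mean = 0.6,
                              nb_duration_sd = 0.15,
                              participation_prob = 0.85,
                              in_burst_rate = 40,
                              frag_prob = 0,
                              frag_count_mean = 1,
                              frag_duration_range = c(0.12, 0.26),
                              frag_gap_range = c(0.1, 0.9),
                              duration = 300,
                              n_electrodes = 16,
                              seed = 1L) {
  cfg <- list(
    background_rate = background_rate, nb_rate = nb_rate, ibi_cov = ibi_cov,
    nb_duration_mean = nb_duration_mean, nb_duration_sd = nb_duration_sd,
    participation_prob = participation_prob, in_burst_rate = in_burst_rate,
    frag_prob = frag_prob, frag_count_mean = frag_count_mean,
    frag_duration_range = frag_duration_range,
    frag_gap_range = frag_gap_range,
    duration = duration, n_electrodes = as.integer(n_electrodes),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  rates <- c(cfg$background_rate, cfg$nb_rate, cfg$in_burst_rate)
  if (any(rates < 0)) stopf("rates must be non-negative")
  probs <- c(cfg$participation_prob, cfg$frag_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$ibi_cov < 0) stopf("ibi_cov must be non-negative")
  if (cfg$nb_duration_mean <= 0 || cfg$nb_duration_sd < 0) {
    stopf("nb duration mean must be > 0 and sd >= 0")
  }
  fdr <- cfg$frag_duration_range
  if (length(fdr) != 2 || fdr[1] >= fdr[2] || fdr[1] <= 0.1 || fdr[2] >= 0.32) {
    stopf("frag_duration_range must be an increasing interval inside (0.1, 0.32)")
  }
  fgr <- cfg$frag_gap_range
  if (length(fgr) != 2 || fgr[1] > fgr[2] || fgr[1] <= 0 || fgr[2] > 1.1) {
    stopf("frag_gap_range must be an interval inside (0, 1.1]")
  }
  if (cfg$frag_prob > 0 && cfg$frag_count_mean < 1) {
    stopf("frag_count_mean must be >= 1 when frag_prob > 0")
  }
  if (cfg$duration <= 0) stopf("duration must be positive")
  if (cfg$n_electrodes < 1) stopf("n_electrodes must be >= 1")
  invisible(cfg)
}

# Apply named overrides to a config, re-validating; unknown names error.
override_config <- function(cfg, overrides) {
  if (!length(overrides)) return(cfg)
  unknown <- setdiff(names(overrides), names(unclass(cfg)))
  if (length(unknown)) {
    stopf("unknown simulation_config field(s): %s",
          paste(unknown, collapse = ", "))
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_simulation_config(cfg)
  cfg
}

# Draw main-burst onsets from the Gamma renewal process on [0, duration].
draw_onsets <- function(nb_rate, ibi_cov, duration) {
  if (nb_rate <= 0) return(numeric(0))
  mean_gap <- 60 / nb_rate
  n_max <- ceiling(duration / mean_gap * 4) + 20
  gaps <- if (ibi_cov <= 0) {
    rep(mean_gap, n_max)
  } else {
    shape <- 1 / ibi_cov^2
    stats::rgamma(n_max, shape = shape, scale = mean_gap * ibi_cov^2)
  }
  onsets <- cumsum(gaps)
  onsets[onsets < duration]
}

#' Simulate one MEA well with ground truth
#'
#' @param config A [simulation_config()].
#' @param well_id Well identifier for the returned recording.
#' @param metadata Named list of well annotations.
#' @param layout A [plate_layout()]; electrode names are taken from it
#'   (the first `n_electrodes` ids).
#' @return A list with elements `recording` (a [spike_recording()]), `truth`
#'   (data frame `well_id, start, end, class, anchor` of planted network-burst
#'   intervals; `anchor` indexes the main burst a fragment chain trails) and
#'   `electrode_truth` (data frame `well_id, electrode_id, start, end` of
#'   planted per-electrode burst intervals).
#' @export
simulate_well <- function(config, well_id = "A1", metadata = list(),
                          layout = plate_layout()) {
  validate_simulation_config(config)
  with_seed(config$seed, simulate_well_impl(config, well_id, metadata, layout))
}

simulate_well_impl <- function(cfg, well_id, metadata, layout) {
  el_ids <- electrode_ids(layout)[seq_len(cfg$n_electrodes)]
  onsets <- draw_onsets(cfg$nb_rate, cfg$ibi_cov, cfg$duration)

  # Log-normal duration parameterized by natural-scale mean/sd.
  draw_duration <- function(n) {
    if (cfg$nb_duration_sd <= 0) return(rep(cfg$nb_duration_mean, n))
    cv2 <- (cfg$nb_duration_sd / cfg$nb_duration_mean)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(cfg$nb_duration_mean) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  }

  # Build each main burst plus its (optional) fragment chain; redraw the whole
  # chain if it would collide with the next onset or run off the recording,
  # so the planted ground truth stays unambiguous. An onset whose chain still
  # cannot be placed after the rejection cap (e.g. an onset landing right at
  # the recording edge) is dropped rather than truncated.
  starts <- numeric(0); ends <- numeric(0)
  classes <- character(0); anchors <- integer(0)
  for (i in seq_along(onsets)) {
    limit <- if (i < length(onsets)) onsets[i + 1] - 0.05 else cfg$duration
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      s <- onsets[i]
      d <- draw_duration(1)
      chain_s <- s; chain_e <- s + d
      chain_cls <- "main"
      if (cfg$frag_prob > 0 && stats::runif(1) < cfg$frag_prob) {
        n_frag <- 1L + stats::rpois(1, cfg$frag_count_mean - 1)
        for (k in seq_len(n_frag)) {
          gap <- stats::runif(1, cfg$frag_gap_range[1], cfg$frag_gap_range[2])
          fd <- stats::runif(1, cfg$frag_duration_range[1],
                             cfg$frag_duration_range[2])
          fs <- chain_e[length(chain_e)] + gap
          chain_s <- c(chain_s, fs); chain_e <- c(chain_e, fs + fd)
          chain_cls <- c(chain_cls, "fragment")
        }
      }
      if (max(chain_e) <= limit) { ok <- TRUE; break }
    }
    if (!ok) next
    main_idx <- length(starts) + 1L
    starts <- c(starts, chain_s); ends <- c(ends, chain_e)
    classes <- c(classes, chain_cls)
    anchors <- c(anchors, ifelse(chain_cls == "main", NA_integer_, main_idx))
  }

  truth <- data.frame(
    well_id = rep(well_id, length(starts)),
    start = starts, end = ends, class = classes, anchor = anchors,
    stringsAsFactors = FALSE
  )

  # Spikes: background Poisson over the recording plus per-burst Poisson
  # trains on participating electrodes (uniform boxcar rate profile).
  tick <- 1 / 12500
  spikes <- stats::setNames(vector("list", length(el_ids)), el_ids)
  et_rows <- list()
  participate <- if (nrow(truth)) {
    matrix(
      stats::runif(length(el_ids) * nrow(truth)) < cfg$participation_prob,
      nrow = length(el_ids)
    )
  } else {
    matrix(logical(0), nrow = length(el_ids))
  }
  for (e in seq_along(el_ids)) {
    n_bg <- stats::rpois(1, cfg$background_rate * cfg$duration)
    t <- stats::runif(n_bg, 0, cfg$duration)
    for (b in seq_len(nrow(truth))) {
      if (!participate[e, b]) next
      dur_b <- truth$end[b] - truth$start[b]
      n_b <- stats::rpois(1, cfg$in_burst_rate * dur_b)
      t <- c(t, stats::runif(n_b, truth$start[b], truth$end[b]))
      et_rows[[length(et_rows) + 1L]] <- data.frame(
        well_id = well_id, electrode_id = el_ids[e],
        start = truth$start[b], end = truth$end[b],
        stringsAsFactors = FALSE
      )
    }
    t <- round(t / tick) * tick
    t <- sort(unique(t))
    t <- t[t >= 0 & t <= cfg$duration]
    spikes[[e]] <- t
  }

  electrode_truth <- if (length(et_rows)) {
    do.call(rbind, et_rows)
  } else {
    data.frame(well_id = character(0), electrode_id = character(0),
               start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)
  }

  rec <- spike_recording(well_id, spikes, duration = cfg$duration,
                         sampling_rate = 12500, metadata = metadata,
                         layout = layout)
  # Restrict the recording to the simulated electrode subset when smaller
  # than the layout.
  rec$spikes <- rec$spikes[el_ids]
  list(recording = rec, truth = truth, electrode_truth = electrode_truth)
}

#' Simulate a multi-group plate
#'
#' Per-well seeds are derived deterministically from the master seed, so a
#' given master seed always yields the identical plate.
#'
#' @param groups Named list of [simulation_config()], one per experimental
#'   group.
#' @param wells_per_group Number of wells per group.
#' @param seed Master integer seed.
#' @param layout A [plate_layout()].
#' @return A list with `recordings` (named list of [spike_recording()], group
#'   label in each recording's metadata), `truth` and `electrode_truth`
#'   (pooled ground-truth tables with a `group` column).
#' @export
simulate_plate <- function(groups, wells_per_group, seed = 1L,
                           layout = plate_layout()) {
  if (!length(groups)) stopf("at least one group is required")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stopf("groups must be a named list")
  }
  if (wells_per_group == 0) {
    warnf("wells_per_group is 0; returning an empty plate")
    return(list(recordings = list(),
                truth = data.frame(), electrode_truth = data.frame()))
  }
  n_total <- length(groups) * wells_per_group
  if (n_total > layout$n_wells) {
    stopf("%d wells requested but the layout has %d", n_total, layout$n_wells)
  }
  wells <- well_ids(layout)[seq_len(n_total)]
  recs <- list(); truths <- list(); etruths <- list()
  idx <- 0L
  for (g in names(groups)) {
    for (w in seq_len(wells_per_group)) {
      idx <- idx + 1L
      cfg <- groups[[g]]
      cfg$seed <- derive_seed(seed, idx)
      sim <- simulate_well(cfg, well_id = wells[idx],
                           metadata = list(group = g), layout = layout)
      recs[[wells[idx]]] <- sim$recording
      if (nrow(sim$truth)) sim$truth$group <- g
      if (nrow(sim$electrode_truth)) sim$electrode_truth$group <- g
      truths[[idx]] <- sim$truth
      etruths[[idx]] <- sim$electrode_truth
    }
  }
  list(
    recordings = recs,
    truth = do.call(rbind, c(truths[vapply(truths, nrow, 1L) > 0],
                             list(make.row.names = FALSE))),
    electrode_truth = do.call(rbind, c(etruths[vapply(etruths, nrow, 1L) > 0],
                                       list(make.row.names = FALSE)))
  )
}

#' Simulate a developmental trajectory
#'
#' Emulates a longitudinal design in which the same plate is recorded at
#' several DIVs (days in vitro) with age-dependent activity: one plate is
#' generated per DIV, applying the trajectory's parameter overrides to the
#' base configuration. Seeds differ per DIV deterministically.
#'
#' @param base A [simulation_config()].
#' @param trajectory Named list mapping DIV label to a list of
#'   `simulation_config` field overrides (may be empty lists).
#' @param wells_per_div Wells simulated at each DIV.
#' @param seed Master seed.
#' @param layout A [plate_layout()].
#' @return Named list (one element per DIV, in the given order) of
#'   [simulate_plate()] results.
#' @export
simulate_development <- function(base, trajectory, wells_per_div = 20,
                                 seed = 1L, layout = plate_layout()) {
  if (!length(trajectory)) stopf("trajectory must name at least one DIV")
  out <- vector("list", length(trajectory))
  names(out) <- names(trajectory)
  for (i in seq_along(trajectory)) {
    cfg <- override_config(base, trajectory[[i]])
    out[[i]] <- simulate_plate(
      groups = stats::setNames(list(cfg), names(trajectory)[i]),
      wells_per_group = wells_per_div,
      seed = derive_seed(seed, 100000L + i),
      layout = layout
    )
  }
  out
}
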