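# Canonical spike-table format: a plain CSV of per-electrode spike timestamps
# (well_id, electrode_id, time_s) accompanied by a YAML manifest carrying the
# recording metadata (duration, sampling rate, per-well annotations). Times are
# seconds from recording start; intervals throughout the package are half-open
# [start, end).

#' Construct a spike recording for one well
#'
#' @param well_id Well identifier (e.g. `"A1"`).
#' @param spikes Named list, one sorted numeric vector of spike times (seconds)
#'   per electrode. Electrodes with no spikes are empty vectors. Names must be
#'   the layout's electrode ids.
#' @param duration Recording duration in seconds (default 300, a 5-minute
#'   recording).
#' @param sampling_rate Acquisition sampling rate in Hz (default 12500).
#' @param metadata Named list of well annotations (line, DIV, group,
#'   treatment, batch, ...).
#' @param layout A [plate_layout()]; electrodes missing from `spikes` are
#'   filled in as empty.
#' @return An object of class `spike_recording`.
#' @export
spike_recording <- function(well_id, spikes = list(), duration = 300,
                            sampling_rate = 12500, metadata = list(),
                            layout = plate_layout()) {
  ids <- electrode_ids(layout)
  full <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) full[[id]] <- numeric(0)
  if (length(spikes)) {
    unknown <- setdiff(names(spikes), ids)
    if (length(unknown)) {
      stopf("unknown electrode id(s): %s", paste(unknown, collapse = ", "))
    }
    for (id in names(spikes)) full[[id]] <- as.numeric(spikes[[id]])
  }
  structure(
    list(
      well_id = as.character(well_id),
      spikes = full,
      duration = as.numeric(duration),
      sampling_rate = as.numeric(sampling_rate),
      metadata = metadata
    ),
    class = "spike_recording"
  )
}

#' @export
print.spike_recording <- function(x, ...) {
  n <- vapply(x$spikes, length, integer(1))
  cat(sprintf(
    "spike_recording %s: %d spikes on %d/%d active electrodes, %g s @ %g Hz\n",
    x$well_id, sum(n), sum(n > 0), length(n), x$duration, x$sampling_rate
  ))
  invisible(x)
}

#' Validate a spike recording
#'
#' Checks the recording invariants: per-electrode times sorted, within
#' `[0, duration]`, and aligned to the sampling grid (multiples of
#' `1/sampling_rate`, tolerance 1e-9 s). Violations are returned, not raised.
#'
#' @param rec A [spike_recording()].
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_recording <- function(rec) {
  out <- character(0)
  tick <- 1 / rec$sampling_rate
  for (id in names(rec$spikes)) {
    t <- rec$spikes[[id]]
    if (!length(t)) next
    if (is.unsorted(t)) {
      out <- c(out, sprintf("electrode %s: spike times not sorted", id))
    }
    if (any(t < 0)) {
      out <- c(out, sprintf("electrode %s: negative spike times", id))
    }
    if (any(t > rec$duration)) {
      out <- c(out, sprintf(
        "electrode %s: spike times beyond duration %g s", id, rec$duration
      ))
    }
    off <- abs(t - round(t / tick) * tick)
    if (any(off > 1e-9)) {
      out <- c(out, sprintf(
        "electrode %s: %d spike time(s) off the %g Hz sampling grid",
        id, sum(off > 1e-9), rec$sampling_rate
      ))
    }
  }
  out
}

# Fixed-precision time formatting: 7 decimals covers the supported sampling
# grids exactly (12.5 kHz ticks are multiples of 8e-5 s).
format_time_s <- function(t) sprintf("%.7f", t)

#' Write spike recordings to the canonical CSV + manifest
#'
#' Writes `spikes.csv` with columns `well_id, electrode_id, time_s` and a YAML
#' manifest recording duration, sampling rate and per-well metadata (so wells
#' and electrodes without spikes survive a round trip).
#'
#' @param recordings List of [spike_recording()] objects.
#' @param path Output CSV path.
#' @param manifest_path Output manifest path; default replaces the CSV
#'   extension with `_manifest.yaml`.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(recordings, path,
                              manifest_path = default_manifest_path(path)) {
  if (inherits(recordings, "spike_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(rec) {
    n <- vapply(rec$spikes, length, integer(1))
    data.frame(
      well_id = rep(rec$well_id, sum(n)),
      electrode_id = rep(names(rec$spikes), n),
      time_s = format_time_s(unlist(rec$spikes, use.names = FALSE)),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)

  wells <- lapply(recordings, function(rec) {
    md <- rec$metadata
    if (!length(md)) md <- list(group = "unspecified")
    md
  })
  names(wells) <- vapply(recordings, function(r) r$well_id, character(1))
  manifest <- list(
    duration_s = recordings[[1]]$duration,
    sampling_rate_hz = recordings[[1]]$sampling_rate,
    wells = wells
  )
  yaml::write_yaml(manifest, manifest_path)
  invisible(path)
}

default_manifest_path <- function(path) {
  sub("\\.csv$", "_manifest.yaml", path)
}

#' Read spike recordings from the canonical CSV + manifest
#'
#' Parses the spike table and returns one [spike_recording()] per well.
#' Electrodes with zero spikes are present as empty vectors; wells listed in
#' the manifest but absent from the CSV are returned as silent recordings.
#' Malformed rows (unparseable time, negative or beyond-duration time, unknown
#' electrode id) raise an error naming the offending row.
#'
#' @param path CSV path (columns `well_id, electrode_id, time_s`).
#' @param manifest_path Manifest path or `NULL` to use defaults (300 s,
#'   12.5 kHz, wells taken from the CSV).
#' @param layout A [plate_layout()].
#' @return Named list of [spike_recording()], one per well.
#' @export
read_spike_table <- function(path, manifest_path = NULL,
                             layout = plate_layout()) {
  if (is.null(manifest_path)) {
    cand <- default_manifest_path(path)
    if (file.exists(cand)) manifest_path <- cand
  }
  manifest <- if (!is.null(manifest_path)) {
    yaml::read_yaml(manifest_path)
  } else {
    list(duration_s = 300, sampling_rate_hz = 12500, wells = NULL)
  }
  duration <- as.numeric(manifest$duration_s %||% 300)
  fs <- as.numeric(manifest$sampling_rate_hz %||% 12500)

  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character"))
  need <- c("well_id", "electrode_id", "time_s")
  if (!all(need %in% names(tab))) {
    stopf("spike table %s must have columns %s", path,
          paste(need, collapse = ", "))
  }
  ids <- electrode_ids(layout)
  if (nrow(tab)) {
    times <- suppressWarnings(as.numeric(tab$time_s))
    bad <- which(is.na(times))
    if (length(bad)) {
      stopf("row %d of %s: unparseable time_s '%s'", bad[1], path,
            tab$time_s[bad[1]])
    }
    bad <- which(times < 0 | times > duration)
    if (length(bad)) {
      stopf("row %d of %s: time_s %g outside [0, %g]", bad[1], path,
            times[bad[1]], duration)
    }
    bad <- which(!(tab$electrode_id %in% ids))
    if (length(bad)) {
      stopf("row %d of %s: unknown electrode id '%s'", bad[1], path,
            tab$electrode_id[bad[1]])
    }
    tab$time_num <- times
  } else {
    warnf("spike table %s contains no spikes", path)
    tab$time_num <- numeric(0)
  }

  well_names <- unique(tab$well_id)
  if (!is.null(manifest$wells)) {
    well_names <- union(names(manifest$wells), well_names)
  }
  recs <- lapply(well_names, function(w) {
    sub <- tab[tab$well_id == w, , drop = FALSE]
    spikes <- split(sub$time_num, factor(sub$electrode_id, levels = ids))
    spikes <- lapply(spikes, sort)
    md <- if (!is.null(manifest$wells)) manifest$wells[[w]] else list()
    spike_recording(w, spikes, duration = duration, sampling_rate = fs,
                    metadata = if (is.null(md)) list() else md,
                    layout = layout)
  })
  stats::setNames(recs, well_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
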