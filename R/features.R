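# Per-well network-activity feature catalogue: 39 parameters grouped as
# spike-level (8), electrode-burst-level (14), network-burst-level (12) and
# fragmentation-level (5). Conventions, fixed here and documented per
# parameter:
#   * "active" electrode = at least one spike in the recording;
#   * spike-level rate/ISI statistics are computed over active electrodes,
#     with ISIs pooled across electrodes;
#   * electrode-burst duration, spikes-per-burst and IBI statistics pool all
#     bursts of the well; in-burst ISI and burst percentage are summarized as
#     a well mean over electrodes with the SD across electrodes as the
#     companion parameter (electrodes weighted equally, not spike-weighted);
#   * "IBI" at network level is the end-to-start gap between consecutive MAIN
#     network bursts; all network-burst statistics except the fragmentation
#     block are computed over main bursts only, so removing fragments leaves
#     them unchanged;
#   * network burst frequency is the count of main bursts scaled to a
#     5-minute recording;
#   * statistics requiring more events than observed are NA, never zero.

#' The network-activity feature catalogue
#'
#' @return Data frame with columns `name`, `group`, `description`; exactly 39
#'   uniquely named parameters, all computable from a spike recording plus its
#'   electrode-burst and classified network-burst tables.
#' @export
feature_catalogue <- function() {
  entry <- function(name, group, description) {
    data.frame(name = name, group = group, description = description,
               stringsAsFactors = FALSE)
  }
  rbind(
    entry("firing_rate_mean", "spike", "mean firing rate across active electrodes (Hz)"),
    entry("firing_rate_sd", "spike", "SD of firing rate across active electrodes (Hz)"),
    entry("firing_rate_cov", "spike", "CoV of firing rate across active electrodes"),
    entry("n_spikes", "spike", "total spikes in the well"),
    entry("n_active_electrodes", "spike", "electrodes with at least one spike"),
    entry("isi_mean", "spike", "mean inter-spike interval, pooled over active electrodes (s)"),
    entry("isi_sd", "spike", "SD of pooled inter-spike intervals (s)"),
    entry("isi_cov", "spike", "CoV of pooled inter-spike intervals"),
    entry("eb_rate_mean", "electrode_burst", "mean electrode burst rate across active electrodes (bursts/min)"),
    entry("eb_duration_mean", "electrode_burst", "mean electrode burst duration, pooled bursts (s)"),
    entry("eb_duration_sd", "electrode_burst", "SD of electrode burst duration, pooled bursts (s)"),
    entry("eb_duration_cov", "electrode_burst", "CoV of electrode burst duration"),
    entry("eb_isi_within_mean", "electrode_burst", "mean ISI within burst: well mean of electrode means (s)"),
    entry("eb_isi_within_sd", "electrode_burst", "SD across electrodes of the mean ISI within burst (s)"),
    entry("eb_isi_within_cov", "electrode_burst", "CoV across electrodes of the mean ISI within burst"),
    entry("burst_pct_mean", "electrode_burst", "burst percentage: well mean over electrodes of % spikes in bursts"),
    entry("burst_pct_sd", "electrode_burst", "SD across electrodes of the burst percentage"),
    entry("eb_ibi_mean", "electrode_burst", "mean electrode inter-burst interval, pooled (s)"),
    entry("eb_ibi_sd", "electrode_burst", "SD of electrode inter-burst intervals, pooled (s)"),
    entry("eb_ibi_cov", "electrode_burst", "CoV of electrode inter-burst intervals"),
    entry("spikes_per_burst_mean", "electrode_burst", "mean spikes per electrode burst, pooled bursts"),
    entry("spikes_per_burst_sd", "electrode_burst", "SD of spikes per electrode burst, pooled bursts"),
    entry("nb_rate", "network_burst", "network burst frequency: main bursts per 5 min"),
    entry("nb_duration_mean", "network_burst", "mean main network burst duration (s)"),
    entry("nb_duration_sd", "network_burst", "SD of main network burst duration (s)"),
    entry("nb_duration_cov", "network_burst", "CoV of main network burst duration"),
    entry("nb_ibi_mean", "network_burst", "mean network IBI: end-to-start gap between consecutive main bursts (s)"),
    entry("nb_ibi_sd", "network_burst", "SD of network IBIs (s)"),
    entry("nb_ibi_cov", "network_burst", "CoV of network IBIs"),
    entry("nb_pct", "network_burst", "network burst percentage: % of spikes inside main network bursts"),
    entry("nb_participation_mean", "network_burst", "mean % of electrodes participating per main burst"),
    entry("nb_participation_sd", "network_burst", "SD of % electrodes participating per main burst"),
    entry("nb_firing_rate_mean", "network_burst", "mean in-burst firing rate per participating electrode, over main bursts (Hz)"),
    entry("nb_firing_rate_sd", "network_burst", "SD of in-burst firing rate over main bursts (Hz)"),
    entry("frag_pct", "fragmentation", "% fragmented over total network bursts"),
    entry("frag_duration_mean", "fragmentation", "mean fragment duration (s)"),
    entry("frag_duration_sd", "fragmentation", "SD of fragment duration (s)"),
    entry("frag_gap_mean", "fragmentation", "mean gap from the preceding burst of the chain to the fragment (s)"),
    entry("frags_per_main_mean", "fragmentation", "fragments per main network burst")
  )
}

#' Extract the 39-parameter feature vector for one well
#'
#' @param rec A [spike_recording()].
#' @param ebursts Electrode bursts for this well, as returned by
#'   [detect_electrode_bursts_well()] (columns `electrode_id, start, end,
#'   n_spikes`).
#' @param nbursts Classified network bursts for this well, as returned by
#'   [detect_network_bursts()] + [classify_fragmented()] (columns `start,
#'   end, class, anchor`, optionally `n_participating`).
#' @param eparams Electrode burst parameters (used only to recompute
#'   per-electrode summaries consistently).
#' @return Named numeric vector, one element per catalogue parameter.
#' @export
extract_features <- function(rec, ebursts, nbursts,
                             eparams = electrode_burst_params()) {
  if (nrow(ebursts) && "well_id" %in% names(ebursts) &&
      !all(ebursts$well_id == rec$well_id)) {
    stopf("electrode bursts belong to a different well than %s", rec$well_id)
  }
  if (nrow(nbursts) && "well_id" %in% names(nbursts) &&
      !all(nbursts$well_id == rec$well_id)) {
    stopf("network bursts belong to a different well than %s", rec$well_id)
  }
  n_el <- length(rec$spikes)
  counts <- vapply(rec$spikes, length, integer(1))
  active <- names(counts)[counts > 0]
  duration <- rec$duration
  out <- stats::setNames(rep(NA_real_, nrow(feature_catalogue())),
                         feature_catalogue()$name)

  # spike level -------------------------------------------------------------
  fr <- counts[active] / duration
  out["firing_rate_mean"] <- mean_or_na(fr)
  out["firing_rate_sd"] <- sd_or_na(fr)
  out["firing_rate_cov"] <- cov_or_na(out["firing_rate_mean"],
                                      out["firing_rate_sd"])
  out["n_spikes"] <- sum(counts)
  out["n_active_electrodes"] <- length(active)
  isis <- unlist(lapply(rec$spikes[active], diff), use.names = FALSE)
  out["isi_mean"] <- mean_or_na(isis)
  out["isi_sd"] <- sd_or_na(isis)
  out["isi_cov"] <- cov_or_na(out["isi_mean"], out["isi_sd"])

  # electrode burst level ---------------------------------------------------
  per_el <- lapply(active, function(id) {
    b <- ebursts[ebursts$electrode_id == id, c("start", "end", "n_spikes"),
                 drop = FALSE]
    electrode_burst_stats(b, rec$spikes[[id]], duration)
  })
  if (length(per_el)) {
    per_el <- do.call(rbind, per_el)
    out["eb_rate_mean"] <- mean_or_na(per_el$burst_rate_per_min)
    durs <- ebursts$end - ebursts$start
    out["eb_duration_mean"] <- mean_or_na(durs)
    out["eb_duration_sd"] <- sd_or_na(durs)
    out["eb_duration_cov"] <- cov_or_na(out["eb_duration_mean"],
                                        out["eb_duration_sd"])
    out["eb_isi_within_mean"] <- mean_or_na(per_el$isi_within_mean)
    out["eb_isi_within_sd"] <- sd_or_na(per_el$isi_within_mean)
    out["eb_isi_within_cov"] <- cov_or_na(out["eb_isi_within_mean"],
                                          out["eb_isi_within_sd"])
    out["burst_pct_mean"] <- mean_or_na(per_el$burst_pct)
    out["burst_pct_sd"] <- sd_or_na(per_el$burst_pct)
    ibis <- unlist(lapply(seq_len(nrow(per_el)), function(i) {
      id <- active[i]
      b <- ebursts[ebursts$electrode_id == id, , drop = FALSE]
      if (nrow(b) >= 2) b$start[-1] - b$end[-nrow(b)] else numeric(0)
    }), use.names = FALSE)
    out["eb_ibi_mean"] <- mean_or_na(ibis)
    out["eb_ibi_sd"] <- sd_or_na(ibis)
    out["eb_ibi_cov"] <- cov_or_na(out["eb_ibi_mean"], out["eb_ibi_sd"])
    out["spikes_per_burst_mean"] <- mean_or_na(ebursts$n_spikes)
    out["spikes_per_burst_sd"] <- sd_or_na(ebursts$n_spikes)
  }

  # network burst level (mains only) ----------------------------------------
  mains <- nbursts[nbursts$class == "main", , drop = FALSE]
  frags <- nbursts[nbursts$class == "fragment", , drop = FALSE]
  out["nb_rate"] <- nrow(mains) * (300 / duration)
  if (nrow(mains)) {
    nd <- mains$end - mains$start
    out["nb_duration_mean"] <- mean_or_na(nd)
    out["nb_duration_sd"] <- sd_or_na(nd)
    out["nb_duration_cov"] <- cov_or_na(out["nb_duration_mean"],
                                        out["nb_duration_sd"])
    if (nrow(mains) >= 2) {
      nibi <- mains$start[-1] - mains$end[-nrow(mains)]
      out["nb_ibi_mean"] <- mean_or_na(nibi)
      out["nb_ibi_sd"] <- sd_or_na(nibi)
      out["nb_ibi_cov"] <- cov_or_na(out["nb_ibi_mean"], out["nb_ibi_sd"])
    }
    spikes_in <- vapply(seq_len(nrow(mains)), function(i) {
      sum(vapply(rec$spikes, function(t) {
        sum(t >= mains$start[i] & t < mains$end[i])
      }, numeric(1)))
    }, numeric(1))
    out["nb_pct"] <- if (sum(counts) > 0) 100 * sum(spikes_in) / sum(counts)
                     else NA_real_
    n_part <- if ("n_participating" %in% names(mains)) {
      mains$n_participating
    } else {
      vapply(seq_len(nrow(mains)), function(i) {
        sum(vapply(rec$spikes, function(t) {
          any(t >= mains$start[i] & t < mains$end[i])
        }, logical(1)))
      }, numeric(1))
    }
    part_pct <- 100 * n_part / n_el
    out["nb_participation_mean"] <- mean_or_na(part_pct)
    out["nb_participation_sd"] <- sd_or_na(part_pct)
    nbfr <- spikes_in / (pmax(n_part, 1) * (mains$end - mains$start))
    out["nb_firing_rate_mean"] <- mean_or_na(nbfr)
    out["nb_firing_rate_sd"] <- sd_or_na(nbfr)
  }

  # fragmentation level -----------------------------------------------------
  if (nrow(nbursts)) {
    out["frag_pct"] <- fragmentation_percentage(nbursts)
  }
  if (nrow(frags)) {
    fd <- frags$end - frags$start
    out["frag_duration_mean"] <- mean_or_na(fd)
    out["frag_duration_sd"] <- sd_or_na(fd)
    # gap to the immediately preceding burst in the sorted list (the chain
    # predecessor by construction of classify_fragmented)
    ord <- order(nbursts$start)
    nb_sorted <- nbursts[ord, , drop = FALSE]
    gaps <- vapply(which(nb_sorted$class == "fragment"), function(i) {
      if (i == 1) return(NA_real_)
      nb_sorted$start[i] - nb_sorted$end[i - 1]
    }, numeric(1))
    out["frag_gap_mean"] <- mean_or_na(gaps)
    if (nrow(mains)) out["frags_per_main_mean"] <- nrow(frags) / nrow(mains)
  } else if (nrow(mains)) {
    out["frags_per_main_mean"] <- 0
  }
  out
}

#' Aggregate per-well feature vectors into a feature table
#'
#' @param features Named list of feature vectors from [extract_features()]
#'   (names = well ids).
#' @param metadata Optional data frame with a `well_id` column and metadata
#'   columns (group, line, DIV, ...), joined onto the table.
#' @return Data frame: `well_id`, metadata columns, then the 39 catalogue
#'   columns in catalogue order.
#' @export
aggregate_table <- function(features, metadata = NULL) {
  if (!length(features)) stopf("no feature vectors supplied")
  mat <- do.call(rbind, features)
  tab <- data.frame(well_id = names(features), stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    if (!"well_id" %in% names(metadata)) {
      stopf("metadata must have a well_id column")
    }
    key <- if ("div" %in% names(metadata)) c("well_id", "div") else "well_id"
    if (anyDuplicated(metadata[key])) {
      stopf("duplicate (well, DIV) rows in metadata")
    }
    tab <- merge(tab, metadata, by = "well_id", sort = FALSE)
  }
  cbind(tab, as.data.frame(mat))
}

#' Normalize a feature column against control wells
#'
#' Each value is divided by the mean of the control rows, so the control mean
#' itself maps to 1.
#'
#' @param table Feature table (data frame).
#' @param value_column Name of the numeric column to normalize.
#' @param control_mask Logical vector marking the control rows.
#' @return Numeric vector of normalized values.
#' @export
normalize_to_control <- function(table, value_column, control_mask) {
  x <- table[[value_column]]
  if (is.null(x)) stopf("no column '%s' in table", value_column)
  ctrl <- x[control_mask]
  ctrl <- ctrl[!is.na(ctrl)]
  if (!length(ctrl)) stopf("no non-missing control values for '%s'", value_column)
  m <- mean(ctrl)
  if (m == 0) stopf("control mean of '%s' is zero; cannot normalize", value_column)
  x / m
}
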