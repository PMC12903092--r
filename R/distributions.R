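# Burst-duration distribution analysis: pooling of main network-burst
# durations per group, the basal-quantile exceedance procedure used to
# quantify disinhibition responses (e.g. acute picrotoxin), and paired
# pre/post firing-rate contrasts.

#' Pool main network-burst durations for a group of wells
#'
#' Fragments are excluded: durations come from main network bursts only.
#'
#' @param nbursts Classified network-burst table (columns `start, end, class`,
#'   optionally `well_id`).
#' @param wells Optional character vector restricting to these well ids.
#' @return Numeric vector of durations in seconds (possibly empty, with a
#'   warning).
#' @export
pool_durations <- function(nbursts, wells = NULL) {
  if (!is.null(wells) && "well_id" %in% names(nbursts)) {
    nbursts <- nbursts[nbursts$well_id %in% wells, , drop = FALSE]
  }
  mains <- nbursts[nbursts$class == "main", , drop = FALSE]
  if (!nrow(mains)) {
    warnf("no main network bursts to pool")
    return(numeric(0))
  }
  mains$end - mains$start
}

# Nearest-rank empirical quantile: x_(ceil(p*n)) of the sorted sample.
nearest_rank_quantile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

#' Basal exceedance threshold across groups
#'
#' Returns a duration threshold above which fewer than `100*tail`% of network
#' burst durations occur under basal conditions in every group: the maximum
#' over groups of the group-wise nearest-rank `(1 - tail)` quantile (the
#' `"pooled"` mode takes the quantile of the pooled sample instead).
#'
#' @param basal_samples Named list of numeric duration vectors, one per
#'   group; all must be non-empty.
#' @param tail Tail fraction (default 0.025, i.e. the 97.5th percentile).
#' @param mode `"per_group_max"` (default) or `"pooled"`.
#' @return Threshold in seconds.
#' @export
basal_exceedance_threshold <- function(basal_samples, tail = 0.025,
                                       mode = c("per_group_max", "pooled")) {
  mode <- match.arg(mode)
  if (!length(basal_samples)) stopf("no basal samples supplied")
  empty <- vapply(basal_samples, length, integer(1)) == 0
  if (any(empty)) {
    stopf("empty basal sample for group(s): %s",
          paste(names(basal_samples)[empty], collapse = ", "))
  }
  if (mode == "pooled") {
    return(nearest_rank_quantile(unlist(basal_samples), 1 - tail))
  }
  max(vapply(basal_samples, nearest_rank_quantile, numeric(1), p = 1 - tail))
}

#' Percentage of durations exceeding a threshold
#'
#' @param sample Numeric duration vector (non-empty).
#' @param threshold Threshold in seconds (strict: only durations above it
#'   count).
#' @return Percentage in `[0, 100]`.
#' @export
exceedance_fraction <- function(sample, threshold) {
  if (!length(sample)) stopf("empty duration sample")
  100 * sum(sample > threshold) / length(sample)
}

#' Compare two duration distributions
#'
#' Two-sided Wilcoxon rank-sum test with continuity correction (normal
#' approximation, so the result is deterministic and tie-tolerant).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (the rank-sum W) and `p_value`.
#' @export
compare_duration_distributions <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stopf("empty duration sample")
  w <- stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                          exact = FALSE, correct = TRUE)
  list(statistic = unname(w$statistic), p_value = w$p.value)
}

#' Paired mean firing rate before and after treatment
#'
#' MFR = total spikes / (active electrodes x duration), where an electrode is
#' active when it has at least one spike. A silent recording yields MFR 0
#' with zero active electrodes.
#'
#' @param rec_pre,rec_post [spike_recording()]s of the same well.
#' @return One-row data frame: `well_id, mfr_pre, mfr_post, n_active_pre,
#'   n_active_post`.
#' @export
firing_rate_change <- function(rec_pre, rec_post) {
  if (rec_pre$well_id != rec_post$well_id) {
    stopf("recordings are from different wells (%s vs %s)",
          rec_pre$well_id, rec_post$well_id)
  }
  mfr <- function(rec) {
    n <- vapply(rec$spikes, length, integer(1))
    act <- sum(n > 0)
    list(mfr = if (act) sum(n) / (act * rec$duration) else 0, active = act)
  }
  pre <- mfr(rec_pre); post <- mfr(rec_post)
  data.frame(well_id = rec_pre$well_id,
             mfr_pre = pre$mfr, mfr_post = post$mfr,
             n_active_pre = pre$active, n_active_post = post$active,
             stringsAsFactors = FALSE)
}
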