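# Scoring of detector output against planted ground truth.

#' Score detected network bursts against planted ground truth
#'
#' Greedy interval matching: each planted burst is matched to the unused
#' detected burst with the largest overlap, and counts as recovered when the
#' overlap covers at least `min_overlap` of the planted interval. Main-burst
#' precision/recall/F1 are computed over bursts planted or detected as main;
#' class accuracy is the fraction of matched bursts whose detected class
#' (main/fragment) equals the planted class; the boundary error is the mean
#' absolute start/end offset of matched main bursts.
#'
#' @param truth Planted intervals (`start, end, class`).
#' @param detected Classified detections (`start, end, class`).
#' @param min_overlap Fraction of the planted interval that must be covered.
#' @return List: `f1_main`, `precision_main`, `recall_main`,
#'   `boundary_error_s`, `label_accuracy`, plus the underlying counts
#'   (`tp`, `fp`, `fn`, `n_class_checked`, `n_class_correct`,
#'   `boundary_errors` vector).
#' @export
score_burst_recovery <- function(truth, detected, min_overlap = 0.5) {
  used <- rep(FALSE, max(nrow(detected), 0))
  tp <- 0L
  b_err <- numeric(0)
  cls_ok <- 0L; cls_tot <- 0L
  for (i in seq_len(nrow(truth))) {
    if (!nrow(detected)) break
    ov <- pmin(truth$end[i], detected$end) - pmax(truth$start[i], detected$start)
    ov[used] <- -Inf
    j <- which.max(ov)
    if (ov[j] >= min_overlap * (truth$end[i] - truth$start[i])) {
      used[j] <- TRUE
      cls_tot <- cls_tot + 1L
      if (detected$class[j] == truth$class[i]) cls_ok <- cls_ok + 1L
      if (truth$class[i] == "main") {
        tp <- tp + 1L
        b_err <- c(b_err, abs(detected$start[j] - truth$start[i]),
                   abs(detected$end[j] - truth$end[i]))
      }
    }
  }
  fn <- sum(truth$class == "main") - tp
  fp <- sum(!used & detected$class == "main")
  list(
    f1_main = if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    precision_main = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall_main = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    boundary_error_s = mean_or_na(b_err),
    label_accuracy = if (cls_tot > 0) cls_ok / cls_tot else NA_real_,
    tp = tp, fp = fp, fn = fn,
    n_class_checked = cls_tot, n_class_correct = cls_ok,
    boundary_errors = b_err
  )
}

#' Pool burst-recovery scores over a simulated plate
#'
#' Runs detection and classification on every well of a [simulate_plate()]
#' result and pools the [score_burst_recovery()] counts.
#'
#' @param plate A [simulate_plate()] result.
#' @param params A [network_burst_params()].
#' @return List: `f1_main`, `boundary_error_s`, `label_accuracy`, counts.
#' @export
score_plate_recovery <- function(plate, params = network_burst_params()) {
  tp <- 0L; fp <- 0L; fn <- 0L
  b_err <- numeric(0)
  cls_ok <- 0L; cls_tot <- 0L
  for (w in names(plate$recordings)) {
    det <- classify_fragmented(detect_network_bursts(plate$recordings[[w]],
                                                     params), params)
    tru <- plate$truth[plate$truth$well_id == w, , drop = FALSE]
    s <- score_burst_recovery(tru, det)
    tp <- tp + s$tp; fp <- fp + s$fp; fn <- fn + s$fn
    b_err <- c(b_err, s$boundary_errors)
    cls_ok <- cls_ok + s$n_class_correct
    cls_tot <- cls_tot + s$n_class_checked
  }
  list(f1_main = 2 * tp / (2 * tp + fp + fn),
       boundary_error_s = mean_or_na(b_err),
       label_accuracy = if (cls_tot > 0) cls_ok / cls_tot else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
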