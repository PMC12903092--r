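# Network burst detection. Spike timestamps are binned (2 ms), each
# electrode's binned train is smoothed with a Gaussian filter (70 ms total
# window, sigma = window/6, unit-sum, reflect padding), the smoothed signals
# are z-scored per electrode, averaged across electrodes, and smoothed again
# with the same kernel. The combined signal is binarized with the Otsu global
# threshold; supra-threshold runs become candidate network-burst intervals
# (bin-edge aligned, half-open), which must involve at least 25% of the
# electrodes, last longer than 0.1 s, and sustain a firing rate of at least
# 12 Hz on at least 25% of the actively participating electrodes. Detected
# bursts shorter than 0.32 s that trail a main (>= 0.32 s) burst by at most
# 1.1 s are classified as fragmented network bursts.

#' Network burst detection parameters
#'
#' @param bin_width Spike-count bin width, seconds (default 2 ms).
#' @param gauss_window Total support of the Gaussian smoothing kernel,
#'   seconds (default 70 ms; sigma is `gauss_window/6`).
#' @param min_participation Minimum fraction of the well's electrodes that
#'   must spike inside a candidate interval (default 0.25).
#' @param min_duration Minimum network-burst duration, seconds, strict
#'   (default 0.1).
#' @param min_rate Minimum in-interval firing rate, Hz, required of at least
#'   `rate_fraction` of the actively participating electrodes (default 12).
#' @param rate_fraction Fraction of actively participating electrodes that
#'   must satisfy `min_rate` (default 0.25).
#' @param main_min_duration Main/fragment duration boundary, seconds; bursts
#'   at least this long are mains, shorter ones are fragment candidates
#'   (default 0.32; the boundary value itself classifies as main).
#' @param frag_max_gap Maximum gap (inclusive) from the preceding burst of a
#'   chain for a short burst to count as a fragment, seconds (default 1.1).
#' @param otsu_bins Histogram bins for the Otsu threshold (default 256).
#' @param chain_gap_mode How the fragment gap is measured: `"previous"`
#'   (default; to the immediately preceding burst of the chain, so fragments
#'   may chain through fragments) or `"main"` (to the anchor main burst
#'   only).
#' @return An object of class `network_burst_params`.
#' @export
network_burst_params <- function(bin_width = 0.002, gauss_window = 0.070,
                                 min_participation = 0.25, min_duration = 0.1,
                                 min_rate = 12, rate_fraction = 0.25,
                                 main_min_duration = 0.32, frag_max_gap = 1.1,
                                 otsu_bins = 256,
                                 chain_gap_mode = c("previous", "main")) {
  stopifnot(bin_width > 0, gauss_window >= bin_width,
            min_participation > 0, min_participation <= 1,
            min_duration > 0, min_rate >= 0,
            rate_fraction > 0, rate_fraction <= 1,
            main_min_duration > 0, frag_max_gap > 0, otsu_bins >= 2)
  structure(
    list(bin_width = bin_width, gauss_window = gauss_window,
         min_participation = min_participation, min_duration = min_duration,
         min_rate = min_rate, rate_fraction = rate_fraction,
         main_min_duration = main_min_duration, frag_max_gap = frag_max_gap,
         otsu_bins = as.integer(otsu_bins),
         chain_gap_mode = match.arg(chain_gap_mode)),
    class = "network_burst_params"
  )
}

#' Bin spike timestamps into a counts matrix
#'
#' Bin `b` covers the half-open interval `[(b-1)*bin_width, b*bin_width)`;
#' a spike exactly on a bin edge falls into the later bin. The total count
#' equals the total number of spikes.
#'
#' @param rec A [spike_recording()].
#' @param bin_width Bin width, seconds.
#' @return Integer matrix, electrodes x bins, rownames = electrode ids.
#' @export
bin_spikes <- function(rec, bin_width = 0.002) {
  n_bins <- as.integer(ceiling(rec$duration / bin_width))
  counts <- vapply(rec$spikes, function(t) {
    idx <- pmin(floor(t / bin_width) + 1L, n_bins)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  t(counts)
}

gaussian_kernel <- function(window, bin_width) {
  n <- round(window / bin_width)
  if (n %% 2 == 0) n <- n + 1  # center the kernel on a bin
  half <- (n - 1) / 2
  x <- (-half:half) * bin_width
  sigma <- window / 6
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a binned signal with the Gaussian filter
#'
#' Convolves with a unit-sum truncated Gaussian whose total support equals
#' `window` (35 bins at the 2 ms / 70 ms defaults) and `sigma = window/6`.
#' The ends are reflect-padded so the output has the input's length.
#'
#' @param signal Numeric per-bin signal.
#' @param window Total kernel support, seconds.
#' @param bin_width Bin width, seconds.
#' @return Smoothed numeric vector, same length as `signal`.
#' @export
gaussian_smooth <- function(signal, window = 0.070, bin_width = 0.002) {
  if (window < bin_width) stopf("window must be at least one bin wide")
  k <- gaussian_kernel(window, bin_width)
  half <- (length(k) - 1) / 2
  n <- length(signal)
  if (half == 0) return(signal)
  pad_left <- if (n > half) signal[(half + 1):2] else
    rev(rep_len(signal, half + 1))[-1]
  pad_right <- if (n > half) signal[(n - 1):(n - half)] else
    rep_len(rev(signal), half + 1)[-1]
  padded <- c(pad_left, signal, pad_right)
  sm <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

#' Standardize, combine and re-smooth per-electrode signals
#'
#' Each electrode's smoothed signal is z-scored over all bins; zero-variance
#' (silent or constant) electrodes are dropped with a message; the remaining
#' signals are averaged across electrodes and smoothed again with the same
#' Gaussian kernel. The mean (rather than the sum) keeps the combined signal
#' invariant to the number of active electrodes.
#'
#' @param smoothed Numeric matrix, electrodes x bins, of already-smoothed
#'   per-electrode signals.
#' @param window,bin_width Kernel parameters, as in [gaussian_smooth()].
#' @return Combined smoothed numeric vector (length = bins).
#' @export
combine_standardized <- function(smoothed, window = 0.070, bin_width = 0.002) {
  sds <- apply(smoothed, 1, stats::sd)
  keep <- !is.na(sds) & sds > 0
  if (!any(keep)) stopf("no active electrodes")
  if (any(!keep)) {
    message(sprintf("dropping %d zero-variance electrode(s) from the combined signal",
                    sum(!keep)))
  }
  z <- (smoothed[keep, , drop = FALSE] -
          rowMeans(smoothed[keep, , drop = FALSE])) / sds[keep]
  combined <- colMeans(z)
  gaussian_smooth(combined, window, bin_width)
}

#' Otsu global threshold of a one-dimensional signal
#'
#' Histograms the signal into `n_bins` equal-width bins over its range and
#' returns the bin edge that maximizes the between-class variance
#' `w0*w1*(mu0-mu1)^2` of the two classes it induces (class means computed
#' from the actual signal values in each class). Deterministic; ties resolve
#' to the lowest edge.
#'
#' @param signal Numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins.
#' @return The threshold value; samples strictly above it are "high".
#' @export
otsu_threshold <- function(signal, n_bins = 256) {
  rng <- range(signal)
  if (!(rng[2] > rng[1])) stopf("signal is constant; no Otsu threshold exists")
  width <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((signal - rng[1]) / width) + 1L, n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  agg <- rowsum(signal, idx)  # per-bin sums of the actual values
  sums_full <- numeric(n_bins)
  sums_full[as.integer(rownames(agg))] <- agg[, 1]
  n <- length(signal)
  total <- sum(signal)
  c_cnt <- cumsum(cnt)[-n_bins]
  c_sum <- cumsum(sums_full)[-n_bins]
  w0 <- c_cnt / n
  w1 <- 1 - w0
  valid <- c_cnt > 0 & c_cnt < n
  mu0 <- c_sum / c_cnt
  mu1 <- (total - c_sum) / (n - c_cnt)
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv)  # first maximum -> lowest edge
  rng[1] + k * width
}

# Runs of TRUE in a logical vector -> half-open bin-index intervals.
runs_to_intervals <- function(flag, bin_width) {
  r <- rle(flag)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  sel <- r$values
  data.frame(
    start = (starts_idx[sel] - 1) * bin_width,
    end = ends_idx[sel] * bin_width
  )
}

#' Detect network bursts in a well
#'
#' Runs the full population-signal procedure (bin, smooth, standardize,
#' combine, Otsu) and applies the participation, duration and firing-rate
#' constraints. Returned intervals are bin-edge aligned, sorted and disjoint,
#' and not yet classified (see [classify_fragmented()]).
#'
#' @param rec A [spike_recording()].
#' @param params A [network_burst_params()].
#' @return Data frame `start, end, n_participating` (`n_participating` =
#'   electrodes with at least one spike inside the interval).
#' @export
detect_network_bursts <- function(rec, params = network_burst_params()) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_participating = integer(0))
  n_spikes <- sum(vapply(rec$spikes, length, integer(1)))
  if (n_spikes == 0) return(empty)
  counts <- bin_spikes(rec, params$bin_width)
  smoothed <- t(apply(counts, 1, gaussian_smooth,
                      window = params$gauss_window,
                      bin_width = params$bin_width))
  combined <- combine_standardized(smoothed, params$gauss_window,
                                   params$bin_width)
  thr <- otsu_threshold(combined, params$otsu_bins)
  cand <- runs_to_intervals(combined > thr, params$bin_width)
  if (!nrow(cand)) return(empty)

  n_el <- length(rec$spikes)
  keep <- logical(nrow(cand))
  n_part <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    counts_in <- vapply(rec$spikes, function(t) sum(t >= s & t < e), integer(1))
    part <- counts_in > 0
    n_part[i] <- sum(part)
    dur <- e - s
    if (n_part[i] < ceiling(params$min_participation * n_el)) next
    if (!(dur > params$min_duration)) next
    rates <- counts_in[part] / dur
    need <- ceiling(params$rate_fraction * n_part[i])
    if (sum(rates >= params$min_rate) < need) next
    keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  out$n_participating <- n_part[keep]
  rownames(out) <- NULL
  out
}

#' Classify network bursts as main or fragmented
#'
#' Left-to-right over the sorted, disjoint bursts: a burst lasting at least
#' `main_min_duration` is a main burst; a shorter burst is a fragment when
#' its gap to the preceding burst of the chain is at most `frag_max_gap`
#' (the chain is anchored at the nearest preceding burst classified main,
#' and fragments may chain through fragments). Short bursts with no
#' qualifying predecessor are kept as (short) mains and may themselves
#' anchor a subsequent chain.
#'
#' @param bursts Data frame from [detect_network_bursts()] (columns `start`,
#'   `end`, sorted, disjoint).
#' @param params A [network_burst_params()].
#' @return `bursts` with added columns `class` (`"main"`/`"fragment"`) and
#'   `anchor` (row index of the anchoring main burst; `NA` for mains).
#' @export
classify_fragmented <- function(bursts, params = network_burst_params()) {
  n <- nrow(bursts)
  cls <- character(n)
  anchor <- rep(NA_integer_, n)
  # chain state: index of the anchoring main and end of the chain's last burst
  chain_anchor <- NA_integer_
  chain_end <- -Inf
  for (i in seq_len(n)) {
    dur <- bursts$end[i] - bursts$start[i]
    if (dur >= params$main_min_duration) {
      cls[i] <- "main"
      chain_anchor <- i
      chain_end <- bursts$end[i]
    } else {
      ref_end <- if (params$chain_gap_mode == "main") {
        if (is.na(chain_anchor)) -Inf else bursts$end[chain_anchor]
      } else {
        chain_end
      }
      gap <- bursts$start[i] - ref_end
      if (!is.na(chain_anchor) && gap <= params$frag_max_gap) {
        cls[i] <- "fragment"
        anchor[i] <- chain_anchor
        chain_end <- bursts$end[i]
      } else {
        # isolated short burst: classified main, so it anchors from here on
        cls[i] <- "main"
        chain_anchor <- i
        chain_end <- bursts$end[i]
      }
    }
  }
  bursts$class <- cls
  bursts$anchor <- anchor
  bursts
}

#' Percentage of fragmented network bursts
#'
#' @param bursts Classified bursts from [classify_fragmented()].
#' @return `100 * fragments / (fragments + mains)`; `NA` when there are no
#'   bursts.
#' @export
fragmentation_percentage <- function(bursts) {
  if (!nrow(bursts)) return(NA_real_)
  100 * sum(bursts$class == "fragment") / nrow(bursts)
}

#' Detect and classify network bursts across wells
#'
#' @param recordings Named list of [spike_recording()].
#' @param params A [network_burst_params()].
#' @return Data frame `well_id, start, end, class, anchor, n_participating`
#'   (the canonical network-burst export format).
#' @export
detect_network_bursts_plate <- function(recordings,
                                        params = network_burst_params()) {
  rows <- lapply(recordings, function(rec) {
    nb <- classify_fragmented(detect_network_bursts(rec, params), params)
    if (!nrow(nb)) return(NULL)
    cbind(data.frame(well_id = rec$well_id, stringsAsFactors = FALSE),
          nb[, c("start", "end", "class", "anchor", "n_participating")])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(well_id = character(0), start = numeric(0),
                      end = numeric(0), class = character(0),
                      anchor = integer(0), n_participating = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
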