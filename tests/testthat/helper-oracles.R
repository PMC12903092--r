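# Independent brute-force oracles, written as literal rule application so the
# fast implementations can be checked against them on random instances.

# Electrode bursts: explicit left-to-right state machine.
oracle_electrode_bursts <- function(times, params) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  if (!length(times)) return(empty)
  groups <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] <= params$max_isi) {
      cur <- c(cur, t)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- t
    }
  }
  groups[[length(groups) + 1]] <- cur
  merged <- list(groups[[1]])
  for (g in groups[-1]) {
    prev <- merged[[length(merged)]]
    if (g[1] - prev[length(prev)] < params$merge_gap) {
      merged[[length(merged)]] <- c(prev, g)
    } else {
      merged[[length(merged) + 1]] <- g
    }
  }
  rows <- list()
  for (g in merged) {
    if (length(g) >= params$min_spikes &&
        (g[length(g)] - g[1]) > params$min_duration) {
      rows[[length(rows) + 1]] <- data.frame(
        start = g[1], end = g[length(g)], n_spikes = length(g))
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Otsu: exhaustive search over every histogram bin edge, classes formed from
# the actual data values on each side of the edge.
oracle_otsu <- function(signal, n_bins) {
  rng <- range(signal)
  width <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((signal - rng[1]) / width) + 1L, n_bins)
  best_k <- NA_integer_
  best_bcv <- -Inf
  n <- length(signal)
  for (k in seq_len(n_bins - 1)) {
    a <- signal[idx <= k]
    b <- signal[idx > k]
    if (!length(a) || !length(b)) next
    bcv <- (length(a) / n) * (length(b) / n) * (mean(a) - mean(b))^2
    if (bcv > best_bcv + 1e-15) {
      best_bcv <- bcv
      best_k <- k
    }
  }
  rng[1] + best_k * width
}

# Fragment classification: literal left-to-right rule application.
oracle_classify <- function(bursts, params) {
  n <- nrow(bursts)
  cls <- character(n)
  anchor <- rep(NA_integer_, n)
  last_main <- NA_integer_   # anchor of the open chain, NA if none
  last_end <- NA_real_       # end of the chain's latest burst
  for (i in seq_len(n)) {
    d <- bursts$end[i] - bursts$start[i]
    if (d >= params$main_min_duration) {
      cls[i] <- "main"
      last_main <- i
      last_end <- bursts$end[i]
    } else if (!is.na(last_main) &&
               bursts$start[i] - last_end <= params$frag_max_gap) {
      cls[i] <- "fragment"
      anchor[i] <- last_main
      last_end <- bursts$end[i]
    } else {
      cls[i] <- "main"
      last_main <- i
      last_end <- bursts$end[i]
    }
  }
  data.frame(class = cls, anchor = anchor, stringsAsFactors = FALSE)
}

# Random test-case generators -----------------------------------------------

random_spike_train <- function(n_max = 200) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(numeric(0))
  # mixture of clustered and scattered spikes so bursts actually occur
  n_clustered <- rbinom(1, n, 0.6)
  clustered <- if (n_clustered > 0) {
    centers <- runif(max(1, rpois(1, 4) + 1), 0, 60)
    sort(sample(centers, n_clustered, replace = TRUE) +
           abs(rnorm(n_clustered, 0, 0.05)))
  } else numeric(0)
  sort(c(clustered, runif(n - n_clustered, 0, 60)))
}

random_eb_params <- function() {
  max_isi <- runif(1, 0.02, 0.2)
  electrode_burst_params(
    max_isi = max_isi,
    min_spikes = sample(2:8, 1),
    min_duration = runif(1, 0.01, 0.1),
    merge_gap = runif(1, 0.005, max_isi)
  )
}

random_signal <- function() {
  n <- sample(50:500, 1)
  base <- rnorm(n, 0, 1)
  k <- sample(0:3, 1)
  for (i in seq_len(k)) {
    idx <- sample(n, max(2, round(n * runif(1, 0.05, 0.3))))
    base[idx] <- base[idx] + runif(1, 2, 10)
  }
  base
}

random_interval_list <- function() {
  n <- sample(0:25, 1)
  if (n == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  gaps <- runif(n, 0.05, 2.2)        # straddles the 1.1 s fragment gap
  durs <- ifelse(runif(n) < 0.5,
                 runif(n, 0.11, 0.31),   # short (fragment candidates)
                 runif(n, 0.33, 1.2))    # long (mains)
  start <- cumsum(gaps) + cumsum(c(0, durs[-n]))
  data.frame(start = start, end = start + durs)
}
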