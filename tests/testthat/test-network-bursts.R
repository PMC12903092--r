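test_that("binning uses half-open bins and conserves counts", {
  rec <- spike_recording("A1", list(R1C1 = 0.0, R1C2 = 0.002), duration = 1)
  m <- bin_spikes(rec, 0.002)
  expect_equal(unname(m["R1C1", 1]), 1L)  # t = 0 falls in bin 1
  expect_equal(unname(m["R1C2", 2]), 1L)  # a spike on the edge takes bin 2
  expect_equal(unname(m["R1C2", 1]), 0L)
  set.seed(1)
  t <- sort(round(runif(500, 0, 1) * 12500) / 12500)
  rec <- spike_recording("A1", list(R1C1 = t), duration = 1)
  expect_identical(sum(bin_spikes(rec, 0.002)["R1C1", ]), length(t))
})

test_that("gaussian smoothing preserves constants and matches dense convolution", {
  expect_equal(gaussian_smooth(rep(3, 200)), rep(3, 200))
  # unit impulse reproduces the symmetric, unit-sum kernel
  x <- c(rep(0, 100), 1, rep(0, 100))
  sm <- gaussian_smooth(x)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(sm[101 - 10], sm[101 + 10], tolerance = 1e-12)
  expect_equal(which.max(sm), 101L)
  # dense-matrix convolution oracle with explicit reflect padding
  set.seed(7)
  x <- rnorm(300)
  k <- exp(-((-17:17) * 0.002)^2 / (2 * (0.07 / 6)^2))
  k <- k / sum(k)
  padded <- c(x[18:2], x, x[299:283])
  oracle <- vapply(seq_along(x), function(i) {
    sum(padded[i:(i + 34)] * k)
  }, numeric(1))
  expect_equal(gaussian_smooth(x), oracle, tolerance = 1e-9)
})

test_that("standardized combination drops silent electrodes and centers", {
  set.seed(8)
  m <- t(vapply(1:16, function(i) gaussian_smooth(rpois(2000, 0.2)),
                numeric(2000)))
  full <- combine_standardized(m)
  # one silent electrode among 16 changes nothing
  m2 <- rbind(m, 0)
  expect_equal(suppressMessages(combine_standardized(m2)), full)
  expect_error(combine_standardized(matrix(0, 4, 100)), "no active electrodes")
  # directly computed z-score mean: centered before re-smoothing, and the
  # combined output is exactly that mean re-smoothed
  zm <- colMeans((m - rowMeans(m)) / apply(m, 1, sd))
  expect_lt(abs(mean(zm)), 1e-9)
  expect_equal(full, gaussian_smooth(zm), tolerance = 1e-12)
})

test_that("otsu threshold separates classes and matches the exhaustive oracle", {
  x <- c(rep(0, 900), rep(10, 100))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0)
  expect_lt(thr, 10)
  expect_error(otsu_threshold(rep(1, 50)), "constant")
  set.seed(31)
  for (i in 1:100) {
    s <- random_signal()
    nb <- sample(2:64, 1)
    expect_equal(otsu_threshold(s, nb), oracle_otsu(s, nb),
                 tolerance = 1e-12)
  }
  # affine invariance up to one bin width
  s <- random_signal()
  t0 <- otsu_threshold(s, 64)
  t1 <- otsu_threshold(3 * s + 2, 64)
  bin_w <- diff(range(3 * s + 2)) / 64
  expect_lt(abs(t1 - (3 * t0 + 2)), bin_w + 1e-9)
})

test_that("network burst detection recovers a planted burst", {
  expect_identical(nrow(detect_network_bursts(spike_recording("A1"))), 0L)
  # 12/16 electrodes firing 100 Hz for 0.4 s over faint background
  set.seed(17)
  tick <- 1 / 12500
  spikes <- lapply(1:16, function(e) {
    bg <- runif(rpois(1, 0.1 * 300), 0, 300)
    t <- if (e <= 12) c(bg, runif(40, 100, 100.4)) else bg
    sort(unique(round(t / tick) * tick))
  })
  names(spikes) <- electrode_ids()
  rec <- spike_recording("A1", spikes)
  nb <- detect_network_bursts(rec)
  expect_identical(nrow(nb), 1L)
  expect_lt(abs(nb$start - 100), 0.070)
  expect_lt(abs(nb$end - 100.4), 0.070)
  expect_gte(nb$n_participating, 12L)
  # with only 2/16 electrodes participating the burst is rejected
  spikes2 <- lapply(1:16, function(e) {
    t <- if (e <= 2) runif(60, 100, 100.4) else runif(2, 0, 300)
    sort(unique(round(t / tick) * tick))
  })
  names(spikes2) <- electrode_ids()
  nb2 <- detect_network_bursts(spike_recording("A1", spikes2))
  expect_false(any(nb2$start < 100.4 & nb2$end > 100))
})

test_that("fragment classification follows the chain rule", {
  p <- network_burst_params()
  nb <- data.frame(start = c(0, 1.0), end = c(0.5, 1.2))
  out <- classify_fragmented(nb, p)
  expect_identical(out$class, c("main", "fragment"))
  expect_identical(out$anchor, c(NA_integer_, 1L))
  # a 1.3 s gap breaks the chain
  nb <- data.frame(start = c(0, 1.8), end = c(0.5, 2.0))
  expect_identical(classify_fragmented(nb, p)$class, c("main", "main"))
  # fragments chain through fragments, all anchored at the main
  nb <- data.frame(start = c(0, 1.0, 2.2), end = c(0.5, 1.2, 2.4))
  out <- classify_fragmented(nb, p)
  expect_identical(out$class, c("main", "fragment", "fragment"))
  expect_identical(out$anchor, c(NA_integer_, 1L, 1L))
  # measuring the gap to the main instead breaks the second fragment
  p_main <- network_burst_params(chain_gap_mode = "main")
  out2 <- classify_fragmented(nb, p_main)
  expect_identical(out2$class, c("main", "fragment", "main"))
  # boundary: duration exactly 0.32 s is a main; gap exactly 1.1 s qualifies
  nb <- data.frame(start = c(0, 1.42), end = c(0.32, 1.62))
  out <- classify_fragmented(nb, p)
  expect_identical(out$class, c("main", "fragment"))
})

test_that("classification matches the left-to-right oracle on random lists", {
  set.seed(47)
  p <- network_burst_params()
  for (i in 1:200) {
    iv <- random_interval_list()
    got <- classify_fragmented(iv, p)
    want <- oracle_classify(iv, p)
    expect_identical(got$class, want$class)
    expect_identical(got$anchor, want$anchor)
  }
})

test_that("fragmentation percentage counts fragments over all bursts", {
  nb <- data.frame(start = 1:10, end = 1:10 + 0.5,
                   class = rep("main", 10), anchor = NA_integer_)
  expect_equal(fragmentation_percentage(nb), 0)
  nb$class[1:5] <- "fragment"
  expect_equal(fragmentation_percentage(nb), 50)
  expect_true(is.na(fragmentation_percentage(nb[0, ])))
})

test_that("detected intervals are sorted and disjoint", {
  for (s in 1:5) {
    cfg <- simulation_config(nb_rate = 8, frag_prob = 0.5, seed = s,
                             in_burst_rate = 50, duration = 120)
    rec <- simulate_well(cfg)$recording
    nb <- detect_network_bursts(rec)
    if (nrow(nb) > 1) {
      expect_true(all(diff(nb$start) > 0))
      expect_true(all(nb$start[-1] >= nb$end[-nrow(nb)]))
    }
  }
})

test_that("doubling the in-burst rate never loses planted bursts", {
  # the monotone quantity is recall of planted mains: a weaker burst can be
  # over-segmented (raising the raw count) but never better recovered
  recall <- function(sim) {
    det <- classify_fragmented(detect_network_bursts(sim$recording))
    score_burst_recovery(sim$truth, det)$recall_main
  }
  for (s in 1:3) {
    lo <- simulate_well(simulation_config(nb_rate = 6, in_burst_rate = 20,
                                          seed = s, duration = 120))
    hi <- simulate_well(simulation_config(nb_rate = 6, in_burst_rate = 40,
                                          seed = s, duration = 120))
    expect_gte(recall(hi), recall(lo))
  }
})
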