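test_that("duration pooling keeps main bursts only", {
  nb <- data.frame(
    well_id = c("A1", "A1", "A1", "A2", "A2"),
    start = c(0, 10, 11, 5, 20),
    end = c(0.5, 10.4, 11.2, 5.6, 20.2),
    class = c("main", "main", "fragment", "main", "fragment")
  )
  expect_equal(pool_durations(nb), c(0.5, 0.4, 0.6))
  expect_equal(pool_durations(nb, wells = "A2"), 0.6)
  expect_warning(d <- pool_durations(nb[nb$class == "fragment", ]), "no main")
  expect_length(d, 0)
})

test_that("the exceedance threshold is the max of group nearest-rank quantiles", {
  # uniform 1..1000 ms grid: the 97.5th nearest-rank percentile is 975 ms
  grid <- seq(0.001, 1, by = 0.001)
  expect_equal(basal_exceedance_threshold(list(g = grid)), 0.975)
  two <- list(a = seq(0.01, 0.40, length.out = 200),
              b = seq(0.01, 0.60, length.out = 200))
  thr <- basal_exceedance_threshold(two)
  expect_equal(thr, nearest_75 <- sort(two$b)[ceiling(0.975 * 200)])
  expect_gte(thr, basal_exceedance_threshold(two["a"]))
  expect_error(basal_exceedance_threshold(list(a = grid, b = numeric(0))),
               "empty basal sample.*b")
  # log-normal sample: close to the analytic 97.5th percentile
  set.seed(12)
  x <- rlnorm(2000, meanlog = log(0.3), sdlog = 0.4)
  thr <- basal_exceedance_threshold(list(g = x))
  expect_lt(abs(thr - qlnorm(0.975, log(0.3), 0.4)) /
              qlnorm(0.975, log(0.3), 0.4), 0.05)
})

test_that("basal exceedance never exceeds the tail in any group", {
  set.seed(77)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    samples <- lapply(seq_len(k), function(j) {
      rlnorm(sample(50:500, 1), log(runif(1, 0.2, 0.6)), runif(1, 0.2, 0.6))
    })
    names(samples) <- paste0("g", seq_len(k))
    thr <- basal_exceedance_threshold(samples)
    for (s in samples) expect_lte(exceedance_fraction(s, thr), 2.5)
  }
})

test_that("the threshold is monotone in the basal data", {
  set.seed(5)
  x <- list(a = rlnorm(300, log(0.3), 0.3), b = rlnorm(300, log(0.4), 0.3))
  t0 <- basal_exceedance_threshold(x)
  x$a <- c(x$a, max(unlist(x)) + 1)
  expect_gte(basal_exceedance_threshold(x), t0)
})

test_that("exceedance fractions count strict exceedances", {
  expect_equal(exceedance_fraction(c(0.1, 0.2, 0.9), 0.625), 100 / 3)
  expect_equal(exceedance_fraction(c(0.1, 0.2), 0.625), 0)
  expect_error(exceedance_fraction(numeric(0), 0.625), "empty")
  # a +0.5 s shift: exceedance matches the analytic tail within 3 SE
  set.seed(31)
  thr <- 0.625
  treated <- rlnorm(2000, log(0.3), 0.35) + 0.5
  p_true <- 1 - plnorm(thr - 0.5, log(0.3), 0.35)
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(exceedance_fraction(treated, thr) / 100 - p_true), 3 * se)
})

test_that("duration distributions compare via the rank-sum test", {
  x <- c(0.3, 0.4, 0.5, 0.6)
  p_same <- compare_duration_distributions(x, x)$p_value
  expect_gte(p_same, 0.99)
  set.seed(9)
  a <- runif(50, 0, 1)
  b <- runif(50, 5, 6)
  expect_lt(compare_duration_distributions(a, b)$p_value, 1e-6)
  # statistic equals an independent rank computation
  a <- rnorm(40); b <- rnorm(35, 0.5)
  w <- compare_duration_distributions(a, b)$statistic
  r <- rank(c(a, b))
  expect_equal(w, sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2)
  expect_error(compare_duration_distributions(a, numeric(0)), "empty")
})

test_that("paired firing-rate changes use active-electrode MFR", {
  pre <- spike_recording("A1", list(R1C1 = seq(0.5, 299.5, by = 1)))
  post <- spike_recording("A1")
  out <- firing_rate_change(pre, post)
  expect_equal(out$mfr_pre, 1)       # 300 spikes / (1 electrode x 300 s)
  expect_equal(out$mfr_post, 0)
  expect_identical(out$n_active_post, 0L)
  expect_error(firing_rate_change(pre, spike_recording("B2")), "different wells")
  # doubling the simulated rate roughly doubles the paired MFR
  set.seed(4)
  ratios <- vapply(1:10, function(s) {
    r_pre <- simulate_well(simulation_config(background_rate = 1, nb_rate = 0,
                                             seed = s))$recording
    r_post <- simulate_well(simulation_config(background_rate = 2, nb_rate = 0,
                                              seed = 1000 + s))$recording
    r_post$well_id <- r_pre$well_id
    out <- firing_rate_change(r_pre, r_post)
    out$mfr_post / out$mfr_pre
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2) / 2, 0.1)
})
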