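test_that("silent configurations give empty recordings and truth", {
  cfg <- simulation_config(background_rate = 0, nb_rate = 0, seed = 3)
  sim <- simulate_well(cfg)
  expect_identical(sum(lengths(sim$recording$spikes)), 0L)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("identical seeds reproduce identical wells", {
  cfg <- simulation_config(nb_rate = 5, frag_prob = 0.5, seed = 42,
                           n_electrodes = 8, duration = 120)
  a <- simulate_well(cfg)
  b <- simulate_well(cfg)
  expect_identical(a$recording$spikes, b$recording$spikes)
  expect_identical(a$truth, b$truth)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(background_rate = -1), "non-negative")
  expect_error(simulation_config(participation_prob = 1.5), "probabilities")
  expect_error(simulation_config(frag_duration_range = c(0.05, 0.2)),
               "frag_duration_range")
  expect_error(simulation_config(frag_gap_range = c(0.5, 1.5)),
               "frag_gap_range")
})

test_that("planted ground truth satisfies the fragment constraints", {
  for (s in 1:20) {
    cfg <- simulation_config(nb_rate = 8, frag_prob = 0.7,
                             frag_count_mean = 2, seed = s,
                             n_electrodes = 2, background_rate = 0,
                             in_burst_rate = 5)
    tru <- simulate_well(cfg)$truth
    frag <- tru[tru$class == "fragment", ]
    expect_true(all(frag$end - frag$start < 0.32))
    expect_true(all(!is.na(frag$anchor)))
    # each fragment starts within 1.1 s of the preceding burst of its chain
    for (i in which(tru$class == "fragment")) {
      expect_lte(tru$start[i] - tru$end[i - 1], 1.1)
      expect_gt(tru$start[i], tru$end[i - 1])
    }
    # intervals disjoint and sorted
    if (nrow(tru) > 1) {
      expect_true(all(diff(tru$start) > 0))
      expect_true(all(tru$start[-1] >= tru$end[-nrow(tru)]))
    }
  }
})

test_that("planted burst counts match the renewal-process expectation", {
  # nb_rate = 2/min over 300 s plants ~10 mains; average over 50 seeds
  counts <- vapply(1:50, function(s) {
    cfg <- simulation_config(nb_rate = 2, background_rate = 0,
                             in_burst_rate = 1, n_electrodes = 1, seed = s)
    sum(simulate_well(cfg)$truth$class == "main")
  }, numeric(1))
  expect_gte(mean(counts), 8)
  expect_lte(mean(counts), 12)
})

test_that("planted inter-onset gaps hit the target CoV", {
  for (target in c(0.2, 0.6)) {
    gaps <- unlist(lapply(1:20, function(s) {
      cfg <- simulation_config(nb_rate = 6, ibi_cov = target,
                               background_rate = 0, in_burst_rate = 1,
                               n_electrodes = 1, seed = 1000 + s)
      tru <- simulate_well(cfg)$truth
      diff(tru$start[tru$class == "main"])
    }))
    cov_hat <- sd(gaps) / mean(gaps)
    expect_lt(abs(cov_hat - target) / target, 0.15)
  }
})

test_that("background-only firing rate matches the configured rate", {
  cfg <- simulation_config(background_rate = 2, nb_rate = 0,
                           n_electrodes = 16, seed = 77)
  rec <- simulate_well(cfg)$recording
  n <- sum(lengths(rec$spikes))
  lambda <- 2 * 16 * 300
  expect_lt(abs(n - lambda) / sqrt(lambda), 3)
})

test_that("plates carry group labels and are seed-deterministic", {
  groups <- list(ctrl = simulation_config(n_electrodes = 4, duration = 60),
                 mut = simulation_config(n_electrodes = 4, duration = 60,
                                         frag_prob = 0.5))
  p1 <- simulate_plate(groups, wells_per_group = 3, seed = 8)
  p2 <- simulate_plate(groups, wells_per_group = 3, seed = 8)
  expect_length(p1$recordings, 6)
  labs <- vapply(p1$recordings, function(r) r$metadata$group, character(1))
  expect_identical(as.integer(table(labs)[c("ctrl", "mut")]), c(3L, 3L))
  expect_identical(lapply(p1$recordings, `[[`, "spikes"),
                   lapply(p2$recordings, `[[`, "spikes"))
  expect_warning(empty <- simulate_plate(groups, wells_per_group = 0),
                 "empty plate")
  expect_length(empty$recordings, 0)
})

test_that("development trajectories apply overrides per DIV", {
  base <- simulation_config(nb_rate = 6, nb_duration_mean = 0.9,
                            nb_duration_sd = 0.1, background_rate = 0,
                            in_burst_rate = 1, n_electrodes = 1)
  traj <- list(div35 = list(), div42 = list(nb_duration_mean = 0.6),
               div49 = list(nb_duration_mean = 0.45))
  dev <- simulate_development(base, traj, wells_per_div = 10, seed = 4)
  mean_dur <- vapply(dev, function(p) {
    m <- p$truth[p$truth$class == "main", ]
    mean(m$end - m$start)
  }, numeric(1))
  expect_true(all(diff(mean_dur) < 0))
  expect_error(simulate_development(base, list(d = list(nope = 1))),
               "unknown simulation_config field")
})
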