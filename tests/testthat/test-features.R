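toy_fixture <- function() {
  dir <- system.file("extdata", "toy_well", package = "meaburst")
  list(
    rec = read_spike_table(file.path(dir, "spikes.csv"),
                           file.path(dir, "spikes_manifest.yaml"))[["A1"]],
    ebursts = utils::read.csv(file.path(dir, "electrode_bursts.csv"),
                              stringsAsFactors = FALSE),
    nbursts = utils::read.csv(file.path(dir, "network_bursts.csv"),
                              stringsAsFactors = FALSE),
    expected = utils::read.csv(file.path(dir, "expected_features.csv"),
                               stringsAsFactors = FALSE)
  )
}

test_that("the catalogue defines 39 uniquely named parameters", {
  cat39 <- feature_catalogue()
  expect_identical(nrow(cat39), 39L)
  expect_false(anyDuplicated(cat39$name) > 0)
  expect_setequal(unique(cat39$group),
                  c("spike", "electrode_burst", "network_burst",
                    "fragmentation"))
})

test_that("every catalogue parameter matches the hand-derived toy well", {
  fx <- toy_fixture()
  fv <- extract_features(fx$rec, fx$ebursts, fx$nbursts)
  expect_setequal(names(fv), fx$expected$name)
  for (i in seq_len(nrow(fx$expected))) {
    got <- unname(fv[fx$expected$name[i]])
    want <- fx$expected$value[i]
    if (is.na(want)) {
      expect_true(is.na(got), label = fx$expected$name[i])
    } else {
      expect_equal(got, want, tolerance = 1e-9,
                   label = fx$expected$name[i])
    }
  }
})

test_that("headline definitions are forced by construction", {
  rec <- spike_recording("A1", list(R1C1 = c(0.5, 10.5, 20.5)))
  # exactly 3 main bursts in 300 s -> frequency 3 per 5 min
  nb <- data.frame(start = c(0, 10, 20), end = c(1, 11, 21),
                   class = "main", anchor = NA_integer_)
  eb <- data.frame(electrode_id = character(0), start = numeric(0),
                   end = numeric(0), n_spikes = integer(0))
  fv <- extract_features(rec, eb, nb)
  expect_equal(unname(fv["nb_rate"]), 3)
  # equal IBIs (9 s each) -> CoV 0
  expect_equal(unname(fv["nb_ibi_mean"]), 9)
  expect_equal(unname(fv["nb_ibi_cov"]), 0)
  # mismatched well ids are rejected
  nb_bad <- cbind(well_id = "B2", nb)
  expect_error(extract_features(rec, eb, nb_bad), "different well")
})

test_that("fragments never influence main-burst parameters", {
  cfg <- simulation_config(nb_rate = 6, frag_prob = 0.6, in_burst_rate = 50,
                           frag_count_mean = 1.5, seed = 5, duration = 120)
  sim <- simulate_well(cfg)
  eb <- detect_electrode_bursts_well(sim$recording)
  nb <- classify_fragmented(detect_network_bursts(sim$recording))
  expect_gt(sum(nb$class == "fragment"), 0)
  with_frag <- extract_features(sim$recording, eb, nb)
  without <- extract_features(sim$recording, eb,
                              nb[nb$class == "main", , drop = FALSE])
  main_params <- feature_catalogue()$name[
    feature_catalogue()$group == "network_burst"]
  expect_equal(with_frag[main_params], without[main_params])
})

test_that("percentage parameters stay within [0, 100]", {
  pct <- c("burst_pct_mean", "nb_pct", "frag_pct", "nb_participation_mean")
  for (s in 1:5) {
    cfg <- simulation_config(nb_rate = sample(2:10, 1), seed = s,
                             frag_prob = runif(1), duration = 120,
                             background_rate = runif(1, 0, 2))
    sim <- simulate_well(cfg)
    fv <- extract_features(
      sim$recording,
      detect_electrode_bursts_well(sim$recording),
      classify_fragmented(detect_network_bursts(sim$recording))
    )
    vals <- fv[pct]
    expect_true(all(is.na(vals) | (vals >= 0 & vals <= 100)))
  }
})

test_that("feature tables aggregate with metadata and survive CSV round trips", {
  fx <- toy_fixture()
  fv <- extract_features(fx$rec, fx$ebursts, fx$nbursts)
  silent <- spike_recording("B1")
  fv_silent <- extract_features(
    silent,
    data.frame(electrode_id = character(0), start = numeric(0),
               end = numeric(0), n_spikes = integer(0)),
    data.frame(start = numeric(0), end = numeric(0), class = character(0),
               anchor = integer(0))
  )
  md <- data.frame(well_id = c("A1", "B1"), group = c("pat", "ctrl"))
  tab <- aggregate_table(list(A1 = fv, B1 = fv_silent), md)
  expect_identical(nrow(tab), 2L)
  expect_true(is.na(tab$nb_duration_mean[tab$well_id == "B1"]))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back$nb_duration_mean, tab$nb_duration_mean)
  expect_equal(back$frag_pct, tab$frag_pct)
  md_bad <- rbind(md, md[1, ])
  expect_error(aggregate_table(list(A1 = fv, B1 = fv_silent), md_bad),
               "duplicate")
})

test_that("normalization maps the control mean to 1", {
  tab <- data.frame(group = c("ctrl", "ctrl", "pat"), x = c(2, 2, 3))
  norm <- normalize_to_control(tab, "x", tab$group == "ctrl")
  expect_equal(norm, c(1, 1, 1.5))
  expect_equal(mean(norm[tab$group == "ctrl"]), 1)
  tab$x <- c(0, 0, 3)
  expect_error(normalize_to_control(tab, "x", tab$group == "ctrl"), "zero")
})
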