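# Provenance of this fixture: rebuilds spikes.csv, the burst tables and
# expected_features.csv from hand-listed intermediates only.
# Build the hand-derived toy-well fixture. Every expected value below is
# computed from hand-listed intermediates (spike lists, burst tables, ISI
# lists), never from package code.
dir <- "."  # run from inst/extdata/toy_well

e1 <- c(10.000,10.050,10.100,10.150,10.200,10.250,
        20.000,20.080,20.160,20.240,20.320,
        50.000,100.000,200.000)
e2 <- c(10.020,10.060,10.100,10.140,10.180,10.220,10.260,10.300,
        150.000,150.050,150.100,150.150,
        250.000)
stopifnot(all(abs(c(e1,e2)*12500 - round(c(e1,e2)*12500)) < 1e-9))

spikes <- data.frame(
  well_id = "A1",
  electrode_id = c(rep("R1C1", length(e1)), rep("R1C2", length(e2))),
  time_s = sprintf("%.7f", c(e1, e2)))
write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE, quote = FALSE)
writeLines(c("duration_s: 300.0",
             "sampling_rate_hz: 12500.0",
             "wells:",
             "  A1:",
             "    line: toy",
             "    group: toy"), file.path(dir, "spikes_manifest.yaml"))

eb <- data.frame(well_id = "A1",
                 electrode_id = c("R1C1","R1C1","R1C2"),
                 start = c(10.000, 20.000, 10.020),
                 end   = c(10.250, 20.320, 10.300),
                 n_spikes = c(6L, 5L, 8L))
write.csv(eb, file.path(dir, "electrode_bursts.csv"), row.names = FALSE)

nb <- data.frame(well_id = "A1",
                 start = c(9.980, 19.960, 21.000, 22.000),
                 end   = c(10.340, 20.360, 21.200, 22.100),
                 class = c("main","main","fragment","fragment"),
                 anchor = c(NA, NA, 2L, 2L),
                 n_participating = c(2L, 1L, 1L, 1L))
write.csv(nb, file.path(dir, "network_bursts.csv"), row.names = FALSE)

# ---- hand-derived expected features ----
fr <- c(14, 13) / 300
isi_e1 <- c(rep(0.05, 5), 9.75, rep(0.08, 4), 29.68, 50, 100)   # 13 gaps
isi_e2 <- c(rep(0.04, 7), 139.70, rep(0.05, 3), 99.85)          # 12 gaps
isis <- c(isi_e1, isi_e2)
isi_within_e1 <- c(rep(0.05, 5), rep(0.08, 4))  # pooled over e1's 2 bursts
isi_within_e2 <- rep(0.04, 7)
isi_within_means <- c(mean(isi_within_e1), mean(isi_within_e2))
burst_pct <- c(100 * 11 / 14, 100 * 8 / 13)
eb_dur <- c(0.25, 0.32, 0.28)
spb <- c(6, 5, 8)
nb_dur <- c(0.36, 0.40)
nb_spikes_in <- c(14, 5)          # NB1: 6 (e1) + 8 (e2); NB2: 5 (e1)
nb_part_pct <- 100 * c(2, 1) / 16
nb_fr <- nb_spikes_in / (c(2, 1) * nb_dur)
frag_dur <- c(0.20, 0.10)
frag_gap <- c(21.000 - 20.360, 22.000 - 21.200)

expected <- c(
  firing_rate_mean = mean(fr), firing_rate_sd = sd(fr),
  firing_rate_cov = sd(fr) / mean(fr),
  n_spikes = 27, n_active_electrodes = 2,
  isi_mean = mean(isis), isi_sd = sd(isis), isi_cov = sd(isis) / mean(isis),
  eb_rate_mean = mean(c(2, 1) / 5),
  eb_duration_mean = mean(eb_dur), eb_duration_sd = sd(eb_dur),
  eb_duration_cov = sd(eb_dur) / mean(eb_dur),
  eb_isi_within_mean = mean(isi_within_means),
  eb_isi_within_sd = sd(isi_within_means),
  eb_isi_within_cov = sd(isi_within_means) / mean(isi_within_means),
  burst_pct_mean = mean(burst_pct), burst_pct_sd = sd(burst_pct),
  eb_ibi_mean = 20.000 - 10.250, eb_ibi_sd = NA, eb_ibi_cov = NA,
  spikes_per_burst_mean = mean(spb), spikes_per_burst_sd = sd(spb),
  nb_rate = 2,
  nb_duration_mean = mean(nb_dur), nb_duration_sd = sd(nb_dur),
  nb_duration_cov = sd(nb_dur) / mean(nb_dur),
  nb_ibi_mean = 19.960 - 10.340, nb_ibi_sd = NA, nb_ibi_cov = NA,
  nb_pct = 100 * 19 / 27,
  nb_participation_mean = mean(nb_part_pct),
  nb_participation_sd = sd(nb_part_pct),
  nb_firing_rate_mean = mean(nb_fr), nb_firing_rate_sd = sd(nb_fr),
  frag_pct = 50,
  frag_duration_mean = mean(frag_dur), frag_duration_sd = sd(frag_dur),
  frag_gap_mean = mean(frag_gap),
  frags_per_main_mean = 1
)
out <- data.frame(name = names(expected),
                  value = sprintf("%.15g", expected))
write.csv(out, file.path(dir, "expected_features.csv"),
          row.names = FALSE, quote = FALSE)
cat(nrow(out), "expected parameters written\n")
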