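# End-to-end orchestration: simulate (or ingest) a plate, detect electrode
# and network bursts, extract the feature table, optionally fingerprint and
# run the duration analyses, and write all outputs under one directory. All
# randomness flows from the master seed through stage-scoped derived seeds,
# so a given configuration and seed always reproduce byte-identical outputs.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a plate from `groups`) or `"ingest"`
#'   (read `spike_table`/`manifest`).
#' @param groups Named list of [simulation_config()] (simulate mode).
#' @param wells_per_group Wells per group (simulate mode).
#' @param spike_table,manifest Paths to the canonical spike CSV and manifest
#'   (ingest mode).
#' @param electrode_params An [electrode_burst_params()].
#' @param network_params A [network_burst_params()].
#' @param fingerprint_config A [fingerprint_config()].
#' @param run_fingerprint,run_distributions Stage toggles.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            groups = NULL, wells_per_group = 4,
                            spike_table = NULL, manifest = NULL,
                            electrode_params = electrode_burst_params(),
                            network_params = network_burst_params(),
                            fingerprint_config = meaburst::fingerprint_config(),
                            run_fingerprint = TRUE,
                            run_distributions = TRUE,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(groups)) {
    stopf("simulate mode needs a named list of simulation configs in 'groups'")
  }
  if (mode == "ingest") {
    if (is.null(spike_table) || !file.exists(spike_table)) {
      stopf("ingest mode needs an existing spike_table path")
    }
    if (!is.null(manifest) && !file.exists(manifest)) {
      stopf("manifest path %s does not exist", manifest)
    }
  }
  structure(
    list(mode = mode, groups = groups, wells_per_group = wells_per_group,
         spike_table = spike_table, manifest = manifest,
         electrode_params = electrode_params,
         network_params = network_params,
         fingerprint_config = fingerprint_config,
         run_fingerprint = isTRUE(run_fingerprint),
         run_distributions = isTRUE(run_distributions),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: input (simulate or ingest), electrode-burst detection, network
#' burst detection + fragmentation classification, feature extraction,
#' optional fingerprint (PCA, retained PCs, UMAP when enough wells), and
#' optional duration analysis (pooled main-burst durations per group plus the
#' basal exceedance threshold). A stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (named list), invisibly written to
#'   `run_manifest.json`: package version, config hash, seed, per-stage
#'   output paths and processing notes.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  notes <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # input -------------------------------------------------------------------
  recordings <- stage("input", {
    if (config$mode == "simulate") {
      plate <- simulate_plate(config$groups, config$wells_per_group,
                              seed = derive_seed(config$seed, 1L))
      outputs["spikes"] <- write_spike_table(
        plate$recordings, file.path(out_dir, "spikes.csv"))
      outputs["ground_truth"] <- write_csv_out(plate$truth, out_dir,
                                                "ground_truth.csv")
      plate$recordings
    } else {
      read_spike_table(config$spike_table, config$manifest)
    }
  })

  # detection ---------------------------------------------------------------
  ebursts <- stage("electrode_bursts", {
    tabs <- lapply(recordings, detect_electrode_bursts_well,
                   params = config$electrode_params)
    do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  })
  outputs["electrode_bursts"] <- write_csv_out(ebursts, out_dir,
                                               "electrode_bursts.csv")

  nbursts <- stage("network_bursts", {
    detect_network_bursts_plate(recordings, config$network_params)
  })
  outputs["network_bursts"] <- write_csv_out(nbursts, out_dir,
                                             "network_bursts.csv")

  # features ----------------------------------------------------------------
  features <- stage("features", {
    fv <- lapply(recordings, function(rec) {
      extract_features(
        rec,
        ebursts[ebursts$well_id == rec$well_id, , drop = FALSE],
        nbursts[nbursts$well_id == rec$well_id, , drop = FALSE],
        config$electrode_params
      )
    })
    md <- data.frame(
      well_id = names(recordings),
      group = vapply(recordings, function(r) {
        as.character(r$metadata$group %||% "unspecified")
      }, character(1)),
      stringsAsFactors = FALSE
    )
    aggregate_table(fv, md)
  })
  outputs["features"] <- write_csv_out(features, out_dir, "features.csv")

  # fingerprint -------------------------------------------------------------
  if (config$run_fingerprint) {
    stage("fingerprint", {
      fpc <- config$fingerprint_config
      sub <- features[, feature_catalogue()$name, drop = FALSE]
      # parameters undefined on most wells (e.g. fragmentation statistics in
      # a fragment-free group) would take every row down with them under
      # row-wise deletion; drop parameters missing on half or more wells first
      mostly_na <- colMeans(is.na(sub)) >= 0.5
      if (any(mostly_na)) {
        notes <- c(notes, sprintf(
          "fingerprint: dropped %d mostly-missing parameter(s): %s",
          sum(mostly_na), paste(names(sub)[mostly_na], collapse = ", ")))
        sub <- sub[, !mostly_na, drop = FALSE]
      }
      n_complete <- sum(stats::complete.cases(sub))
      if (n_complete < 4) {
        notes <- c(notes, "fingerprint skipped: fewer than 4 complete wells")
      } else {
        fpc$umap_neighbors <- min(fpc$umap_neighbors, n_complete - 1)
        fp <- suppressMessages(fingerprint(sub, fpc))
        outputs["loadings"] <- write_csv_out(
          data.frame(parameter = fp$pca$params, fp$pca$loadings),
          out_dir, "loadings.csv")
        outputs["explained_variance"] <- write_csv_out(
          data.frame(pc = seq_along(fp$pca$explained),
                     explained_ratio = fp$pca$explained,
                     retained = seq_along(fp$pca$explained) %in% fp$retained),
          out_dir, "explained_variance.csv")
        if (!is.null(fp$embedding)) {
          outputs["embedding"] <- write_csv_out(
            data.frame(well_id = rownames(fp$pca$scores) %||%
                         seq_len(nrow(fp$embedding)),
                       umap1 = fp$embedding[, 1], umap2 = fp$embedding[, 2]),
            out_dir, "embedding.csv")
        }
        if (!is.null(fp$sets)) {
          sel_path <- file.path(out_dir, "selected_parameters.json")
          jsonlite::write_json(fp$sets, sel_path, auto_unbox = FALSE,
                               pretty = TRUE)
          outputs["selected_parameters"] <- sel_path
        }
      }
    })
  }

  # distributions -----------------------------------------------------------
  if (config$run_distributions) {
    stage("distributions", {
      if (!nrow(nbursts)) {
        notes <- c(notes, "distribution analysis skipped: no network bursts")
      } else {
        groups <- vapply(recordings, function(r) {
          as.character(r$metadata$group %||% "unspecified")
        }, character(1))
        dur_rows <- lapply(unique(groups), function(g) {
          d <- suppressWarnings(
            pool_durations(nbursts, wells = names(groups)[groups == g]))
          if (!length(d)) return(NULL)
          data.frame(group = g, condition = "basal", duration_s = d,
                     stringsAsFactors = FALSE)
        })
        dur_rows <- dur_rows[!vapply(dur_rows, is.null, logical(1))]
        durations <- do.call(rbind, c(dur_rows, list(make.row.names = FALSE)))
        outputs["durations"] <- write_csv_out(durations, out_dir,
                                               "durations.csv")
        samples <- split(durations$duration_s, durations$group)
        thr <- basal_exceedance_threshold(samples)
        report <- list(
          threshold_s = thr,
          basal_exceedance_pct = lapply(samples, exceedance_fraction,
                                        threshold = thr)
        )
        rep_path <- file.path(out_dir, "exceedance_report.json")
        jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        outputs["exceedance_report"] <- rep_path
      }
    })
  }

  # manifest ----------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest <- list(
    package = "meaburst",
    version = as.character(utils::packageVersion("meaburst")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    outputs = as.list(outputs),
    notes = notes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Flatten a pipeline_config into plain lists for hashing/serialization.
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}
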