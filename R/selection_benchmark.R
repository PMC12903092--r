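# Planted-structure benchmark for the stable/variable parameter-selection
# chain. Because every column is z-scored before PCA, "stability" cannot be
# planted as low raw variance; what places a parameter on the trailing PCs of
# a correlation-matrix PCA is redundancy. The generator therefore plants, in
# the rescue datasets, two moderately correlated parameter pairs whose minor
# (difference) directions are the smallest retained eigenvalues - the
# least-variance retained directions - while in the patient dataset two
# 10-parameter factor blocks (one driven by a two-group contrast) dominate
# PC1 and PC2. Running the chain (top-k loadings, stable-across-rescues,
# exclusive overlay) on these tables must recover exactly the planted
# stable-only parameters.

#' Simulate feature tables with planted variable and stable parameters
#'
#' Generates one "patient" table and two "rescue" tables over the same 24
#' parameters: `varA01..varA10` (a block driven by a two-group mean shift in
#' the patient table), `varB01..varB10` (a block driven by a shared latent
#' factor), and `stab1..stab4` (two correlated pairs in the rescue tables,
#' independent noise in the patient table). All columns have comparable raw
#' variance, so the structure survives column scaling.
#'
#' @param seed Integer seed.
#' @param n_patient Rows in the patient table (default 400).
#' @param n_rescue Rows in each rescue table (default 3000; large enough that
#'   the trailing sample eigenvalues of the noise block stay above the
#'   planted pair-minor eigenvalues).
#' @return List: `patient` (data frame), `rescues` (list of 2 data frames),
#'   `planted_stable` (`stab1..stab4`), `planted_variable` (the block
#'   parameter names).
#' @export
simulate_selection_tables <- function(seed = 1L, n_patient = 400,
                                      n_rescue = 3000) {
  params_a <- sprintf("varA%02d", 1:10)
  params_b <- sprintf("varB%02d", 1:10)
  params_s <- sprintf("stab%d", 1:4)
  all_params <- c(params_a, params_b, params_s)

  corr_pair <- function(n, rho) {
    u <- stats::rnorm(n)
    cbind(sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n),
          sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n))
  }
  with_seed(seed, {
    # patient: block A = group contrast, block B = latent factor, S = noise
    g <- rep(c(-1, 1), length.out = n_patient) * 1.53
    f2 <- stats::rnorm(n_patient) * 1.22
    pat <- cbind(
      vapply(1:10, function(j) g + stats::rnorm(n_patient), numeric(n_patient)),
      vapply(1:10, function(j) f2 + stats::rnorm(n_patient), numeric(n_patient)),
      matrix(stats::rnorm(n_patient * 4), ncol = 4)
    )
    colnames(pat) <- all_params

    rescues <- lapply(c(0.30, 0.30), function(rho1) {
      resc <- cbind(
        matrix(stats::rnorm(n_rescue * 20), ncol = 20),
        corr_pair(n_rescue, 0.30),
        corr_pair(n_rescue, 0.35)
      )
      colnames(resc) <- all_params
      as.data.frame(resc)
    })
    list(
      patient = as.data.frame(pat),
      rescues = rescues,
      planted_stable = params_s,
      planted_variable = c(params_a, params_b)
    )
  })
}

#' Run the stable/variable parameter-selection chain
#'
#' Applies the full selection workflow: PCA per dataset, variable set from
#' the patient table's leading PCs, stable sets from each rescue table's
#' trailing retained PCs, intersection across rescues, and the exclusive
#' overlay removing variable parameters.
#'
#' @param patient Patient-network feature table.
#' @param rescues List of rescue-network feature tables (length >= 2).
#' @param config A [fingerprint_config()].
#' @return List: `variable` (patient variable set), `stable_sets` (per
#'   rescue), `stable_across` (intersection), `exclusive` (stable-only
#'   parameters).
#' @export
run_selection_chain <- function(patient, rescues,
                                config = fingerprint_config()) {
  fp_sets <- function(tab) {
    pca <- run_pca(scale_features(tab))
    retained <- select_pcs(pca$explained, config$variance_threshold)
    variable_stable_sets(pca, retained, config)
  }
  patient_sets <- fp_sets(patient)
  rescue_sets <- lapply(rescues, fp_sets)
  stable_sets <- lapply(rescue_sets, `[[`, "stable")
  stable_across <- suppressWarnings(stable_across_datasets(stable_sets))
  list(
    variable = patient_sets$variable,
    stable_sets = stable_sets,
    stable_across = stable_across,
    exclusive = exclusive_selection(stable_across, patient_sets$variable)
  )
}
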