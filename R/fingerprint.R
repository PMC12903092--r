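# Network fingerprinting: PCA on column-scaled feature tables, retention of
# the PCs explaining more than a variance-ratio threshold, a UMAP overview
# embedding of the retained PC scores, and the loading-based selection of
# "variable" (first PCs) and "stable" (last retained PCs) parameters with the
# cross-dataset intersection / exclusive-overlay filtering steps.

#' Fingerprint analysis configuration
#'
#' @param variance_threshold Minimum explained-variance ratio (strict) for a
#'   PC to be retained. Default 0.025 for MEA feature tables; use 0.05 for
#'   smaller single-cell property tables.
#' @param top_k Parameters taken per PC when building loading-based sets
#'   (default 10).
#' @param n_variable_pcs Number of leading retained PCs defining the variable
#'   set (default 2).
#' @param n_stable_pcs Number of trailing retained PCs defining the stable
#'   set (default 2).
#' @param umap_neighbors,umap_min_dist UMAP hyperparameters (defaults 15 and
#'   0.1).
#' @param seed Seed for the UMAP embedding (recorded in the result).
#' @return An object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(variance_threshold = 0.025, top_k = 10,
                               n_variable_pcs = 2, n_stable_pcs = 2,
                               umap_neighbors = 15, umap_min_dist = 0.1,
                               seed = 42L) {
  stopifnot(variance_threshold > 0, variance_threshold < 1, top_k >= 1,
            n_variable_pcs >= 1, n_stable_pcs >= 1, umap_neighbors >= 2,
            umap_min_dist > 0)
  structure(
    list(variance_threshold = variance_threshold, top_k = as.integer(top_k),
         n_variable_pcs = as.integer(n_variable_pcs),
         n_stable_pcs = as.integer(n_stable_pcs),
         umap_neighbors = as.integer(umap_neighbors),
         umap_min_dist = umap_min_dist, seed = as.integer(seed)),
    class = "fingerprint_config"
  )
}

#' Column-scale a feature table for PCA
#'
#' Z-scores every feature column (mean 0, SD 1). Rows with any missing value
#' are dropped with a message reporting the count; zero-variance columns are
#' dropped with a message naming them.
#'
#' @param table Data frame or matrix; non-numeric columns (metadata) are
#'   ignored.
#' @return Numeric matrix of scaled features (attribute `dropped_rows` gives
#'   the dropped row count).
#' @export
scale_features <- function(table) {
  if (is.data.frame(table)) {
    num <- vapply(table, is.numeric, logical(1))
    mat <- as.matrix(table[, num, drop = FALSE])
  } else {
    mat <- as.matrix(table)
  }
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    message(sprintf("dropping %d row(s) with missing values", sum(!complete)))
  }
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2) stopf("fewer than 2 complete rows; cannot scale")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(mat)[sds == 0], collapse = ", ")))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  out <- scale(mat)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped_rows") <- sum(!complete)
  out
}

#' PCA of a scaled feature matrix
#'
#' Standard SVD-based PCA (centered; no further rescaling beyond
#' [scale_features()]). The sign convention is fixed so that each PC's
#' largest-magnitude loading is positive, making loadings reproducible.
#'
#' @param scaled Matrix from [scale_features()].
#' @return List of class `fingerprint_pca`: `loadings` (parameters x PCs),
#'   `explained` (variance ratios, non-increasing), `scores` (rows x PCs),
#'   `params` (column names).
#' @export
run_pca <- function(scaled) {
  if (nrow(scaled) < 2 || ncol(scaled) < 2) stopf("matrix too small for PCA")
  p <- stats::prcomp(scaled, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  p$rotation[, flip] <- -p$rotation[, flip]
  p$x[, flip] <- -p$x[, flip]
  structure(
    list(loadings = p$rotation,
         explained = p$sdev^2 / sum(p$sdev^2),
         scores = p$x,
         params = colnames(scaled)),
    class = "fingerprint_pca"
  )
}

#' Retain the PCs explaining more than a threshold of the variance
#'
#' @param explained Vector of explained-variance ratios.
#' @param variance_threshold Strict lower bound on the ratio.
#' @return Integer indices of the retained PCs, in order.
#' @export
select_pcs <- function(explained, variance_threshold = 0.025) {
  idx <- which(explained > variance_threshold)
  if (!length(idx)) stopf("no PC explains more than %.3g of the variance",
                          variance_threshold)
  idx
}

#' UMAP embedding of retained PC scores
#'
#' @param scores Rows x retained-PCs score matrix.
#' @param config A [fingerprint_config()]; the embedding is deterministic
#'   given `config$seed` (single-threaded SGD).
#' @return Rows x 2 embedding matrix.
#' @export
embed_umap <- function(scores, config = fingerprint_config()) {
  if (nrow(scores) < config$umap_neighbors + 1) {
    stopf("UMAP needs at least umap_neighbors + 1 = %d rows, got %d",
          config$umap_neighbors + 1, nrow(scores))
  }
  with_seed(config$seed, {
    uwot::umap(scores, n_neighbors = config$umap_neighbors,
               min_dist = config$umap_min_dist, n_components = 2,
               n_threads = 1, n_sgd_threads = 0)
  })
}

#' Parameters contributing the most to one PC
#'
#' Contribution is read as loading magnitude (sign-agnostic); ties break by
#' catalogue (column) order, so the result is deterministic.
#'
#' @param pca A [run_pca()] result.
#' @param pc PC index.
#' @param top_k Number of parameters to return.
#' @return Character vector of parameter names, by descending `|loading|`.
#' @export
top_loading_parameters <- function(pca, pc, top_k = 10) {
  if (pc < 1 || pc > ncol(pca$loadings)) stopf("PC %d out of range", pc)
  l <- pca$loadings[, pc]
  if (top_k > length(l)) {
    message(sprintf("top_k = %d exceeds the %d parameters; returning all",
                    top_k, length(l)))
    top_k <- length(l)
  }
  ord <- order(-abs(l), seq_along(l))
  pca$params[ord[seq_len(top_k)]]
}

#' Variable and stable parameter sets from retained PCs
#'
#' The variable set unions the top-loading parameters of the first
#' `n_variable_pcs` retained PCs (the directions of greatest variance); the
#' stable set unions those of the last `n_stable_pcs` retained PCs (the
#' retained directions of least variance).
#'
#' @param pca A [run_pca()] result.
#' @param retained Indices from [select_pcs()].
#' @param config A [fingerprint_config()].
#' @return List with `variable` and `stable` character vectors.
#' @export
variable_stable_sets <- function(pca, retained,
                                 config = fingerprint_config()) {
  need <- config$n_variable_pcs + config$n_stable_pcs
  if (length(retained) < need) {
    stopf("need at least %d retained PCs, got %d", need, length(retained))
  }
  first <- retained[seq_len(config$n_variable_pcs)]
  last <- retained[seq(length(retained) - config$n_stable_pcs + 1,
                       length(retained))]
  list(
    variable = unique(unlist(lapply(first, top_loading_parameters,
                                    pca = pca, top_k = config$top_k))),
    stable = unique(unlist(lapply(last, top_loading_parameters,
                                  pca = pca, top_k = config$top_k)))
  )
}

#' Parameters stable across several datasets
#'
#' @param sets List (length >= 2) of stable-set character vectors, one per
#'   dataset.
#' @return Their intersection; a warning is issued when it is empty.
#' @export
stable_across_datasets <- function(sets) {
  if (length(sets) < 2) stopf("need stable sets from at least 2 datasets")
  out <- Reduce(intersect, sets)
  if (!length(out)) warnf("no parameter is stable across all datasets")
  out
}

#' Parameters contributing exclusively to the stable PCs
#'
#' @param stable_set,variable_set Character vectors of parameter names.
#' @return `stable_set` with every member of `variable_set` removed.
#' @export
exclusive_selection <- function(stable_set, variable_set) {
  setdiff(stable_set, variable_set)
}

#' Parameters variable in one dataset but not another
#'
#' @param variable_a,variable_b Character vectors (e.g. the variable sets of
#'   patient and rescue networks).
#' @return `variable_a` minus `variable_b`.
#' @export
variable_in_one_not_other <- function(variable_a, variable_b) {
  setdiff(variable_a, variable_b)
}

#' Full fingerprint analysis of one feature table
#'
#' Convenience wrapper: scale, PCA, PC retention, variable/stable sets and
#' (when the table is large enough) the UMAP embedding.
#'
#' @param table Feature table (data frame; non-numeric columns ignored).
#' @param config A [fingerprint_config()].
#' @param umap Logical; compute the UMAP embedding (skipped with a message
#'   when there are too few rows).
#' @return List of class `fingerprint_result`: `pca`, `retained`, `sets`
#'   (NULL when fewer than `n_variable_pcs + n_stable_pcs` PCs are retained),
#'   `embedding` (or NULL), `config`.
#' @export
fingerprint <- function(table, config = fingerprint_config(), umap = TRUE) {
  scaled <- scale_features(table)
  pca <- run_pca(scaled)
  retained <- select_pcs(pca$explained, config$variance_threshold)
  sets <- if (length(retained) >= config$n_variable_pcs + config$n_stable_pcs) {
    variable_stable_sets(pca, retained, config)
  } else {
    message("too few retained PCs for variable/stable sets")
    NULL
  }
  embedding <- NULL
  if (umap) {
    if (nrow(scaled) >= config$umap_neighbors + 1) {
      embedding <- embed_umap(pca$scores[, retained, drop = FALSE], config)
    } else {
      message("too few rows for the UMAP embedding; skipping")
    }
  }
  structure(
    list(pca = pca, retained = retained, sets = sets, embedding = embedding,
         config = config),
    class = "fingerprint_result"
  )
}
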