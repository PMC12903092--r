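test_that("scaling z-scores columns and drops degenerate data", {
  tab <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_message(scaled <- scale_features(tab), "zero-variance")
  expect_identical(colnames(scaled), c("a", "c"))
  expect_equal(scaled[, "a"], c(-1, 0, 1), tolerance = 1e-3)
  tab$c[2] <- NA
  expect_message(scaled <- scale_features(tab), "1 row")
  expect_identical(nrow(scaled), 2L)
  expect_error(suppressMessages(scale_features(tab[1:2, ])), "fewer than 2")
})

test_that("PCA matches the correlation-eigenvalue oracle and reconstructs", {
  set.seed(11)
  x <- matrix(rnorm(200), 20, 10)
  colnames(x) <- letters[1:10]
  scaled <- scale_features(x)
  pca <- run_pca(scaled)
  expect_true(all(diff(pca$explained) <= 1e-12))
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pca$explained, ev / sum(ev), tolerance = 1e-8)
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(recon, scaled, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-|loading| entry of every PC is positive
  for (j in seq_len(ncol(pca$loadings))) {
    l <- pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # exact 2D line: PC1 carries all the variance
  line <- cbind(x = 1:10, y = 2 * (1:10))
  p1 <- run_pca(scale_features(line))
  expect_equal(p1$explained[1], 1, tolerance = 1e-9)
})

test_that("PC retention uses a strict variance threshold", {
  ratios <- c(0.5, 0.3, 0.1, 0.05, 0.03, 0.015, 0.005)
  expect_identical(select_pcs(ratios, 0.025), 1:5)
  expect_identical(select_pcs(ratios, 0.05), 1:3)  # 0.05 is not > 0.05
  expect_error(select_pcs(ratios, 0.6), "no PC")
})

test_that("top loadings rank by magnitude with catalogue-order ties", {
  loadings <- matrix(c(0.9, -0.3, 0.3, 0.1), ncol = 1,
                     dimnames = list(c("w", "x", "y", "z"), "PC1"))
  pca <- structure(list(loadings = loadings, params = rownames(loadings)),
                   class = "fingerprint_pca")
  expect_identical(top_loading_parameters(pca, 1, 2), c("w", "x"))
  expect_identical(top_loading_parameters(pca, 1, 3), c("w", "x", "y"))
  expect_message(all4 <- top_loading_parameters(pca, 1, 10), "returning all")
  expect_length(all4, 4)
  expect_error(top_loading_parameters(pca, 5), "out of range")
})

test_that("set operations implement the selection workflow", {
  expect_identical(stable_across_datasets(list(c("a", "b", "c"),
                                               c("b", "c", "d"))),
                   c("b", "c"))
  expect_warning(none <- stable_across_datasets(list("a", "b")), "no parameter")
  expect_length(none, 0)
  expect_error(stable_across_datasets(list("a")), "at least 2")
  expect_identical(exclusive_selection(c("a", "b"), c("b", "c")), "a")
  expect_length(exclusive_selection(c("a", "b"), c("a", "b", "c")), 0)
  expect_identical(exclusive_selection(c("a", "b"), character(0)), c("a", "b"))
  expect_identical(variable_in_one_not_other(c("ibi", "isi_sd"), "ibi"),
                   "isi_sd")
  expect_length(variable_in_one_not_other(c("a", "b"), c("a", "b")), 0)
})

test_that("variable/stable sets need enough retained PCs", {
  set.seed(3)
  x <- matrix(rnorm(300), 30, 10)
  colnames(x) <- letters[1:10]
  pca <- run_pca(scale_features(x))
  cfg <- fingerprint_config()
  expect_error(variable_stable_sets(pca, 1:3, cfg), "at least 4")
  sets <- variable_stable_sets(pca, 1:10, cfg)
  expect_lte(length(sets$variable), 2 * cfg$top_k)
  expect_true(all(sets$variable %in% colnames(x)))
})

test_that("selection is invariant to row permutation", {
  x <- simulate_selection_tables(seed = 12, n_patient = 200, n_rescue = 1000)
  pca1 <- run_pca(scale_features(x$patient))
  sets1 <- variable_stable_sets(pca1, select_pcs(pca1$explained),
                                fingerprint_config())
  set.seed(1)
  shuffled <- x$patient[sample(nrow(x$patient)), ]
  pca2 <- run_pca(scale_features(shuffled))
  sets2 <- variable_stable_sets(pca2, select_pcs(pca2$explained),
                                fingerprint_config())
  expect_setequal(sets1$variable, sets2$variable)
  expect_setequal(sets1$stable, sets2$stable)
})

test_that("the selection chain recovers planted structure", {
  x <- simulate_selection_tables(seed = 2024)
  chain <- run_selection_chain(x$patient, x$rescues)
  expect_setequal(chain$variable, x$planted_variable)
  expect_setequal(chain$exclusive, x$planted_stable)
})

test_that("UMAP embeddings are deterministic and separate planted blobs", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(20 * 5), 20, 5),
                 matrix(rnorm(20 * 5, mean = 10), 20, 5))
  labels <- rep(c(1, 2), each = 20)
  cfg <- fingerprint_config(umap_neighbors = 10, seed = 99)
  e1 <- embed_umap(blobs, cfg)
  e2 <- embed_umap(blobs, cfg)
  expect_identical(e1, e2)
  expect_identical(ncol(e1), 2L)
  # nearest-neighbor label purity in the embedding
  purity <- mean(vapply(seq_len(nrow(e1)), function(i) {
    d <- sqrt(rowSums((e1 - matrix(e1[i, ], nrow(e1), 2, byrow = TRUE))^2))
    d[i] <- Inf
    labels[which.min(d)] == labels[i]
  }, logical(1)))
  expect_gte(purity, 0.9)
  expect_error(embed_umap(blobs[1:5, ], cfg), "at least")
})
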