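test_that("location PCA matches a dense eigen-decomposition oracle", {
  set.seed(51)
  v <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("L", 1:5)))
  got <- pca_locations(v)
  # oracle: centered column observations, eigen of covariance
  X <- scale(t(v), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  k <- min(nrow(X) - 1, ncol(X))
  for (j in seq_len(k)) {
    load <- ev$vectors[, j]
    if (load[which.max(abs(load))] < 0) load <- -load
    expect_equal(unname(got$loadings[, j]), unname(load), tolerance = 1e-8)
    expect_equal(unname(got$scores[, j]), unname(as.vector(X %*% load)),
                 tolerance = 1e-8)
  }
  expect_equal(got$var_explained[seq_len(k)],
               (ev$values[seq_len(k)] / sum(ev$values[seq_len(k)])),
               tolerance = 1e-8)
})

test_that("PCA handles identical, two-point, and single-location inputs", {
  v <- matrix(5, 4, 3, dimnames = list(paste0("P", 1:4), paste0("L", 1:3)))
  got <- pca_locations(v)
  expect_true(all(got$var_explained == 0))   # identical locations
  v2 <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(c("P1", "P2"), c("a", "b")))
  got2 <- pca_locations(v2)
  d <- sqrt(sum((v2[, 1] - v2[, 2])^2))
  expect_equal(sort(unname(got2$scores[, 1])), c(-d / 2, d / 2))
  expect_error(pca_locations(matrix(1, 2, 1, dimnames = list(c("a", "b"), "L"))),
               class = "enamelmap_validation_error")
})

test_that("hierarchical clustering recovers planted blobs and honors k bounds", {
  set.seed(61)
  n_each <- 5
  v <- cbind(matrix(rnorm(10 * n_each, 0, 0.1), 10),
             matrix(rnorm(10 * n_each, 8, 0.1), 10))
  dimnames(v) <- list(paste0("P", 1:10), paste0("L", 1:(2 * n_each)))
  cl <- hcluster_locations(v, k = 2)
  expect_equal(ari(cl$cluster, rep(1:2, each = n_each)), 1)
  expect_equal(length(unique(hcluster_locations(v, k = 10)$cluster)), 10L)
  expect_equal(length(unique(hcluster_locations(v, k = 1)$cluster)), 1L)
  expect_error(hcluster_locations(v, k = 11),
               class = "enamelmap_validation_error")
})

test_that("clusters are named by majority stage with ties toward the earlier stage", {
  grid <- data.frame(location_id = paste0("L", 1:4), tooth = "M3",
                     grid_row = 0:3, grid_col = 0,
                     stage = c("secretory", "late_maturation", "dentin", "bone"),
                     volume_mm3 = 2)
  v <- matrix(rep(c(0, 0.1, 50, 50.1), each = 3), 3, 4,
              dimnames = list(paste0("P", 1:3), grid$location_id))
  cl <- hcluster_locations(v, k = 2, grid = grid)
  # cluster of L1+L2 ties Secretion/Maturation -> earlier stage wins
  expect_equal(unname(cl$group_of["L1"]), "Secretion")
  expect_equal(unname(cl$group_of["L3"]), "NonEnamel")
})

test_that("permutation ANOVA honors its degenerate-value conventions", {
  res <- permutation_anova(rep(3, 8), rep(c("a", "b"), each = 4))
  expect_equal(res$p_value, 1)      # all values equal
  res <- permutation_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(res$statistic, Inf)  # zero within-group variance
  expect_equal(res$method, "exhaustive")
  expect_error(permutation_anova(c(1, 2, 3), c("a", "a", "b")),
               class = "enamelmap_validation_error")
  expect_error(permutation_anova(c(1, NA, 3, 4), rep(c("a", "b"), 2)),
               class = "enamelmap_validation_error")
})

test_that("exhaustive permutation p equals the full-enumeration oracle", {
  set.seed(71)
  for (i in 1:8) {
    v <- rnorm(4)
    g <- c("a", "a", "b", "b")
    res <- permutation_anova(v, g, n_permutations = 4999)
    expect_equal(res$method, "exhaustive")
    expect_equal(res$n_permutations, 6L)   # 4!/(2!2!) arrangements
    expect_equal(res$p_value, oracle_perm_p(v, g))
  }
  v <- rnorm(6)
  g <- c("a", "a", "b", "b", "c", "c")
  expect_equal(permutation_anova(v, g)$p_value, oracle_perm_p(v, g))
})

test_that("Monte-Carlo and exhaustive permutation p agree within sampling error", {
  set.seed(81)
  for (i in 1:5) {
    v <- rnorm(8)
    g <- rep(c("a", "b"), each = 4)
    ex <- permutation_anova(v, g, n_permutations = 4999)   # 70 arrangements
    expect_equal(ex$method, "exhaustive")
    B <- 4000
    mc <- permutation_anova(v, g, n_permutations = B, seed = 100 + i)
    tol <- 2 * sqrt(ex$p_value * (1 - ex$p_value) / B) + 2 / B
    expect_lt(abs(mc$p_value - ex$p_value), tol + 1e-12)
  }
})

test_that("Monte-Carlo permutation p is reproducible under a seed", {
  v <- rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  p1 <- permutation_anova(v, g, n_permutations = 299, seed = 5)$p_value
  p2 <- permutation_anova(v, g, n_permutations = 299, seed = 5)$p_value
  expect_identical(p1, p2)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03)$q_values, 0.03)       # single p
  expect_equal(bh_adjust(rep(0.2, 5))$q_values, rep(0.2, 5))
  set.seed(91)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p)$q_values, oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 0)), class = "enamelmap_validation_error")
  expect_error(bh_adjust(1.2), class = "enamelmap_validation_error")
  got <- bh_adjust(c(0.001, 0.5), alpha = 0.05)
  expect_identical(got$rejected, c(TRUE, FALSE))
})

test_that("direction assignment compares each group to the mean of the others", {
  v <- c(L1 = 10, L2 = 11, L3 = 1, L4 = 2, L5 = 1, L6 = 2)
  g <- c("Secretion", "Secretion", "DEJ", "DEJ", "Maturation", "Maturation")
  dir <- assign_direction(v, g)
  expect_equal(unname(dir["Secretion"]), "higher")
  expect_equal(unname(dir["DEJ"]), "lower")
  flat <- assign_direction(rep(4, 6), g)
  expect_true(all(flat == "neutral"))
})

test_that("the percentile pre-filter drops the lowest tail by nearest rank", {
  x <- stats::setNames(1:10, paste0("P", 1:10))
  kept <- percentile_filter(x, 10)
  expect_equal(length(kept), 9L)              # exactly 1 removed
  expect_false("P1" %in% names(kept))
  same <- percentile_filter(stats::setNames(rep(2, 6), paste0("P", 1:6)), 10)
  expect_equal(length(same), 6L)              # none strictly below
  expect_equal(length(percentile_filter(numeric(0))), 0L)
})

test_that("over-representation p-values equal the exact hypergeometric tail", {
  bg <- paste0("G", 1:1000)
  ann <- data.frame(identifier = bg,
                    term = c(rep("term50", 50), rep("other", 950)))
  set <- c(paste0("G", 1:10), paste0("G", 101:110))   # 10 of 20 in term50
  res <- over_representation(set, ann, bg)
  row <- res[res$term == "term50", ]
  expect_equal(row$p_value, oracle_hyper_tail(10, 50, 1000, 20))
  expect_equal(row$fold_enrichment, (10 / 20) / (50 / 1000))
  # a term covering the whole background has fold enrichment 1
  ann2 <- data.frame(identifier = bg, term = "everything")
  res2 <- over_representation(set, ann2, bg)
  expect_equal(res2$fold_enrichment, 1)
  # empty set and out-of-background genes
  expect_equal(nrow(over_representation(character(0), ann, bg)), 0L)
  res3 <- over_representation(c(set, "NOT_THERE"), ann, bg)
  expect_identical(attr(res3, "audit"), "NOT_THERE")
})

test_that("terms with fewer than two hits are skipped", {
  bg <- paste0("G", 1:100)
  ann <- data.frame(identifier = bg,
                    term = c("rare", rep("common", 99)))
  res <- over_representation(paste0("G", 1:10), ann, bg)
  expect_false("rare" %in% res$term)
})

test_that("row-wise differential abundance is coherent and seed-stable", {
  set.seed(101)
  v <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("P", 1:20), paste0("L", 1:12)))
  v[1:3, 1:4] <- v[1:3, 1:4] + 5        # planted effect in group a
  g <- rep(c("a", "b", "c"), each = 4)
  res <- diff_abundance(v, g, n_permutations = 499, seed = 3)
  expect_equal(res$q_value, oracle_bh(res$p_value))
  expect_true(all(res$significant[1:3]))
  expect_equal(res$dir_a[1:3], rep("higher", 3))
  # direction pattern must be consistent with the reported group means
  for (i in which(res$significant)) {
    means <- unlist(res[i, c("mean_a", "mean_b", "mean_c")])
    for (j in 1:3) {
      rel <- means[j] - mean(means[-j])
      want <- if (rel > 0) "higher" else if (rel < 0) "lower" else "neutral"
      expect_equal(unname(unlist(res[i, paste0("dir_", c("a", "b", "c"))[j]])),
                   want)
    }
  }
  res2 <- diff_abundance(v, g, n_permutations = 499, seed = 3)
  expect_identical(res$p_value, res2$p_value)
  # row order does not change a protein's p-value (per-row sub-streams)
  res3 <- diff_abundance(v[20:1, ], g, n_permutations = 499, seed = 3)
  expect_equal(res3$p_value[res3$protein_accession == "P20"],
               res$p_value[res$protein_accession == "P20"])
})
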