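## spatialstats: stage-group definition (PCA + hierarchical clustering) and
## permutation-based differential abundance with FDR control.

## Replace missingness before location-space analyses: absence = not
## detected, imputed as 0 on the percent scale (default), or rows with any
## missingness dropped.
complete_matrix <- function(x, na_action = c("zero", "drop_rows")) {
  v <- .am_values(x)
  na_action <- match.arg(na_action)
  if (na_action == "zero") {
    v[is.na(v)] <- 0
  } else {
    v <- v[stats::complete.cases(v), , drop = FALSE]
  }
  v
}

#' PCA of sample locations
#'
#' Treats each location (column) as an observation in protein space,
#' column-centers, and decomposes.  Components are ordered by decreasing
#' variance and each component's sign is fixed so its largest-magnitude
#' loading is positive.  When the locations are all identical the variance
#' fractions are reported as zero.
#'
#' @param x `abundance_matrix` or matrix (rows x locations).
#' @param na_action Missing-value policy before the decomposition:
#'   `"zero"` (impute zero; intended for the percent scale) or
#'   `"drop_rows"`.
#' @return Object of class `location_pca`: list with `scores` (locations x
#'   components), `loadings`, `var_explained`.
#' @export
pca_locations <- function(x, na_action = c("zero", "drop_rows")) {
  v <- complete_matrix(x, na_action)
  if (ncol(v) < 2L) stop_validation("PCA needs at least 2 locations")
  p <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  scores <- p$x
  load <- p$rotation
  for (k in seq_len(ncol(load))) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  tot <- sum(p$sdev^2)
  ve <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  structure(list(scores = scores, loadings = load, var_explained = ve),
            class = "location_pca")
}

#' @export
print.location_pca <- function(x, ...) {
  k <- min(3L, length(x$var_explained))
  cat(sprintf("Location PCA: %d locations; variance explained: %s\n",
              nrow(x$scores),
              paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$var_explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

## Majority a-priori stage label per cluster, ties broken toward the earlier
## developmental stage (GROUP_ORDER).
.name_clusters <- function(cluster, stages) {
  groups <- stage_groups(stages)
  vapply(sort(unique(cluster)), function(k) {
    g <- groups[cluster == k]
    tab <- table(factor(g, levels = GROUP_ORDER))
    names(tab)[which.max(tab)]   # which.max takes the first = earliest stage
  }, character(1))
}

#' Hierarchical clustering of sample locations
#'
#' Euclidean-distance agglomerative clustering of the locations, cut at `k`
#' clusters.  When a grid with a-priori stage labels is supplied, each
#' cluster is named by the majority group of its members' stage labels
#' (ties toward the earlier developmental stage): `Secretion`, `Maturation`,
#' `Cuspal`, `DEJ` or `NonEnamel`.
#'
#' @param x `abundance_matrix` or matrix (rows x locations).
#' @param k Number of clusters, `1 <= k <=` number of locations.
#' @param linkage Agglomeration method: `"average"` (default), `"single"`,
#'   `"complete"` or `"ward"` (Ward.D2).
#' @param grid Optional grid with `stage` labels for cluster naming.
#' @param na_action Missing-value policy (see [pca_locations()]).
#' @return Object of class `grid_clustering`: `cluster` (location ->
#'   cluster index), `groups` (cluster index -> name), `group_of`
#'   (location -> name), and the `hclust` merge tree.
#' @export
hcluster_locations <- function(x, k, linkage = c("average", "single",
                                                 "complete", "ward"),
                               grid = NULL,
                               na_action = c("zero", "drop_rows")) {
  linkage <- match.arg(linkage)
  v <- complete_matrix(x, na_action)
  n <- ncol(v)
  if (!is_count(k) || k > n) {
    stop_validation("k must be a count between 1 and the number of locations (%d)", n)
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"), method = method)
  cl <- stats::cutree(hc, k = k)
  groups <- NULL
  group_of <- NULL
  if (!is.null(grid)) {
    stages <- grid$stage[match(names(cl), grid$location_id)]
    if (any(is.na(stages))) {
      stop_validation("location(s) missing from grid: %s",
                      paste(names(cl)[is.na(stages)], collapse = ", "))
    }
    groups <- .name_clusters(cl, stages)
    names(groups) <- as.character(sort(unique(cl)))
    group_of <- groups[as.character(cl)]
    names(group_of) <- names(cl)
  }
  structure(list(cluster = cl, k = k, linkage = linkage, groups = groups,
                 group_of = group_of, hclust = hc),
            class = "grid_clustering")
}

#' @export
print.grid_clustering <- function(x, ...) {
  cat(sprintf("Location clustering: %d locations, k = %d (%s linkage, Euclidean)\n",
              length(x$cluster), x$k, x$linkage))
  if (!is.null(x$groups)) {
    for (k in names(x$groups)) {
      cat(sprintf("  cluster %s -> %s: %s\n", k, x$groups[[k]],
                  paste(names(x$cluster)[x$cluster == as.integer(k)],
                        collapse = ", ")))
    }
  }
  invisible(x)
}

## One-way F from group sums.  S: groups x B matrix of per-group sums for B
## (permuted) value assignments; all permutations share sum(v) and sum(v^2).
.f_from_sums <- function(S, ngr, total, sstot, n) {
  g <- length(ngr)
  ssb <- colSums(S^2 / ngr) - total^2 / n
  ssb <- pmax(ssb, 0)
  ssw <- pmax(sstot - ssb, 0)
  tol <- 1e-12 * (sstot + 1e-300)
  ifelse(ssw > tol,
         (ssb / (g - 1)) / (ssw / (n - g)),
         ifelse(ssb > tol, Inf, 0))
}

## Number of distinct label arrangements n! / prod(ngr!)
.n_arrangements <- function(ngr) {
  round(exp(lgamma(sum(ngr) + 1) - sum(lgamma(ngr + 1))))
}

## All distinct arrangements of the group-label multiset, as an N x n matrix
## of group indices.  Only called when N is small.
.label_arrangements <- function(ngr) {
  n <- sum(ngr)
  rec <- function(counts) {
    if (sum(counts) == 0L) return(matrix(integer(0), 1L, 0L))
    do.call(rbind, lapply(which(counts > 0L), function(j) {
      counts2 <- counts
      counts2[j] <- counts2[j] - 1L
      cbind(j, rec(counts2))
    }))
  }
  rec(as.integer(ngr))
}

#' Permutation one-way ANOVA for a single protein
#'
#' Tests whether a protein's abundance differs across location groups.  The
#' statistic is the one-way F (between-group over within-group mean
#' squares); its null distribution is built by uniformly permuting the group
#' labels.  When the number of distinct label arrangements is at most
#' `n_permutations` the null is enumerated exhaustively and
#' `p = #\{F_perm >= F_obs\} / N` (the identity arrangement included);
#' otherwise `n_permutations` Monte-Carlo draws give
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' Zero within-group variance with non-zero between-group variance gives
#' `F = +Inf`; the permutation comparison remains well-defined.  All values
#' equal gives `p = 1`.
#'
#' @param values Complete numeric vector, one value per location tested.
#' @param groups Group labels (factor or character), every group with at
#'   least 2 members.
#' @param n_permutations Monte-Carlo permutation count (default 4999, used
#'   with the add-one correction).
#' @param seed Optional seed for the Monte-Carlo draws.
#' @return List with `statistic`, `p_value`, `method`
#'   (`"exhaustive"`/`"monte_carlo"`) and `n_permutations`.
#' @export
#' @examples
#' permutation_anova(c(1, 2, 9, 10), c("a", "a", "b", "b"))
permutation_anova <- function(values, groups, n_permutations = 4999,
                              seed = NULL) {
  if (any(is.na(values))) {
    stop_validation("values must be complete for the tested locations")
  }
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(values) != length(groups)) {
    stop_validation("values and groups differ in length")
  }
  ngr <- as.integer(table(groups))
  if (length(ngr) < 2L) stop_validation("need at least 2 groups")
  if (any(ngr < 2L)) stop_validation("every group needs at least 2 members")
  if (!is_count(n_permutations)) {
    stop_validation("n_permutations must be a positive count")
  }
  n <- length(values)
  g <- length(ngr)
  G <- matrix(0, g, n)
  G[cbind(as.integer(groups), seq_len(n))] <- 1
  total <- sum(values)
  sstot <- sum(values^2) - total^2 / n
  f_obs <- .f_from_sums(G %*% values, ngr, total, sstot, n)
  tol <- if (is.finite(f_obs)) 1e-10 * (1 + abs(f_obs)) else 0
  N <- .n_arrangements(ngr)
  if (is.finite(N) && N <= n_permutations) {
    A <- .label_arrangements(ngr)
    S <- vapply(seq_len(g), function(j) as.vector((A == j) %*% values),
                numeric(nrow(A)))
    f_all <- .f_from_sums(t(S), ngr, total, sstot, n)
    p <- mean(f_all >= f_obs - tol)
    list(statistic = f_obs, p_value = p, method = "exhaustive",
         n_permutations = nrow(A))
  } else {
    draw <- function() {
      idx <- vapply(seq_len(n_permutations), function(i) sample.int(n),
                    integer(n))
      V <- matrix(values[idx], n, n_permutations)
      f_all <- .f_from_sums(G %*% V, ngr, total, sstot, n)
      (1 + sum(f_all >= f_obs - tol)) / (1 + n_permutations)
    }
    p <- if (is.null(seed)) draw() else with_seed(seed, draw())
    list(statistic = f_obs, p_value = p, method = "monte_carlo",
         n_permutations = n_permutations)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: monotone-enforced q-values and the
#' rejection flags `q <= alpha`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return List with `q_values` and logical `rejected`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) && (any(is.na(p_values)) ||
                           any(p_values <= 0 | p_values > 1))) {
    stop_validation("p-values must lie in (0, 1]")
  }
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) {
    stop_validation("alpha must lie in (0, 1]")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = q <= alpha)
}

#' Direction of differential abundance per named group
#'
#' For each protein and each named group, compares the group's mean with the
#' mean of the other groups' means: `higher`, `lower`, or `neutral` on a
#' tie.
#'
#' @param values Numeric matrix (proteins x locations) or vector.
#' @param groups Group label per location (character/factor, may contain
#'   `NA` for locations excluded from testing).
#' @return Character matrix proteins x groups (or a named vector for vector
#'   input).
#' @export
assign_direction <- function(values, groups) {
  vec_in <- is.null(dim(values))
  v <- if (vec_in) matrix(values, 1L, dimnames = list("protein", names(values)))
       else values
  keep <- !is.na(groups)
  v <- v[, keep, drop = FALSE]
  groups <- factor(groups[keep])
  lv <- levels(groups)
  gm <- vapply(lv, function(g) {
    rowMeans(v[, groups == g, drop = FALSE])
  }, numeric(nrow(v)))
  gm <- matrix(gm, nrow = nrow(v), dimnames = list(rownames(v), lv))
  dir <- matrix("neutral", nrow(gm), ncol(gm), dimnames = dimnames(gm))
  for (j in seq_along(lv)) {
    others <- rowMeans(gm[, -j, drop = FALSE])
    dir[gm[, j] > others, j] <- "higher"
    dir[gm[, j] < others, j] <- "lower"
  }
  if (vec_in) dir[1L, ] else dir
}

#' Abundance pre-filter: drop the least abundant percentile
#'
#' Removes the proteins in the lowest `percentile` of group-mean abundance,
#' nearest-rank style: with `k = ceiling(percentile * n / 100)`, values
#' strictly below the `(k+1)`-th order statistic are removed, so the bottom
#' `k` are dropped when values are distinct and nothing is dropped when all
#' values are equal.
#'
#' @param abundances Named numeric vector of group-mean abundances.
#' @param percentile Percentile to drop (default 10).
#' @return The retained sub-vector, with the cut threshold as attribute
#'   `threshold`.
#' @export
percentile_filter <- function(abundances, percentile = 10) {
  n <- length(abundances)
  if (n == 0L) return(abundances)
  if (!is_number(percentile) || percentile < 0 || percentile > 100) {
    stop_validation("percentile must lie in [0, 100]")
  }
  k <- ceiling(percentile * n / 100)
  s <- sort(abundances)
  thr <- if (k + 1 > n) s[[n]] else s[[k + 1]]
  out <- abundances[abundances >= thr]
  attr(out, "threshold") <- thr
  out
}

#' Hypergeometric over-representation test
#'
#' One-sided hypergeometric enrichment of annotation terms in a gene set
#' against a background, BH-adjusted across the tested terms.  Terms with
#' fewer than 2 hits in the set are skipped; set members absent from the
#' background are ignored and reported in the `audit` attribute.
#'
#' @param genes Character vector of identifiers (the set).
#' @param annotation Data frame whose first two columns map identifier ->
#'   term.
#' @param background Character vector of identifiers forming the universe.
#' @return Data frame (term, hits, set_size, term_size, background_size,
#'   fold_enrichment, p_value, q_value) ordered by p-value, with ignored
#'   identifiers in `attr(, "audit")`.
#' @export
over_representation <- function(genes, annotation, background) {
  if (!is.data.frame(annotation) || ncol(annotation) < 2L) {
    stop_validation("annotation must be a data frame with identifier and term columns")
  }
  ann <- annotation[, 1:2]
  names(ann) <- c("id", "term")
  ann <- ann[ann$id %in% background, , drop = FALSE]
  missing_genes <- setdiff(genes, background)
  set <- intersect(unique(genes), background)
  N <- length(unique(background))
  n_set <- length(set)
  empty <- data.frame(term = character(0), hits = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      background_size = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      q_value = numeric(0))
  attr(empty, "audit") <- missing_genes
  if (n_set == 0L) return(empty)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    members <- unique(ann$id[ann$term == tm])
    K <- length(members)
    k <- length(intersect(members, set))
    if (k < 2L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n_set, lower.tail = FALSE)
    data.frame(term = tm, hits = k, set_size = n_set, term_size = K,
               background_size = N,
               fold_enrichment = (k / n_set) / (K / N),
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term), ]
  rownames(res) <- NULL
  attr(res, "audit") <- missing_genes
  res
}

#' Per-protein differential abundance across location groups
#'
#' Runs the permutation one-way ANOVA row-wise over an abundance matrix,
#' adjusts p-values by Benjamini-Hochberg, and assigns each significant
#' protein a per-group direction pattern from the group means.  Locations
#' with `NA` group labels are excluded from testing (e.g. non-enamel
#' reference tissues).
#'
#' @param x `abundance_matrix` or matrix (proteins x locations), complete
#'   for the tested locations (in the pipeline, absence is imputed as 0 on
#'   the percent scale first).
#' @param groups Group label per column; `NA` columns are dropped.
#' @param n_permutations,seed Passed to [permutation_anova()]; each row uses
#'   a sub-stream seed derived from `seed` and the row name, so results are
#'   reproducible and independent of row order.
#' @param alpha FDR level for the rejection flags.
#' @return Object of class `diff_abundance`: a data frame with the observed
#'   F statistic, permutation p-value, BH q-value, per-group means
#'   (`mean_<group>`) and direction pattern (`dir_<group>`, `NA` for
#'   proteins not flagged significant).
#' @export
diff_abundance <- function(x, groups, n_permutations = 4999, seed = NULL,
                           alpha = 0.05) {
  v <- .am_values(x)
  if (length(groups) != ncol(v)) {
    stop_validation("groups must have one label per matrix column")
  }
  keep <- !is.na(groups)
  v <- v[, keep, drop = FALSE]
  grp <- factor(groups[keep])
  row_index <- function(i) {
    nm <- rownames(v)[i]
    if (is.null(nm)) return(i)
    sum(utf8ToInt(nm) * seq_len(nchar(nm))) %% 1e6
  }
  res <- lapply(seq_len(nrow(v)), function(i) {
    permutation_anova(v[i, ], grp, n_permutations = n_permutations,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, row_index(i), 6))
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  f <- vapply(res, `[[`, numeric(1), "statistic")
  adj <- bh_adjust(p, alpha = alpha)
  gm <- vapply(levels(grp), function(g) {
    rowMeans(v[, grp == g, drop = FALSE])
  }, numeric(nrow(v)))
  gm <- matrix(gm, nrow = nrow(v),
               dimnames = list(rownames(v), levels(grp)))
  dir <- assign_direction(v, as.character(grp))
  dir[!adj$rejected, ] <- NA_character_
  out <- data.frame(protein_accession = rownames(v), statistic = f,
                    p_value = p, q_value = adj$q_values,
                    significant = adj$rejected, stringsAsFactors = FALSE)
  colnames(gm) <- paste0("mean_", colnames(gm))
  dirdf <- as.data.frame(dir, stringsAsFactors = FALSE)
  colnames(dirdf) <- paste0("dir_", levels(grp))
  out <- cbind(out, as.data.frame(gm), dirdf)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("diff_abundance", "data.frame")
  out
}

#' @export
print.diff_abundance <- function(x, ...) {
  cat(sprintf("Differential abundance: %d proteins tested, %d significant at FDR %.2g (B = %d)\n",
              nrow(x), sum(x$significant), attr(x, "alpha"),
              attr(x, "n_permutations")))
  top <- x[order(x$p_value), , drop = FALSE]
  print.data.frame(utils::head(top[c("protein_accession", "statistic",
                                     "p_value", "q_value")], 10L),
                   digits = 4)
  invisible(x)
}
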