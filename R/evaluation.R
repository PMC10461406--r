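#' Precision-recall against labeled essential/nonessential genes
#'
#' Sweeps a depletion-rank threshold over gene scores (ascending score =
#' more depleted = predicted essential), computing precision and recall over
#' labeled genes only; unlabeled genes never affect the curve. Tied scores
#' enter or leave a threshold together. Also reports recall at the largest
#' threshold whose precision still meets `precision_target`.
#'
#' @param scores Tibble `gene`, `score` (more negative = more depleted).
#' @param labels Tibble `gene`, `label` with values `"pos"` (essential) and
#'   `"neg"` (nonessential); the two sets must be disjoint.
#' @param precision_target Precision level for the reported recall
#'   (default 0.95).
#' @return List of class `pr_curve`: `curve` (threshold-wise tibble),
#'   `recall_at_precision`, `precision_target`, `n_pos`, `n_neg`.
#' @export
precision_recall <- function(scores, labels, precision_target = 0.95) {
  if (any(duplicated(labels$gene))) {
    abort("Labeled gene sets must be disjoint (duplicated labels found).")
  }
  dat <- inner_join(scores, labels, by = "gene")
  n_pos <- sum(dat$label == "pos")
  n_neg <- sum(dat$label == "neg")
  if (n_pos < 1L || n_neg < 1L) {
    abort("Need at least one positive and one negative labeled gene with a score.")
  }
  dat <- arrange(dat, .data$score, .data$gene)
  thresholds <- sort(unique(dat$score))
  curve <- purrr::map(thresholds, function(th) {
    called <- dat$score <= th
    tp <- sum(called & dat$label == "pos")
    fp <- sum(called & dat$label == "neg")
    tibble(threshold = th, n_called = sum(called), tp = tp, fp = fp,
           precision = tp / (tp + fp), recall = tp / n_pos)
  }) |> bind_rows()
  feasible <- curve[curve$precision >= precision_target, ]
  recall_at <- if (nrow(feasible)) max(feasible$recall) else 0
  structure(list(curve = curve, recall_at_precision = recall_at,
                 precision_target = precision_target,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf(
    "Precision-recall over %d positive / %d negative genes; recall %.3f at precision >= %.2f\n",
    x$n_pos, x$n_neg, x$recall_at_precision, x$precision_target))
  invisible(x)
}

#' Replicate correlation and clustering of sgRNA profiles
#'
#' Pearson correlations between per-guide LFC profiles on their shared
#' guides, and average-linkage hierarchical clustering on `1 - r`. Profiles
#' are sorted by name beforehand so the leaf order is deterministic.
#'
#' @param profiles Guides-by-profiles tibble (guide_id first) or matrix.
#' @return List of class `profile_correlation`: `r` (correlation matrix),
#'   `hclust`, `order` (leaf labels in plotting order).
#' @export
replicate_correlation <- function(profiles) {
  mat <- counts_to_matrix(profiles)
  if (ncol(mat) < 2L) abort("Need >= 2 profiles.")
  mat <- mat[complete.cases(mat), sort(colnames(mat)), drop = FALSE]
  if (nrow(mat) < 3L) abort("Fewer than 3 shared guides across profiles.")
  r <- cor(mat, method = "pearson")
  hc <- hclust(as.dist(1 - r), method = "average")
  structure(list(r = r, hclust = hc, order = colnames(r)[hc$order]),
            class = "profile_correlation")
}

#' PCA of sgRNA profiles
#'
#' Centered principal component analysis of samples in guide space. The sign
#' of each component is fixed so its largest-magnitude loading is positive,
#' making coordinates reproducible across platforms.
#'
#' @param profiles Guides-by-samples tibble (guide_id first) or matrix.
#' @param n_components Number of components to return (>= 2).
#' @return List of class `profile_pca`: `coords` (tibble sample, PC columns),
#'   `var_explained` (fractions), `loadings`.
#' @export
pca_profiles <- function(profiles, n_components = 2L) {
  mat <- counts_to_matrix(profiles)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (all(apply(mat, 2, sd) == 0) || sd(as.numeric(mat)) == 0) {
    abort("Profile matrix is constant; PCA undefined.")
  }
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(max(2L, n_components), ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    coords = bind_cols(tibble(sample_id = rownames(coords)),
                       as_tibble(coords, .name_repair = "minimal")),
    var_explained = ve[seq_len(k)],
    loadings = loadings
  ), class = "profile_pca")
}
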