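#' Benjamini-Hochberg adjustment with validation
#'
#' Standard BH step-up on a p-value vector; errors on values outside
#' \[0, 1\]. Adjusted values are monotone in the raw ranks and never smaller
#' than the raw p.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Per-sgRNA species-by-time count model
#'
#' Fits, for every sgRNA, a log-link negative-binomial GLM of raw counts on
#' individual fixed effects (nested within species) and species-specific
#' time effects, with median-ratio size factors as offsets:
#' `log mu = individual + beta_A * (t * 1[species A]) + beta_B * (t *
#' 1[species B])`. Overdispersion comes from the non-targeting trend
#' (a single quadratic trend, no per-guide shrinkage). The species terms are
#' contrasted to give each sgRNA a Wald p-value and a log2 fold-change
#' difference `beta_B - beta_A`; all three term p-value sets are BH-adjusted.
#' sgRNAs meeting `padj_diff < 0.01` and `|dlfc| >= 0.5` are flagged
#' `species_different`.
#'
#' @param counts Raw count tibble (guide_id + samples).
#' @param design Sample sheet; needs >= 2 individuals per species and both
#'   timepoints per individual.
#' @param library Guide library (NT flags for the dispersion trend and the
#'   guide-to-gene map).
#' @param alpha Overdispersion; default `NULL` estimates it as the median of
#'   the per-screen NT trend fits.
#' @return Tibble of class `sgrna_contrast`: per sgRNA `lfc_a`, `p_a`,
#'   `padj_a`, `lfc_b`, `p_b`, `padj_b`, `dlfc`, `p_diff`, `padj_diff`,
#'   `converged`, `species_different`. All-zero sgRNAs are dropped (ids in
#'   attribute `skipped`); attribute `alpha` records the dispersion used.
#' @export
fit_sgrna_contrast <- function(counts, design, library, alpha = NULL) {
  validate_sample_sheet(design, paired = TRUE)
  per_species <- design |>
    distinct(.data$species, .data$individual) |>
    dplyr::count(.data$species)
  if (any(per_species$n < 2L)) {
    abort("Need >= 2 individuals per species for individual fixed effects.")
  }
  norm <- median_ratio_normalize(counts)
  if (is.null(alpha)) {
    nt_ids <- library$guide_id[library$is_nt]
    if (length(nt_ids)) {
      nm <- fit_nt_null(norm$normalized, design, nt_ids)
      alpha <- median(nm$trend$alpha)
    } else {
      abort("No non-targeting guides; supply `alpha` explicitly.")
    }
  }
  alpha <- max(alpha, 1e-8)

  mat <- counts_to_matrix(counts)
  design <- design[match(colnames(mat), design$sample_id), ]
  sf <- norm$size_factors$size_factor[
    match(colnames(mat), norm$size_factors$sample_id)]
  offs <- log(sf)

  indiv <- factor(paste(design$species, design$individual, sep = ":"))
  tnum <- as.numeric(design$timepoint == "tfinal")
  spA <- sort(unique(design$species))[1]
  tA <- tnum * (design$species == spA)
  tB <- tnum * (design$species != spA)
  X <- model.matrix(~ indiv + tA + tB)
  iA <- which(colnames(X) == "tA")
  iB <- which(colnames(X) == "tB")
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  log2e <- 1 / log(2)

  skipped <- rownames(mat)[rowSums(mat) == 0]
  keep <- rownames(mat)[rowSums(mat) > 0]
  res <- purrr::map(keep, function(g) {
    y <- mat[g, ]
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, offset = offs)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || any(is.na(fit$coefficients))) {
      return(tibble(guide_id = g, lfc_a = NA_real_, p_a = 1,
                    lfc_b = NA_real_, p_b = 1, dlfc = NA_real_, p_diff = 1,
                    converged = FALSE))
    }
    w <- fit$weights
    V <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
    if (is.null(V)) {
      return(tibble(guide_id = g, lfc_a = NA_real_, p_a = 1,
                    lfc_b = NA_real_, p_b = 1, dlfc = NA_real_, p_diff = 1,
                    converged = FALSE))
    }
    bA <- unname(fit$coefficients[iA])
    bB <- unname(fit$coefficients[iB])
    seA <- sqrt(V[iA, iA]); seB <- sqrt(V[iB, iB])
    sed <- sqrt(V[iA, iA] + V[iB, iB] - 2 * V[iA, iB])
    tibble(
      guide_id = g,
      lfc_a = bA * log2e, p_a = 2 * pnorm(-abs(bA / seA)),
      lfc_b = bB * log2e, p_b = 2 * pnorm(-abs(bB / seB)),
      dlfc = (bB - bA) * log2e, p_diff = 2 * pnorm(-abs((bB - bA) / sed)),
      converged = TRUE
    )
  }) |> bind_rows()

  res <- res |>
    mutate(
      padj_a = adjust_pvalues(.data$p_a),
      padj_b = adjust_pvalues(.data$p_b),
      padj_diff = adjust_pvalues(.data$p_diff),
      species_different = .data$padj_diff < 0.01 & !is.na(.data$dlfc) &
        abs(.data$dlfc) >= 0.5
    ) |>
    left_join(select(library, "guide_id", "gene", "is_nt"),
              by = "guide_id") |>
    select("guide_id", "gene", "is_nt", dplyr::everything())
  class(res) <- c("sgrna_contrast", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "skipped") <- skipped
  attr(res, "species_a") <- spA
  res
}

rra_rho <- function(sorted_ranks, n_g, alpha) {
  below <- sorted_ranks[sorted_ranks <= alpha]
  j <- length(below)
  if (j == 0L) return(1)
  min(pbeta(below, seq_len(j), n_g - seq_len(j) + 1))
}

#' Alpha-robust rank aggregation of sgRNA p-values to genes
#'
#' MAGeCK-style alpha-RRA. Every sgRNA's adjusted p-value is converted to a
#' percentile rank over all supplied sgRNAs. For a gene with `n_g` sgRNAs,
#' only sgRNAs with rank percentile at or below the threshold `alpha`
#' contribute: the gene statistic is `rho = min_k Beta-CDF(r_(k); k, n_g - k
#' + 1)` over the contributing order statistics. By default `alpha` itself is
#' set to the fraction of all sgRNAs with adjusted p below `adj_threshold`
#' (0.01), so insignificant sgRNAs cannot influence gene significance. Gene
#' p-values come from a permutation null (random sgRNA ranks, stratified by
#' gene size, draws shared within a stratum) with the add-one correction,
#' and gene FDRs are BH. Genes with no sgRNA below `alpha` get p = 1.
#'
#' @param padj Adjusted sgRNA p-values (the ranking basis).
#' @param gene Gene id per sgRNA; `NA` entries (e.g. non-targeting) take part
#'   in the ranking but form no gene.
#' @param alpha Rank-percentile threshold; default derived from
#'   `adj_threshold`.
#' @param adj_threshold Adjusted-p cutoff defining the default `alpha`.
#' @param n_perm Permutation draws per gene-size stratum (default 10000).
#' @param seed RNG seed for the permutation null.
#' @return Tibble: `gene`, `n_sgrna`, `n_pass_alpha`, `rho`, `p`, `fdr`;
#'   attribute `alpha` is the threshold used.
#' @export
alpha_rra <- function(padj, gene, alpha = NULL, adj_threshold = 0.01,
                      n_perm = 10000L, seed = 1L) {
  ok <- !is.na(padj)
  n <- sum(ok)
  r_all <- rep(NA_real_, length(padj))
  r_all[ok] <- rank(padj[ok], ties.method = "average") / n
  alpha <- alpha %||% mean(padj[ok] < adj_threshold)
  genes_tab <- tibble(gene = gene, r = r_all) |>
    filter(!is.na(.data$gene), !is.na(.data$r)) |>
    group_by(.data$gene) |>
    summarise(n_sgrna = dplyr::n(),
              n_pass_alpha = sum(.data$r <= alpha),
              rho = rra_rho(sort(.data$r), dplyr::n(), alpha),
              .groups = "drop")
  if (alpha <= 0) {
    warn("alpha-RRA threshold is 0; all gene p-values set to 1.")
    out <- mutate(genes_tab, p = 1, fdr = 1)
    attr(out, "alpha") <- alpha
    return(out)
  }

  set.seed(seed)
  pool <- r_all[ok]
  p_of <- numeric(nrow(genes_tab))
  for (m in sort(unique(genes_tab$n_sgrna))) {
    idx <- which(genes_tab$n_sgrna == m)
    null_rho <- vapply(seq_len(n_perm), function(i) {
      rra_rho(sort(pool[sample.int(n, m)]), m, alpha)
    }, numeric(1))
    ecdf_sorted <- sort(null_rho)
    cnt <- findInterval(genes_tab$rho[idx], ecdf_sorted)
    p_of[idx] <- (1 + cnt) / (n_perm + 1)
  }
  p_of[genes_tab$n_pass_alpha == 0L] <- 1
  out <- mutate(genes_tab, p = p_of, fdr = adjust_pvalues(p_of))
  attr(out, "alpha") <- alpha
  out
}

#' Call species-specific genetic dependencies
#'
#' Aggregates the per-sgRNA contrast to genes with [alpha_rra()] (run on the
#' contrast term and on each species term), computes each gene's per-species
#' log2 fold-change as the mean of its four sgRNAs with the largest absolute
#' LFC, and applies the final three-condition caller: a gene is
#' species-specific iff (1) contrast-term gene FDR is below `fdr_threshold`,
#' (2) at least `min_pass` of its sgRNAs pass the alpha threshold, and
#' (3) the between-species gene LFC difference is at least `lfc_diff` —
#' unless the shared-effect exclusion removes it: any gene whose FDR in both
#' species terms is below the highest FDR reached by a gene with at least one
#' alpha-passing sgRNA (computed within each term) is discarded as shared.
#' The called species is the one with the larger absolute gene LFC.
#'
#' @param contrast An `sgrna_contrast` table from [fit_sgrna_contrast()].
#' @param fdr_threshold Contrast-term gene FDR cutoff (default 0.01).
#' @param min_pass Minimum alpha-passing sgRNAs (default 3).
#' @param lfc_diff Minimum between-species gene LFC difference (default 0.75).
#' @param use_contrast_lfc If `TRUE`, measure the gene LFC difference from
#'   the contrast-term sgRNA deltas (top-4) instead of the per-species terms.
#' @param n_perm,seed Passed to [alpha_rra()].
#' @return Tibble of class `species_calls`: per gene the three term FDRs,
#'   alpha-passing counts, per-species gene LFCs, `lfc_diff_gene`,
#'   `excluded_shared` and `call` in
#'   \{speciesA-specific, speciesB-specific, shared, none\}.
#' @export
call_species_specific <- function(contrast, fdr_threshold = 0.01,
                                  min_pass = 3L, lfc_diff = 0.75,
                                  use_contrast_lfc = FALSE,
                                  n_perm = 10000L, seed = 1L) {
  targ <- filter(contrast, !.data$is_nt)
  rra_d <- alpha_rra(contrast$padj_diff, contrast$gene, n_perm = n_perm,
                     seed = seed)
  rra_a <- alpha_rra(contrast$padj_a, contrast$gene, n_perm = n_perm,
                     seed = seed + 1L)
  rra_b <- alpha_rra(contrast$padj_b, contrast$gene, n_perm = n_perm,
                     seed = seed + 2L)

  top4 <- function(col) {
    targ |>
      select("gene", "guide_id", lfc = all_of(col)) |>
      filter(!is.na(.data$lfc)) |>
      gene_score(mode = "top_k", k = 4L, by = character())
  }
  ga <- suppressWarnings(top4("lfc_a"))
  gb <- suppressWarnings(top4("lfc_b"))
  gd <- suppressWarnings(top4("dlfc"))

  genes <- rra_d |>
    rename(n_pass_diff = "n_pass_alpha", fdr_diff = "fdr",
           p_diff = "p", rho_diff = "rho") |>
    left_join(select(rra_a, "gene", fdr_a = "fdr", n_pass_a = "n_pass_alpha"),
              by = "gene") |>
    left_join(select(rra_b, "gene", fdr_b = "fdr", n_pass_b = "n_pass_alpha"),
              by = "gene") |>
    left_join(select(ga, "gene", lfc_a_gene = "score"), by = "gene") |>
    left_join(select(gb, "gene", lfc_b_gene = "score"), by = "gene") |>
    left_join(select(gd, "gene", dlfc_gene = "score"), by = "gene")

  genes <- mutate(genes, lfc_diff_gene = if (use_contrast_lfc) {
    abs(.data$dlfc_gene)
  } else {
    abs(.data$lfc_a_gene - .data$lfc_b_gene)
  })

  thr_a <- suppressWarnings(max(genes$fdr_a[genes$n_pass_a >= 1L],
                                na.rm = TRUE))
  thr_b <- suppressWarnings(max(genes$fdr_b[genes$n_pass_b >= 1L],
                                na.rm = TRUE))
  if (!is.finite(thr_a)) thr_a <- -Inf
  if (!is.finite(thr_b)) thr_b <- -Inf

  genes <- genes |>
    mutate(
      excluded_shared = .data$fdr_a < thr_a & .data$fdr_b < thr_b,
      passes = .data$fdr_diff < fdr_threshold &
        .data$n_pass_diff >= min_pass &
        .data$lfc_diff_gene >= lfc_diff,
      call = dplyr::case_when(
        passes & excluded_shared ~ "shared",
        passes & abs(lfc_a_gene) >= abs(lfc_b_gene) ~ "speciesA-specific",
        passes ~ "speciesB-specific",
        TRUE ~ "none"
      )
    ) |>
    select(-"passes")
  class(genes) <- c("species_calls", class(genes))
  attr(genes, "alpha_rra") <- attr(rra_d, "alpha")
  attr(genes, "exclusion_thresholds") <- c(a = thr_a, b = thr_b)
  attr(genes, "thresholds") <- list(fdr = fdr_threshold, min_pass = min_pass,
                                    lfc_diff = lfc_diff)
  genes
}

#' Run the full validation-screen pipeline
#'
#' Convenience wrapper: [fit_sgrna_contrast()] then
#' [call_species_specific()].
#'
#' @inheritParams fit_sgrna_contrast
#' @inheritParams call_species_specific
#' @return List of class `crispr_contrast` with `sgrna` and `genes` tables.
#' @export
run_validation_pipeline <- function(counts, design, library, alpha = NULL,
                                    fdr_threshold = 0.01, min_pass = 3L,
                                    lfc_diff = 0.75, n_perm = 10000L,
                                    seed = 1L) {
  sg <- fit_sgrna_contrast(counts, design, library, alpha = alpha)
  genes <- call_species_specific(sg, fdr_threshold = fdr_threshold,
                                 min_pass = min_pass, lfc_diff = lfc_diff,
                                 n_perm = n_perm, seed = seed)
  structure(list(sgrna = sg, genes = genes), class = "crispr_contrast")
}

#' @export
print.crispr_contrast <- function(x, ...) {
  called <- sum(x$genes$call %in% c("speciesA-specific", "speciesB-specific"))
  cat(sprintf(
    "Species-contrast analysis: %d sgRNAs, %d genes, %d species-specific calls\n",
    nrow(x$sgrna), nrow(x$genes), called))
  invisible(x)
}

#' Flag genes whose effect depends on p53 responsiveness
#'
#' Welch two-tailed t-test, per gene, comparing gene scores between the
#' responsive and unresponsive cell lines of one species. Exploratory flag;
#' degenerate (constant) genes report p = 1.
#'
#' @param line_scores Long tibble: `gene`, `line`, `score`.
#' @param responsive Tibble: `line`, `responsive` (logical).
#' @param threshold Flag threshold (default 0.05, exploratory).
#' @return Tibble: `gene`, `statistic`, `p`, `flag`, `degenerate`.
#' @export
flag_p53_dependence <- function(line_scores, responsive, threshold = 0.05) {
  dat <- left_join(line_scores, responsive, by = "line")
  if (anyNA(dat$responsive)) {
    abort("Every line needs a `responsive` flag.")
  }
  sizes <- dat |>
    distinct(.data$line, .data$responsive) |>
    dplyr::count(.data$responsive)
  if (nrow(sizes) < 2L || any(sizes$n < 2L)) {
    abort("Both responsiveness groups need >= 2 lines.")
  }
  dat |>
    group_by(.data$gene) |>
    summarise(
      res = list(tryCatch(
        t.test(.data$score[!.data$responsive],
               .data$score[.data$responsive]),
        error = function(e) NULL
      )),
      .groups = "drop"
    ) |>
    mutate(
      statistic = purrr::map_dbl(.data$res,
                                 ~ if (is.null(.x)) NA_real_
                                   else unname(.x$statistic)),
      p = purrr::map_dbl(.data$res, ~ if (is.null(.x)) 1 else .x$p.value),
      degenerate = purrr::map_lgl(.data$res, is.null) | is.nan(.data$p),
      p = if_else(is.nan(.data$p), 1, .data$p),
      flag = .data$p < threshold
    ) |>
    select(-"res")
}

#' Partition per-sgRNA variance across design factors
#'
#' Estimates, for every sgRNA, the variance attributable to species,
#' individual (nested within species) and timepoint under a random-intercept
#' model, using a sequential ANOVA (Henderson method-of-moments) estimator:
#' expected sums of squares are equated to their observed values and the
#' resulting linear system is solved per sgRNA, components truncated at zero
#' and reported as fractions summing to 1. The projection matrices depend
#' only on the design, so the estimator is a single matrix product across
#' all sgRNAs. Gene-level values are the mean fractions over the gene's
#' sgRNAs.
#'
#' @param values Guides-by-samples tibble (guide_id first) or matrix of
#'   responses (e.g. log-normalized counts or LFC-scale values).
#' @param design Sample sheet matching the value columns.
#' @param gene_map Optional tibble `guide_id`, `gene` for gene-level means.
#' @return List with `per_sgrna` (guide_id + fraction per component) and,
#'   when `gene_map` is given, `per_gene`.
#' @export
variance_partition <- function(values, design, gene_map = NULL) {
  Y <- counts_to_matrix(values)
  design <- design[match(colnames(Y), design$sample_id), ]
  n <- ncol(Y)
  fac <- list(
    species = factor(design$species),
    individual = factor(paste(design$species, design$individual, sep = ":")),
    timepoint = factor(design$timepoint)
  )
  for (nm in names(fac)) {
    if (nlevels(fac[[nm]]) < 2L) {
      abort(sprintf("Factor '%s' has fewer than 2 levels.", nm))
    }
  }

  proj <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  X0 <- matrix(1, n, 1)
  Xs <- model.matrix(~ 0 + fac$species)
  Xi <- model.matrix(~ 0 + fac$individual)
  Xt <- cbind(Xi, model.matrix(~ 0 + fac$timepoint))
  P0 <- proj(X0)
  P1 <- proj(Xs)
  P2 <- proj(Xi)
  r1 <- qr(Xs)$rank; r2 <- qr(Xi)$rank; r3 <- qr(Xt)$rank
  if (r2 <= r1) {
    abort("Factors 'species' and 'individual' are aliased (one individual per species level).")
  }
  if (r3 <= r2) {
    abort("Factor 'timepoint' is aliased with 'individual'.")
  }
  P3 <- proj(Xt)
  H <- list(species = P1 - P0, individual = P2 - P1, timepoint = P3 - P2,
            residual = diag(n) - P3)

  Z <- list(species = model.matrix(~ 0 + fac$species),
            individual = model.matrix(~ 0 + fac$individual),
            timepoint = model.matrix(~ 0 + fac$timepoint))
  comp <- c("species", "individual", "timepoint", "residual")
  C <- matrix(0, 4, 4, dimnames = list(comp, comp))
  for (k in seq_along(H)) {
    for (f in 1:3) {
      C[k, f] <- sum(H[[k]] * tcrossprod(Z[[f]]))
    }
    C[k, 4] <- sum(diag(H[[k]]))
  }

  SS <- vapply(H, function(Hk) rowSums((Y %*% Hk) * Y), numeric(nrow(Y)))
  SS <- matrix(SS, nrow = nrow(Y),
               dimnames = list(rownames(Y), comp))
  sigma2 <- t(solve(C, t(SS)))
  sigma2[sigma2 < 0] <- 0
  tot <- rowSums(sigma2)
  frac <- sigma2 / ifelse(tot > 0, tot, 1)
  frac[tot == 0, ] <- c(0, 0, 0, 1)

  per_sgrna <- bind_cols(tibble(guide_id = rownames(Y)),
                         as_tibble(frac, .name_repair = "minimal"))
  out <- list(per_sgrna = per_sgrna)
  if (!is.null(gene_map)) {
    out$per_gene <- per_sgrna |>
      left_join(gene_map, by = "guide_id") |>
      filter(!is.na(.data$gene)) |>
      group_by(.data$gene) |>
      summarise(across(all_of(comp), mean), .groups = "drop")
  }
  out
}
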