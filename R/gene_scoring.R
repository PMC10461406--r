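#' Gene scores from per-guide log2 fold-changes
#'
#' Two conventions. `"retained_mean"`: the mean LFC over guides passing the
#' upstream filters (perfect cross-species match plus per-guide significance;
#' supply the logical in `retained`) — genes with no retained guide get a
#' missing score. `"top_k"`: the mean of the `k` guides with the largest
#' absolute LFC (k = 3 is the genome-wide convention, k = 4 the validation
#' convention); ties break by guide id, and genes with fewer than `k` guides
#' use all of them with a warning.
#'
#' @param lfc_table Tibble with columns `gene`, `guide_id`, `lfc`, optionally
#'   `retained`, and any grouping keys (e.g. species, individual).
#' @param mode `"retained_mean"` or `"top_k"`.
#' @param k Number of guides for `"top_k"`.
#' @param by Character vector of extra grouping columns; defaults to every
#'   column other than gene/guide_id/lfc/retained.
#' @return Tibble with the grouping keys, `gene`, `score`, `n_guides`.
#' @export
#' @examples
#' toy <- tibble::tibble(gene = "g", guide_id = paste0("s", 1:5),
#'                       lfc = c(-4, -3, -1, 0, 0))
#' gene_score(toy, mode = "top_k", k = 3)$score  # -2.667
gene_score <- function(lfc_table, mode = c("retained_mean", "top_k"),
                       k = 3L, by = NULL) {
  mode <- match.arg(mode)
  by <- by %||% setdiff(names(lfc_table),
                        c("gene", "guide_id", "lfc", "retained"))
  grouped <- lfc_table |>
    filter(!is.na(.data$gene)) |>
    group_by(across(all_of(c(by, "gene"))))
  if (mode == "retained_mean") {
    if (!"retained" %in% names(lfc_table)) {
      abort("`retained_mean` mode needs a logical `retained` column.")
    }
    out <- grouped |>
      summarise(
        score = if (any(.data$retained)) mean(.data$lfc[.data$retained])
                else NA_real_,
        n_guides = sum(.data$retained),
        .groups = "drop"
      )
  } else {
    sizes <- grouped |> summarise(n = dplyr::n(), .groups = "drop")
    if (any(sizes$n < k)) {
      warn(sprintf("%d gene group(s) have fewer than k = %d guides; using all available.",
                   sum(sizes$n < k), k))
    }
    out <- grouped |>
      arrange(desc(abs(.data$lfc)), .data$guide_id, .by_group = TRUE) |>
      summarise(
        score = mean(.data$lfc[seq_len(min(k, dplyr::n()))]),
        n_guides = min(k, dplyr::n()),
        .groups = "drop"
      )
  }
  out
}

#' Bootstrap gene-level significance from non-targeting guides
#'
#' Builds an empirical null for each gene's retained-mean score by averaging
#' groups of non-targeting LFCs: a gene scored from `m` retained guides is
#' compared against `n_boot` means of `m` NT LFCs (group size matched to `m`,
#' 1-5, preserving the variance of the mean; set `match_size = FALSE` to draw
#' the size uniformly from 1-5 instead). Two-sided empirical p-values use the
#' add-one correction, and gene FDRs are Benjamini-Hochberg across genes.
#'
#' @param scores Tibble from [gene_score()] (needs `gene`, `score`,
#'   `n_guides`; extra key columns are carried through). Genes with
#'   `n_guides` of 0 or missing scores are excluded.
#' @param nt_lfc Numeric pool of non-targeting LFCs (>= 50 recommended).
#' @param n_boot Null draws per group-size stratum (default 10000).
#' @param seed RNG seed.
#' @param replace Draw NT guides with replacement (default TRUE).
#' @param match_size Match the null group size to the gene's retained count.
#' @return `scores` with columns `boot_p` and `boot_fdr` added.
#' @export
bootstrap_gene_fdr <- function(scores, nt_lfc, n_boot = 10000L, seed = 1L,
                               replace = TRUE, match_size = TRUE) {
  if (length(nt_lfc) < 50L) {
    warn(sprintf("NT pool has %d LFCs; >= 50 recommended.", length(nt_lfc)))
  }
  keep <- !is.na(scores$score) & scores$n_guides >= 1L
  out <- scores[keep, ]
  set.seed(seed)
  sizes <- sort(unique(pmin(pmax(out$n_guides, 1L), 5L)))
  null_abs <- lapply(setNames(sizes, sizes), function(m) {
    mm <- if (match_size) m else sample(1:5, n_boot, replace = TRUE)
    if (match_size) {
      draws <- matrix(sample(nt_lfc, n_boot * m, replace = replace),
                      nrow = m)
      abs(colMeans(draws))
    } else {
      vapply(mm, function(g) {
        abs(mean(sample(nt_lfc, g, replace = replace)))
      }, numeric(1))
    }
  })
  m_of <- as.character(pmin(pmax(out$n_guides, 1L), 5L))
  out$boot_p <- vapply(seq_len(nrow(out)), function(i) {
    nulls <- null_abs[[m_of[i]]]
    (1 + sum(nulls >= abs(out$score[i]))) / (length(nulls) + 1)
  }, numeric(1))
  out$boot_fdr <- p.adjust(out$boot_p, method = "BH")
  out
}

#' Direction scores per gene and per species
#'
#' The direction score of a gene in one screen is the number of its
#' significantly depleted sgRNAs minus the number significantly enriched.
#' The species score is the sum over that species' screens.
#'
#' @param stats An `sgrna_stats` table (or any tibble with gene, species,
#'   individual, call).
#' @param library Guide library (maps guide_id to gene if `stats` lacks one).
#' @return List with `per_screen` (gene, species, individual,
#'   direction_score) and `per_species` (gene, species, direction_score).
#' @export
direction_scores <- function(stats, library = NULL) {
  if (!"gene" %in% names(stats)) {
    if (is.null(library)) abort("Provide `library` to map guides to genes.")
    stats <- left_join(stats, select(library, "guide_id", "gene"),
                       by = "guide_id")
  }
  per_screen <- stats |>
    filter(!is.na(.data$gene)) |>
    group_by(.data$gene, .data$species, .data$individual) |>
    summarise(
      direction_score = sum(.data$call == "depleted") -
        sum(.data$call == "enriched"),
      .groups = "drop"
    )
  per_species <- per_screen |>
    group_by(.data$gene, .data$species) |>
    summarise(direction_score = sum(.data$direction_score), .groups = "drop")
  list(per_screen = per_screen, per_species = per_species)
}

#' Classify genes as essential / nonessential per screen
#'
#' A gene is essential in a screen when it ranks within the `top_n` most
#' depleted genes *and* its score shows more than 4-fold mean depletion
#' (score <= -2); nonessential when depletion is less than 2-fold
#' (score > -1); intermediate otherwise. Ties at the `top_n` boundary are all
#' included. Intersection sets over screens apply the dual inclusion rule:
#' a gene belongs to set S when it is essential in every screen in S and
#' nonessential in every screen outside S.
#'
#' @param scores Tibble with `gene`, `score` and a `screen` column naming the
#'   screen (build one with e.g. `paste(species, individual)`).
#' @param top_n Depletion rank cutoff (default 3000).
#' @param essential_max_score Essential score ceiling (default -2).
#' @param nonessential_min_score Nonessential score floor, exclusive
#'   (default -1).
#' @return List with `classes` (gene, screen, class) and `intersections`
#'   (set, gene) where `set` names the member screens, `+`-separated.
#' @export
classify_essentiality <- function(scores, top_n = 3000L,
                                  essential_max_score = -2,
                                  nonessential_min_score = -1) {
  screens <- unique(scores$screen)
  classes <- scores |>
    group_by(.data$screen) |>
    mutate(
      rank = rank(.data$score, ties.method = "min"),
      class = dplyr::case_when(
        .data$rank <= min(top_n, dplyr::n()) &
          .data$score <= essential_max_score ~ "essential",
        .data$score > nonessential_min_score ~ "nonessential",
        TRUE ~ "intermediate"
      )
    ) |>
    ungroup() |>
    select("gene", "screen", "class")
  if (top_n > length(unique(scores$gene))) {
    warn("`top_n` exceeds the number of genes; using all genes.")
  }

  wide <- tidyr::pivot_wider(classes, names_from = "screen",
                             values_from = "class")
  full <- wide[complete.cases(wide), ]
  subsets <- unlist(lapply(seq_along(screens), function(k) {
    utils::combn(screens, k, simplify = FALSE)
  }), recursive = FALSE)
  inter <- purrr::map(subsets, function(s) {
    members <- s
    non <- setdiff(screens, s)
    ok <- rep(TRUE, nrow(full))
    for (sc in members) ok <- ok & full[[sc]] == "essential"
    for (sc in non) ok <- ok & full[[sc]] == "nonessential"
    if (!any(ok)) return(NULL)
    tibble(set = paste(sort(members), collapse = "+"),
           gene = full$gene[ok])
  }) |> bind_rows()
  list(classes = classes, intersections = inter)
}

#' Candidate selection criteria for a cross-species validation library
#'
#' Evaluates, verbatim as published, the twelve magnitude- and
#' direction-score-based selection sets plus the per-line 10%/25% FDR rule,
#' and labels every gene with each set it satisfies. Species A plays the
#' human role and species B the chimpanzee role; each species contributes two
#' screened lines (1 and 2). Set-2 criteria keep the published per-line
#' asymmetries. A gene may carry several labels; the union is the candidate
#' list.
#'
#' @param gene_table Tibble with one row per gene and columns: `gene`,
#'   `a_avg`, `b_avg` (species-level mean gene scores), `fdr_a1`, `fdr_a2`,
#'   `fdr_b1`, `fdr_b2` (per-line bootstrap FDRs; optional — FDR-dependent
#'   sets are skipped with a warning when absent), `ds_a1`, `ds_a2`, `ds_b1`,
#'   `ds_b2` (per-line direction scores; optional likewise).
#' @param fdr Set-membership FDR threshold (default 0.05).
#' @param rule_fdr_in,rule_fdr_out The per-line FDR rule: below
#'   `rule_fdr_in` in both lines of one species, above `rule_fdr_out` in both
#'   lines of the other (defaults 0.10 / 0.25).
#' @return List with `labels` (long tibble gene, set), `matrix` (wide logical
#'   tibble) and `candidates` (character vector, the union).
#' @export
candidate_selection <- function(gene_table, fdr = 0.05,
                                rule_fdr_in = 0.10, rule_fdr_out = 0.25) {
  gt <- gene_table
  need_avg <- c("a_avg", "b_avg")
  if (!all(need_avg %in% names(gt))) {
    abort("`gene_table` needs species-average columns `a_avg`, `b_avg`.")
  }
  have_fdr <- all(c("fdr_a1", "fdr_a2", "fdr_b1", "fdr_b2") %in% names(gt))
  have_ds <- all(c("ds_a1", "ds_a2", "ds_b1", "ds_b2") %in% names(gt))
  if (!have_fdr) {
    warn("Per-line FDR columns missing; FDR-dependent sets skipped.")
  }
  if (!have_ds) {
    warn("Per-line direction-score columns missing; direction-score sets skipped.")
  }

  sets <- list()
  f <- function(x) if_else(is.na(x), FALSE, x)
  if (have_fdr) {
    fa <- gt$fdr_a1 < fdr & gt$fdr_a2 < fdr
    fb <- gt$fdr_b1 < fdr & gt$fdr_b2 < fdr
    fall <- fa & fb
    sets$a_essential_set1 <- f(
      gt$b_avg > -1 & gt$b_avg < 1 & gt$a_avg < -2 &
        (gt$a_avg - gt$b_avg) < -2 & fa)
    sets$a_enriched_set1 <- f(
      gt$b_avg > -1 & gt$b_avg < 1 & gt$a_avg > 1 &
        (gt$a_avg - gt$b_avg) > 0.2 & fa)
    sets$b_essential_set1 <- f(
      gt$b_avg < -2 & gt$a_avg < 1 & gt$a_avg > -1 &
        (gt$a_avg - gt$b_avg) > 2 & fb)
    sets$b_enriched_set1 <- f(
      gt$b_avg > 2 & gt$a_avg < 1 & gt$a_avg > -1 &
        (gt$a_avg - gt$b_avg) < -2 & fb)
    sets$b_essential_a_enriched <- f(
      gt$b_avg < -0.8 & gt$a_avg > 0.4 & (gt$a_avg - gt$b_avg) > 0.2 & fall)
    sets$a_essential_b_enriched <- f(
      gt$b_avg > 0.8 & gt$a_avg < -0.8 & (gt$a_avg - gt$b_avg) < -0.2 & fall)
    sets$both_essential_a_more <- f(
      gt$b_avg < -1 & gt$a_avg < -2.5 & (gt$a_avg / gt$b_avg) > 2 & fall)
    sets$both_essential_b_more <- f(
      gt$b_avg < -3 & gt$a_avg < -1 & (gt$a_avg / gt$b_avg) < 0.3 & fall)
    sets$fdr_rule_a <- f(
      gt$fdr_a1 < rule_fdr_in & gt$fdr_a2 < rule_fdr_in &
        gt$fdr_b1 > rule_fdr_out & gt$fdr_b2 > rule_fdr_out)
    sets$fdr_rule_b <- f(
      gt$fdr_b1 < rule_fdr_in & gt$fdr_b2 < rule_fdr_in &
        gt$fdr_a1 > rule_fdr_out & gt$fdr_a2 > rule_fdr_out)
  }
  if (have_ds) {
    ads <- gt$ds_a1 + gt$ds_a2
    bds <- gt$ds_b1 + gt$ds_b2
    lratio <- suppressWarnings(log2(abs(ads / bds)))
    sets$a_essential_set2 <- f(
      ads > 4 & gt$ds_a1 >= 2 & gt$ds_a2 >= 2 & (ads - bds) >= 4)
    sets$a_enriched_set2 <- f(
      ads < -4 & gt$ds_a1 <= -1 & gt$ds_a2 <= -2 & (ads - bds) <= -3 &
        lratio >= 1)
    # published criterion opens on the species-A sum; kept verbatim
    sets$b_essential_set2 <- f(
      ads > 4 & gt$ds_b1 >= -1 & gt$ds_b2 >= -2 & (bds - ads) >= 4 &
        lratio >= 1)
    sets$b_enriched_set2 <- f(
      bds < -4 & gt$ds_b1 <= -2 & gt$ds_b2 <= -2 & (bds - ads) <= -4 &
        lratio >= 1)
  }

  mat <- if (length(sets)) {
    bind_cols(tibble(gene = gt$gene), as_tibble(sets))
  } else {
    tibble(gene = gt$gene)
  }
  labels <- if (length(sets)) {
    tidyr::pivot_longer(mat, -"gene", names_to = "set",
                        values_to = "member") |>
      filter(.data$member) |>
      select("gene", "set")
  } else {
    tibble(gene = character(), set = character())
  }
  list(labels = labels, matrix = mat,
       candidates = sort(unique(labels$gene)))
}
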