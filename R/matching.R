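#' Find protospacer target sites in a genome
#'
#' Scans both strands of every contig for occurrences of the spacer with at
#' most `max_mismatch` substitutions inside the protospacer, requiring an
#' exactly matching NGG PAM immediately 3' of the protospacer (PAM mismatches
#' are never tolerated). Coordinates are 0-based, half-open, on the forward
#' strand; for minus-strand sites the reported interval still covers the
#' protospacer in forward coordinates.
#'
#' @param spacer A spacer sequence over A/C/G/T (typically 19-20 nt).
#' @param genome A [Biostrings::DNAStringSet-class] or path to a FASTA file.
#' @param max_mismatch Maximum substitutions allowed in the protospacer (<= 3).
#' @return Tibble with columns `contig`, `start` (0-based), `strand`,
#'   `mismatches`, sorted by (contig, start).
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTTACGTACGTACGTACGTACGTAGGTTT"))
#' find_target_sites("ACGTACGTACGTACGTACGT", g)
find_target_sites <- function(spacer, genome, max_mismatch = 0L) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- read_genome_fasta(genome)
  }
  spacer <- toupper(spacer)
  if (grepl("[^ACGT]", spacer)) {
    abort(sprintf("Spacer contains ambiguous bases: '%s'", spacer))
  }
  if (max_mismatch > 3L) abort("`max_mismatch` must be <= 3.")
  L <- nchar(spacer)
  pat_fwd <- Biostrings::DNAString(spacer)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)

  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }

  res <- purrr::map(seq_along(genome), function(ci) {
    subject <- genome[[ci]]
    seq_chr <- as.character(subject)
    n <- length(subject)
    out <- list()

    m <- Biostrings::matchPattern(pat_fwd, subject,
                                  max.mismatch = max_mismatch)
    st <- Biostrings::start(m)
    keep <- st + L + 2L <= n + 1L  # PAM must fit: positions st+L .. st+L+2
    st <- st[keep]
    if (length(st)) {
      pam <- substring(seq_chr, st + L, st + L + 2L)
      ok <- substring(pam, 2L, 3L) == "GG"
      st <- st[ok]
      if (length(st)) {
        mm <- vapply(st, function(s) {
          hamming(substring(seq_chr, s, s + L - 1L), spacer)
        }, numeric(1))
        out$fwd <- tibble(contig = names(genome)[ci], start = st - 1L,
                          strand = "+", mismatches = as.integer(mm))
      }
    }

    m <- Biostrings::matchPattern(pat_rev, subject,
                                  max.mismatch = max_mismatch)
    st <- Biostrings::start(m)
    keep <- st - 3L >= 1L  # PAM (revcomp NGG = CCN) at st-3 .. st-1
    st <- st[keep]
    if (length(st)) {
      pam <- substring(seq_chr, st - 3L, st - 1L)
      ok <- substring(pam, 1L, 2L) == "CC"
      st <- st[ok]
      if (length(st)) {
        rc_sp <- as.character(pat_rev)
        mm <- vapply(st, function(s) {
          hamming(substring(seq_chr, s, s + L - 1L), rc_sp)
        }, numeric(1))
        out$rev <- tibble(contig = names(genome)[ci], start = st - 1L,
                          strand = "-", mismatches = as.integer(mm))
      }
    }
    bind_rows(out)
  })
  res <- bind_rows(res)
  if (!nrow(res)) {
    return(tibble(contig = character(), start = integer(),
                  strand = character(), mismatches = integer()))
  }
  arrange(res, .data$contig, .data$start)
}

#' Cross-species perfect-match guide filter
#'
#' Annotates every guide with its number of perfect-match PAM-adjacent sites
#' in each genome and retains targeting guides with at least one perfect site
#' in both. Non-targeting guides pass vacuously and stay flagged as NT.
#'
#' @param library Guide library tibble.
#' @param genome_a,genome_b Genomes ([Biostrings::DNAStringSet-class] or FASTA
#'   paths).
#' @return List with `annotation` (guide_id, is_nt, n_perfect_a, n_perfect_b,
#'   perfect_in_both) and `retained` (the filtered library, NT guides
#'   included).
#' @export
cross_species_filter <- function(library, genome_a, genome_b) {
  if (is.character(genome_a)) genome_a <- read_genome_fasta(genome_a)
  if (is.character(genome_b)) genome_b <- read_genome_fasta(genome_b)
  n_sites <- function(spacer, genome) {
    nrow(find_target_sites(spacer, genome, max_mismatch = 0L))
  }
  ann <- library |>
    mutate(
      n_perfect_a = if_else(.data$is_nt, NA_integer_,
        unname(vapply(.data$spacer, n_sites, integer(1), genome = genome_a))),
      n_perfect_b = if_else(.data$is_nt, NA_integer_,
        unname(vapply(.data$spacer, n_sites, integer(1), genome = genome_b))),
      perfect_in_both = !.data$is_nt & .data$n_perfect_a >= 1L &
        .data$n_perfect_b >= 1L
    ) |>
    select("guide_id", "is_nt", "n_perfect_a", "n_perfect_b",
           "perfect_in_both")
  retained <- library[library$is_nt |
                        ann$perfect_in_both[match(library$guide_id,
                                                  ann$guide_id)], ]
  list(annotation = ann, retained = retained)
}

#' Minimum-guide coverage filter for gene-level analysis
#'
#' Drops genes (TSSs) covered by fewer than `min_guides` retained targeting
#' guides; genes below the threshold cannot support a stable gene score.
#'
#' @param retained Filtered library tibble (e.g. from
#'   [cross_species_filter()]`$retained`).
#' @param min_guides Minimum retained guides per gene (default 3).
#' @return The library restricted to kept genes (NT guides untouched), with
#'   attribute `dropped_genes`.
#' @export
tss_coverage_filter <- function(retained, min_guides = 3L) {
  cov <- retained |>
    filter(!.data$is_nt) |>
    dplyr::count(.data$gene)
  dropped <- cov$gene[cov$n < min_guides]
  out <- retained[retained$is_nt | !(retained$gene %in% dropped), ]
  attr(out, "dropped_genes") <- dropped
  out
}

#' Select guides for a validation library
#'
#' Applies the validation-library design rules per gene: off-target filtering
#' (exactly one perfect-match site per genome, specificity score above
#' `min_specificity`, maximal predicted off-target activity below
#' `max_offtarget`), an on-target activity floor, TSS-position bucketing, and
#' ranking by on-target score within bucket. Previously validated guides
#' (logical column `validated`, optional) are retained first. Ties break by
#' descending score then lexicographic guide id, so selection is
#' deterministic. Scores are consumed as annotation columns, never computed
#' here.
#'
#' @param candidates Tibble with columns guide_id, gene, tss_offset,
#'   on_target_score, specificity_score, max_offtarget_activity, n_perfect_a,
#'   n_perfect_b and optionally validated.
#' @param n_per_gene Guides to select per gene (default 8).
#' @param min_on_target On-target score floor; guides below are excluded
#'   (default 0.4378, one standard deviation below the design pool's mean in
#'   the reference library).
#' @param min_specificity Specificity score must exceed this (default 0.20).
#' @param max_offtarget Max predicted off-target activity must be below this
#'   (default 0.80).
#' @param tss_windows List of `c(lo, hi)` half-open windows of TSS offset in
#'   priority order; guides are bucketed by the first window containing their
#'   offset, and earlier windows outrank later ones.
#' @return Tibble of selected guides with `tss_bucket` and `rank_in_gene`;
#'   genes with fewer than `n_per_gene` surviving guides are kept with a
#'   warning.
#' @export
select_validation_guides <- function(candidates,
                                     n_per_gene = 8L,
                                     min_on_target = 0.4378,
                                     min_specificity = 0.20,
                                     max_offtarget = 0.80,
                                     tss_windows = list(c(0, 100),
                                                        c(100, 200),
                                                        c(-50, 0),
                                                        c(200, 300))) {
  need <- c("guide_id", "gene", "tss_offset", "on_target_score",
            "specificity_score", "max_offtarget_activity",
            "n_perfect_a", "n_perfect_b")
  missing_cols <- setdiff(need, names(candidates))
  if (length(missing_cols)) {
    abort(sprintf("`candidates` lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"validated" %in% names(candidates)) candidates$validated <- FALSE

  bucket_of <- function(off) {
    for (i in seq_along(tss_windows)) {
      w <- tss_windows[[i]]
      if (!is.na(off) && off >= w[1] && off < w[2]) return(i)
    }
    length(tss_windows) + 1L
  }

  surviving <- candidates |>
    filter(
      .data$n_perfect_a == 1L, .data$n_perfect_b == 1L,
      .data$specificity_score > min_specificity,
      .data$max_offtarget_activity < max_offtarget,
      .data$on_target_score >= min_on_target
    ) |>
    mutate(tss_bucket = vapply(.data$tss_offset, bucket_of, integer(1)))

  selected <- surviving |>
    arrange(.data$gene, desc(.data$validated), .data$tss_bucket,
            desc(.data$on_target_score), .data$guide_id) |>
    group_by(.data$gene) |>
    mutate(rank_in_gene = row_number()) |>
    filter(.data$rank_in_gene <= n_per_gene) |>
    ungroup()

  short <- selected |>
    dplyr::count(.data$gene) |>
    filter(.data$n < n_per_gene)
  if (nrow(short)) {
    warn(sprintf("%d gene(s) have fewer than %d surviving guides: %s",
                 nrow(short), n_per_gene,
                 paste(head(short$gene, 5), collapse = ", ")))
  }
  selected
}
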