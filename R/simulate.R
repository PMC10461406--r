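#' Configuration for a synthetic two-species CRISPRi screen
#'
#' Bundles every tunable of the screen simulator. The defaults describe a
#' desk-scale genome-wide CRISPRi fitness screen: ~5 sgRNAs per gene plus a
#' pool of non-targeting (NT) controls, deep starting coverage, modest
#' negative-binomial overdispersion, a minority of genes with fitness effects,
#' and a fraction of guides whose target site in species B carries mismatches.
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene sgRNAs designed per gene (library convention: 5).
#' @param n_nt_guides Number of non-targeting control sgRNAs.
#' @param lines_per_species Cell lines (individuals) screened per species.
#' @param reps_per_line Technical replicates per line and timepoint.
#' @param mean_t0_depth Expected sequencing reads per guide at t0.
#' @param dispersion_alpha Negative-binomial overdispersion: counts are drawn
#'   with variance `mu + alpha * mu^2`. Real screens rarely report their
#'   dispersion; 0.05 is a typical value for deep-coverage pooled screens
#'   and is this package's documented default.
#' @param frac_shared_essential Fraction of genes with a fitness effect shared
#'   by both species (negative draws are shared-essential, positive draws are
#'   proliferation suppressors).
#' @param frac_species_specific Fraction of genes whose effect is present in
#'   exactly one species. Must satisfy
#'   `frac_shared_essential + frac_species_specific <= 1`.
#' @param effect_lfc_mean,effect_lfc_sd Normal draw for the true fitness
#'   effect gamma, expressed as total log2 change in relative abundance over
#'   the screen (t0 to tfinal, not a per-day rate).
#' @param guide_activity_range Length-2 numeric in \[0,1\]: each targeting
#'   guide's knockdown activity `a` is drawn uniformly in this range and
#'   multiplies gamma in log2 space.
#' @param frac_mismatch_in_B Fraction of targeting guides whose embedded
#'   target site in the species-B genome receives 1-3 substitutions. The
#'   default 0.226 reproduces a 77.4% perfect-match rate.
#' @param seed Master seed. Each artifact (library, genomes, counts) uses its
#'   own stream derived from this seed, so regenerating one artifact with a
#'   changed parameter leaves the others untouched.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, n_nt_guides = 10)
#' sim <- simulate_library(cfg)
#' dplyr::count(sim$library, is_nt)
sim_config <- function(n_genes = 100,
                       guides_per_gene = 5,
                       n_nt_guides = 50,
                       lines_per_species = 2,
                       reps_per_line = 2,
                       mean_t0_depth = 500,
                       dispersion_alpha = 0.05,
                       frac_shared_essential = 0.2,
                       frac_species_specific = 0.1,
                       effect_lfc_mean = -3,
                       effect_lfc_sd = 1,
                       guide_activity_range = c(0.5, 1),
                       frac_mismatch_in_B = 0.226,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    guides_per_gene = as.integer(guides_per_gene),
    n_nt_guides = as.integer(n_nt_guides),
    lines_per_species = as.integer(lines_per_species),
    reps_per_line = as.integer(reps_per_line),
    mean_t0_depth = as.numeric(mean_t0_depth),
    dispersion_alpha = as.numeric(dispersion_alpha),
    frac_shared_essential = as.numeric(frac_shared_essential),
    frac_species_specific = as.numeric(frac_species_specific),
    effect_lfc_mean = as.numeric(effect_lfc_mean),
    effect_lfc_sd = as.numeric(effect_lfc_sd),
    guide_activity_range = as.numeric(guide_activity_range),
    frac_mismatch_in_B = as.numeric(frac_mismatch_in_B),
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "guides_per_gene", "n_nt_guides",
              "lines_per_species", "reps_per_line")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      abort(sprintf("`%s` must be a positive integer.", nm))
    }
  }
  if (cfg$mean_t0_depth <= 0) abort("`mean_t0_depth` must be positive.")
  if (cfg$dispersion_alpha <= 0) abort("`dispersion_alpha` must be positive.")
  fracs <- c("frac_shared_essential", "frac_species_specific",
             "frac_mismatch_in_B")
  for (nm in fracs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  if (cfg$frac_shared_essential + cfg$frac_species_specific > 1) {
    abort("`frac_shared_essential` + `frac_species_specific` must be <= 1.")
  }
  rng <- cfg$guide_activity_range
  if (length(rng) != 2L || any(rng < 0) || any(rng > 1) || rng[1] > rng[2]) {
    abort("`guide_activity_range` must be an increasing pair in [0, 1].")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulator configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read YAML configs.")
  }
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

random_spacers <- function(n, length = 20L, avoid = character(),
                           max_tries = 100L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      dup <- c(out, avoid)[duplicated(c(out, avoid))][1]
      abort(sprintf(
        "Could not draw %d distinct spacers after %d rounds (collision near '%s').",
        n, max_tries, dup %||% "?"
      ))
    }
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
    cand <- setdiff(unique(cand), c(out, avoid))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Simulate a guide library with ground truth
#'
#' Draws `n_genes * guides_per_gene` targeting sgRNAs with random distinct
#' 20-nt spacers plus `n_nt_guides` non-targeting controls, and assigns each
#' gene a ground-truth class and per-species fitness effect gamma (log2 change
#' in relative abundance over the screen). Guide knockdown activities are
#' uniform in `guide_activity_range`; a `frac_mismatch_in_B` fraction of
#' targeting guides is marked to receive 1-3 substitutions in the species-B
#' genome. Output is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `library` (tibble: guide_id, spacer, gene,
#'   tss_offset, is_nt, on_target_score, specificity_score) and `truth`
#'   (list of `genes` and `guides` tibbles).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_t <- config$n_genes * config$guides_per_gene
  genes <- sprintf("G%04d", seq_len(config$n_genes))

  spacers <- random_spacers(n_t + config$n_nt_guides)
  lib <- tibble(
    guide_id = c(
      paste0(rep(genes, each = config$guides_per_gene), "_g",
             rep(seq_len(config$guides_per_gene), config$n_genes)),
      sprintf("NT_%04d", seq_len(config$n_nt_guides))
    ),
    spacer = spacers,
    gene = c(rep(genes, each = config$guides_per_gene),
             rep(NA_character_, config$n_nt_guides)),
    tss_offset = c(sample(-50:300, n_t, replace = TRUE),
                   rep(NA_integer_, config$n_nt_guides)),
    is_nt = rep(c(FALSE, TRUE), c(n_t, config$n_nt_guides)),
    on_target_score = round(c(runif(n_t, 0.2, 1),
                              rep(NA_real_, config$n_nt_guides)), 4),
    specificity_score = round(c(runif(n_t, 0.05, 1),
                                rep(NA_real_, config$n_nt_guides)), 4)
  )

  n_shared <- round(config$frac_shared_essential * config$n_genes)
  n_spec <- round(config$frac_species_specific * config$n_genes)
  idx <- sample(config$n_genes)
  shared_idx <- idx[seq_len(n_shared)]
  spec_idx <- idx[n_shared + seq_len(n_spec)]
  spec_a <- spec_idx[seq_len(floor(n_spec / 2))]
  spec_b <- setdiff(spec_idx, spec_a)

  gamma_a <- gamma_b <- rep(0, config$n_genes)
  class <- rep("neutral", config$n_genes)
  eff <- function(n) rnorm(n, config$effect_lfc_mean, config$effect_lfc_sd)
  if (length(shared_idx)) {
    g <- eff(length(shared_idx))
    gamma_a[shared_idx] <- g
    gamma_b[shared_idx] <- g
    class[shared_idx] <- if_else(g < 0, "shared-essential", "suppressor")
  }
  if (length(spec_a)) {
    gamma_a[spec_a] <- eff(length(spec_a))
    class[spec_a] <- "speciesA-specific"
  }
  if (length(spec_b)) {
    gamma_b[spec_b] <- eff(length(spec_b))
    class[spec_b] <- "speciesB-specific"
  }
  truth_genes <- tibble(gene = genes, class = class,
                        gamma_a = gamma_a, gamma_b = gamma_b)

  targeting <- lib$guide_id[!lib$is_nt]
  mm <- rbinom(length(targeting), 1L, config$frac_mismatch_in_B) *
    sample(1:3, length(targeting), replace = TRUE)
  truth_guides <- tibble(
    guide_id = lib$guide_id,
    activity = c(runif(length(targeting), config$guide_activity_range[1],
                       config$guide_activity_range[2]),
                 rep(0, config$n_nt_guides)),
    mismatch_b = c(mm, rep(0L, config$n_nt_guides))
  )

  list(library = lib,
       truth = list(genes = truth_genes, guides = truth_guides))
}

mutate_spacer <- function(spacer, n_sub) {
  bases <- strsplit(spacer, "", fixed = TRUE)[[1]]
  pos <- sample(length(bases), n_sub)
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
  }
  paste(bases, collapse = "")
}

embed_guides <- function(spacers, genome_length, seed_chars) {
  n <- length(spacers)
  slot <- 23L + 7L  # protospacer + PAM + spacing
  if (genome_length < n * slot + 10L) {
    abort(sprintf(
      "Genome of length %d too short to embed %d guides without overlap (need >= %d).",
      genome_length, n, n * slot + 10L
    ))
  }
  bg <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  starts0 <- 5L + (seq_len(n) - 1L) * slot  # 0-based starts
  for (i in seq_len(n)) {
    s0 <- starts0[i]
    pam <- c(sample(c("A", "C", "G", "T"), 1), "G", "G")
    bg[(s0 + 1L):(s0 + 23L)] <- c(strsplit(spacers[i], "")[[1]], pam)
  }
  list(seq = paste(bg, collapse = ""), starts0 = starts0)
}

#' Simulate toy genomes embedding the library's target sites
#'
#' Builds one single-contig genome per species. Every targeting spacer is
#' embedded exactly once, followed by an NGG PAM, on the forward strand. In
#' the species-B genome, guides marked in the ground truth receive 1-3
#' substitutions inside the embedded protospacer, so they no longer match
#' perfectly. Non-targeting spacers are verified absent from both genomes (in
#' either orientation) and re-drawn if found; the possibly revised library is
#' returned alongside the sequences.
#'
#' @param library,truth As produced by [simulate_library()].
#' @param config The [sim_config()] used for the library.
#' @param genome_length Length of each contig; defaults to a size that fits
#'   all guides with spacing.
#' @return List with `genome_a`, `genome_b` ([Biostrings::DNAStringSet-class]),
#'   `library` (possibly with re-drawn NT spacers), and `sites` (tibble of
#'   embedded 0-based positions per genome).
#' @export
simulate_genomes <- function(library, truth, config, genome_length = NULL) {
  set.seed(config$seed + 1L)
  targ <- library[!library$is_nt, ]
  n <- nrow(targ)
  genome_length <- genome_length %||% (n * 30L + 200L)

  emb_a <- embed_guides(targ$spacer, genome_length)
  mm_n <- truth$guides$mismatch_b[match(targ$guide_id, truth$guides$guide_id)]
  spacer_b <- targ$spacer
  for (i in which(mm_n > 0)) {
    spacer_b[i] <- mutate_spacer(spacer_b[i], mm_n[i])
  }
  emb_b <- embed_guides(spacer_b, genome_length)

  genome_a <- Biostrings::DNAStringSet(setNames(emb_a$seq, "chrA"))
  genome_b <- Biostrings::DNAStringSet(setNames(emb_b$seq, "chrB"))

  # NT spacers must have no target in either genome, either orientation
  nt_idx <- which(library$is_nt)
  for (i in nt_idx) {
    tries <- 0L
    repeat {
      sp <- Biostrings::DNAString(library$spacer[i])
      hits <- sum(
        Biostrings::vcountPattern(sp, genome_a),
        Biostrings::vcountPattern(Biostrings::reverseComplement(sp), genome_a),
        Biostrings::vcountPattern(sp, genome_b),
        Biostrings::vcountPattern(Biostrings::reverseComplement(sp), genome_b)
      )
      if (hits == 0L) break
      tries <- tries + 1L
      if (tries > 50L) abort("Could not draw a genome-absent NT spacer.")
      library$spacer[i] <- random_spacers(1L, avoid = library$spacer)
    }
  }

  sites <- tibble(
    guide_id = rep(targ$guide_id, 2),
    genome = rep(c("A", "B"), each = n),
    contig = rep(c("chrA", "chrB"), each = n),
    start = c(emb_a$starts0, emb_b$starts0),
    strand = "+",
    mismatches = c(rep(0L, n), mm_n)
  )
  list(genome_a = genome_a, genome_b = genome_b,
       library = library, sites = sites)
}

#' Simulate screen count matrices
#'
#' Generates a guides-by-samples table of negative-binomial counts for the
#' full design (2 species x `lines_per_species` individuals x `reps_per_line`
#' technical replicates x timepoints t0/tfinal). t0 expected abundance is
#' `mean_t0_depth` times a lognormal library weight; at tfinal the relative
#' abundance of guide i in species s is multiplied by `2^(gamma[g,s] *
#' activity[i])` and renormalized so each sample keeps the same expected
#' sequencing depth. Counts are drawn with variance `mu + alpha * mu^2`.
#' Non-targeting guides use gamma = 0 and so are exchangeable with guides
#' targeting neutral genes. Deterministic given `config$seed`.
#'
#' @inheritParams simulate_genomes
#' @return List with `counts` (tibble, first column `guide_id` then one column
#'   per sample) and `design` (tibble: sample_id, species, individual,
#'   replicate, timepoint).
#' @export
simulate_counts <- function(library, truth, config) {
  set.seed(config$seed + 2L)
  n_guides <- nrow(library)
  size <- 1 / config$dispersion_alpha

  w <- rlnorm(n_guides, 0, 0.5)
  w <- w / mean(w)

  gt <- truth$genes
  gidx <- match(library$gene, gt$gene)
  act <- truth$guides$activity[match(library$guide_id,
                                     truth$guides$guide_id)]
  gamma <- cbind(
    A = if_else(library$is_nt, 0, gt$gamma_a[gidx] * act),
    B = if_else(library$is_nt, 0, gt$gamma_b[gidx] * act)
  )

  design <- tidyr::expand_grid(
    species = c("A", "B"),
    individual = sprintf("i%d", seq_len(config$lines_per_species)),
    replicate = sprintf("r%d", seq_len(config$reps_per_line)),
    timepoint = c("t0", "tfinal")
  )
  design <- mutate(design,
    sample_id = paste(.data$species, .data$individual, .data$replicate,
                      .data$timepoint, sep = "_"),
    .before = 1
  )

  depth_total <- config$mean_t0_depth * n_guides
  cols <- lapply(seq_len(nrow(design)), function(j) {
    sp <- design$species[j]
    if (design$timepoint[j] == "t0") {
      mu <- config$mean_t0_depth * w
    } else {
      rel <- w * 2^gamma[, sp]
      mu <- depth_total * rel / sum(rel)
    }
    rnbinom(n_guides, mu = mu, size = size)
  })
  counts <- bind_cols(
    tibble(guide_id = library$guide_id),
    setNames(as_tibble(cols, .name_repair = "minimal"), design$sample_id)
  )
  list(counts = counts, design = design)
}

#' Simulate a complete two-species screen
#'
#' Convenience wrapper running [simulate_library()], [simulate_genomes()]
#' and [simulate_counts()] from one configuration.
#'
#' @param config A [sim_config()].
#' @param genomes If `FALSE`, skip genome construction (counts-only studies).
#' @return List with `library`, `truth`, `counts`, `design` and (if requested)
#'   `genome_a`, `genome_b`, `sites`.
#' @export
simulate_screen <- function(config, genomes = TRUE) {
  sim <- simulate_library(config)
  out <- list(library = sim$library, truth = sim$truth, config = config)
  if (genomes) {
    g <- simulate_genomes(sim$library, sim$truth, config)
    out$library <- g$library
    out$genome_a <- g$genome_a
    out$genome_b <- g$genome_b
    out$sites <- g$sites
  }
  cc <- simulate_counts(out$library, sim$truth, config)
  out$counts <- cc$counts
  out$design <- cc$design
  out
}
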