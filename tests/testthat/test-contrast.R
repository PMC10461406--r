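test_that("BH adjustment matches a reference step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))^2
    adj <- adjust_pvalues(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj >= 0 & adj <= 1))
  }
})

make_contrast_design <- function(lines = 2, reps = 2) {
  design <- tidyr::expand_grid(
    species = c("A", "B"), individual = paste0("i", seq_len(lines)),
    replicate = paste0("r", seq_len(reps)), timepoint = c("t0", "tfinal")
  )
  design$sample_id <- with(design, paste(species, individual, replicate,
                                         timepoint, sep = "_"))
  design[, c("sample_id", "species", "individual", "replicate", "timepoint")]
}

test_that("the species-by-time model recovers deterministic contrasts", {
  design <- make_contrast_design()
  lib <- tibble::tibble(
    guide_id = c("flat", "b_halves", "nt1"),
    gene = c("G1", "G2", NA), is_nt = c(FALSE, FALSE, TRUE),
    spacer = "ACGT"
  )
  base <- 400
  counts <- tibble::tibble(guide_id = lib$guide_id)
  for (j in seq_len(nrow(design))) {
    val <- c(base, base, base)
    if (design$timepoint[j] == "tfinal" && design$species[j] == "B") {
      val[2] <- base / 2  # guide 2 halves in species B only
    }
    counts[[design$sample_id[j]]] <- val
  }
  res <- fit_sgrna_contrast(counts, design, lib, alpha = 0.05)
  flat <- res[res$guide_id == "flat", ]
  expect_equal(flat$dlfc, 0, tolerance = 1e-6)
  expect_gt(flat$p_diff, 0.99)
  halves <- res[res$guide_id == "b_halves", ]
  expect_equal(halves$dlfc, -1, tolerance = 1e-3)
  expect_equal(halves$lfc_a, 0, tolerance = 1e-3)
  expect_equal(halves$lfc_b, -1, tolerance = 1e-3)
  expect_lt(halves$p_diff, 0.05)
})

test_that("the contrast model requires a valid paired two-species design", {
  design <- make_contrast_design(lines = 1)
  lib <- tibble::tibble(guide_id = "g", gene = "G", is_nt = FALSE)
  counts <- tibble::tibble(guide_id = "g")
  for (s in design$sample_id) counts[[s]] <- 10
  expect_error(fit_sgrna_contrast(counts, design, lib, alpha = 0.05),
               ">= 2 individuals")
})

test_that("species-different sgRNA flags follow the FDR and effect rule", {
  cfg <- sim_config(n_genes = 80, n_nt_guides = 200, lines_per_species = 2,
                    reps_per_line = 2, frac_shared_essential = 0.1,
                    frac_species_specific = 0.2,
                    guide_activity_range = c(1, 1), seed = 12)
  sim <- simulate_screen(cfg, genomes = FALSE)
  res <- fit_sgrna_contrast(sim$counts, sim$design, sim$library)
  expect_true(all(res$padj_diff >= res$p_diff - 1e-12))
  flagged <- res[res$species_different, ]
  expect_true(all(flagged$padj_diff < 0.01 & abs(flagged$dlfc) >= 0.5))
  # flagged guides overwhelmingly target truly species-specific genes
  truth <- sim$truth$genes
  cls <- truth$class[match(flagged$gene, truth$gene)]
  expect_gt(mean(cls %in% c("speciesA-specific", "speciesB-specific")), 0.9)
  # NT guides are essentially never flagged
  expect_lt(mean(res$species_different[res$is_nt]), 0.02)
})

test_that("alpha-RRA rho equals the closed-form Beta order-statistic", {
  # gene with 4 sgRNAs at known percentiles among 1000 sgRNAs
  target_pct <- c(0.001, 0.002, 0.003, 0.9)
  n <- 1000
  padj <- rep(0, n)
  ranks_wanted <- round(target_pct * n)
  padj <- seq(0.001, 1, length.out = n)  # rank i / n = percentile
  gene <- rep(NA_character_, n)
  gene[ranks_wanted] <- "G1"
  res <- alpha_rra(padj, gene, alpha = 0.05, n_perm = 100, seed = 1)
  r <- ranks_wanted / n
  below <- r[r <= 0.05]
  oracle_rho <- min(pbeta(below, seq_along(below),
                          4 - seq_along(below) + 1))
  expect_equal(res$rho, oracle_rho, tolerance = 1e-10)
  expect_equal(res$n_pass_alpha, 3L)

  # gene with every sgRNA above alpha gets p = 1
  gene2 <- rep(NA_character_, n)
  gene2[c(900, 950)] <- "G2"
  res2 <- alpha_rra(padj, gene2, alpha = 0.05, n_perm = 100, seed = 1)
  expect_equal(res2$p, 1)
})

test_that("alpha-RRA derives alpha from the adjusted-p fraction and is null-uniform", {
  set.seed(8)
  n_genes <- 1000
  padj <- runif(n_genes * 5)
  padj[1:200] <- padj[1:200] / 100  # some signal defines alpha
  gene <- rep(sprintf("g%04d", seq_len(n_genes)), each = 5)
  # permuted gene labels: no gene structure, p should be uniform
  gene_perm <- sample(gene)
  res <- alpha_rra(padj, gene_perm, n_perm = 2000, seed = 5)
  expect_equal(attr(res, "alpha"), mean(padj < 0.01), tolerance = 1e-12)
  # genes with no alpha-passing guide form an atom at p = 1 by design, so
  # strict uniformity holds in the regime where every gene passes...
  res_u <- alpha_rra(padj, gene_perm, alpha = 0.8, n_perm = 4000, seed = 5)
  ks <- suppressWarnings(ks.test(res_u$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # ...while at the derived alpha the p-values remain valid (super-uniform
  # up to Monte-Carlo error)
  for (t in c(0.01, 0.05, 0.1, 0.2)) {
    expect_lte(mean(res$p <= t), t + 3 * sqrt(t * (1 - t) / n_genes) + 0.01)
  }
  # monotonicity: inflating every sgRNA p can only weaken gene significance
  worse <- pmin(1, padj * 2)
  res_w <- alpha_rra(worse, gene_perm, alpha = attr(res, "alpha"),
                     n_perm = 2000, seed = 5)
  expect_true(all(res_w$rho >= res$rho - 1e-12))

  expect_warning(r0 <- alpha_rra(rep(0.5, 10), rep("g", 10), alpha = 0),
                 "threshold is 0")
  expect_equal(r0$p, 1)
})

# Builds an sgrna_contrast-shaped table directly, to drive the caller
# through controlled branches. Each gene supplies its five guides' raw
# p-values per term explicitly.
fake_contrast <- function(genes) {
  rows <- purrr::pmap(genes, function(gene, p_a, p_b, p_diff, lfc_a, lfc_b,
                                      dlfc, ...) {
    n <- 5
    tibble::tibble(
      guide_id = paste0(gene, "_g", 1:n), gene = gene, is_nt = FALSE,
      lfc_a = lfc_a + rnorm(n, 0, 0.01),
      lfc_b = lfc_b + rnorm(n, 0, 0.01),
      dlfc = dlfc + rnorm(n, 0, 0.01),
      p_a = p_a, p_b = p_b, p_diff = p_diff,
      converged = TRUE
    )
  })
  nt <- tibble::tibble(
    guide_id = paste0("nt", 1:100), gene = NA_character_, is_nt = TRUE,
    lfc_a = rnorm(100, 0, 0.05), lfc_b = rnorm(100, 0, 0.05),
    dlfc = rnorm(100, 0, 0.05),
    p_a = runif(100), p_b = runif(100), p_diff = runif(100),
    converged = TRUE
  )
  out <- dplyr::bind_rows(c(rows, list(nt)))
  out$padj_a <- adjust_pvalues(out$p_a)
  out$padj_b <- adjust_pvalues(out$p_b)
  out$padj_diff <- adjust_pvalues(out$p_diff)
  out$species_different <- out$padj_diff < 0.01 & abs(out$dlfc) >= 0.5
  class(out) <- c("sgrna_contrast", class(out))
  out
}

test_that("the three-condition caller enforces each printed condition", {
  set.seed(15)
  strong <- list(rep(1e-8, 5))
  weak <- list(runif(5, 0.3, 1))
  two_sig <- list(c(1e-8, 1e-8, 0.5, 0.7, 0.9))
  # one guide strong enough to pass alpha, but alone: the gene's FDR stays
  # high, which makes it define the shared-effect exclusion threshold
  marginal <- list(c(1e-4, 0.6, 0.7, 0.8, 0.9))
  genes <- tibble::tibble(
    gene = c("called_a", "too_few_pass", "small_diff", "shared", "null",
             "marginal_a", "marginal_b"),
    p_a = c(strong, strong, weak, strong, weak, marginal, weak),
    p_b = c(weak, weak, weak, strong, weak, weak, marginal),
    p_diff = c(strong, two_sig, strong, strong, weak, weak, weak),
    lfc_a = c(-1, -1, -0.3, -2, 0, -0.3, 0),
    lfc_b = c(0, 0, 0.3, -2, 0, 0, -0.3),
    dlfc = c(0.9, 0.9, 0.4, 0.1, 0, 0, 0)
  )
  ctr <- fake_contrast(genes)
  calls <- call_species_specific(ctr, n_perm = 2000, seed = 3)

  expect_equal(calls$call[calls$gene == "called_a"], "speciesA-specific")
  # fails the >= 3 alpha-passing guides condition
  expect_equal(calls$call[calls$gene == "too_few_pass"], "none")
  expect_lt(calls$n_pass_diff[calls$gene == "too_few_pass"], 3)
  # fails the gene LFC difference condition
  expect_equal(calls$call[calls$gene == "small_diff"], "none")
  # strong in both species terms: removed by the shared-effect exclusion
  expect_true(calls$excluded_shared[calls$gene == "shared"])
  expect_true(calls$call[calls$gene == "shared"] %in% c("shared", "none"))
  expect_equal(calls$call[calls$gene == "null"], "none")

  # output invariant to gene and guide order
  ctr2 <- ctr[sample(nrow(ctr)), ]
  class(ctr2) <- class(ctr)
  calls2 <- call_species_specific(ctr2, n_perm = 2000, seed = 3)
  expect_equal(dplyr::arrange(tibble::as_tibble(calls), gene)$call,
               dplyr::arrange(tibble::as_tibble(calls2), gene)$call)
})

test_that("p53-dependence flags come from a per-gene Welch t-test", {
  scores <- tibble::tibble(
    gene = rep(c("equal", "dependent", "constant"), each = 6),
    line = rep(paste0("L", 1:6), 3),
    score = c(
      c(-1, -1, -1, -1, -1, -1),
      c(-3, -3.01, 0.01, -0.01, 0.005, 0),
      rep(0, 6)
    )
  )
  responsive <- tibble::tibble(line = paste0("L", 1:6),
                               responsive = c(FALSE, FALSE, TRUE, TRUE,
                                              TRUE, TRUE))
  res <- flag_p53_dependence(scores, responsive)
  expect_equal(res$p[res$gene == "equal"], 1)
  expect_lt(res$p[res$gene == "dependent"], 0.01)
  expect_true(res$flag[res$gene == "dependent"])
  expect_equal(res$p[res$gene == "constant"], 1)
  expect_true(res$degenerate[res$gene == "constant"])

  # oracle: hand-computed Welch statistic for the dependent gene
  x <- scores$score[scores$gene == "dependent"][1:2]
  y <- scores$score[scores$gene == "dependent"][3:6]
  tstat <- (mean(x) - mean(y)) / sqrt(var(x) / 2 + var(y) / 4)
  expect_equal(res$statistic[res$gene == "dependent"], tstat,
               tolerance = 1e-8)

  small <- responsive
  small$responsive <- c(FALSE, rep(TRUE, 5))
  expect_error(flag_p53_dependence(scores, small), ">= 2 lines")
})

test_that("variance partitioning attributes pure shifts correctly", {
  design <- make_contrast_design(lines = 3, reps = 2)
  n <- nrow(design)
  # pure species shift, almost no noise
  y <- ifelse(design$species == "A", 1, -1) + rnorm(n, 0, 1e-3)
  mat <- matrix(rep(y, 5), nrow = 5, byrow = TRUE,
                dimnames = list(paste0("g", 1:5), design$sample_id))
  vp <- variance_partition(mat, design)
  expect_true(all(vp$per_sgrna$species > 0.95))

  # permuted species labels carry no species variance on average
  set.seed(30)
  G <- 200
  Y <- t(vapply(seq_len(G), function(g) rnorm(n), numeric(n)))
  rownames(Y) <- paste0("g", 1:G); colnames(Y) <- design$sample_id
  vp0 <- variance_partition(Y, design)
  expect_lt(mean(vp0$per_sgrna$species), 0.1)

  # aliased design errors
  one_line <- make_contrast_design(lines = 1, reps = 2)
  m1 <- matrix(rnorm(2 * nrow(one_line)), nrow = 2,
               dimnames = list(c("a", "b"), one_line$sample_id))
  expect_error(variance_partition(m1, one_line), "aliased")
})

test_that("variance components are recovered from a simulated mixed model", {
  design <- make_contrast_design(lines = 3, reps = 2)
  n <- nrow(design)
  set.seed(31)
  G <- 500
  Y <- t(vapply(seq_len(G), function(g) {
    a <- stats::setNames(rnorm(2, 0, 1), c("A", "B"))
    b <- stats::setNames(rnorm(6, 0, 1),
                         unique(paste(design$species, design$individual,
                                      sep = ":")))
    a[design$species] +
      b[paste(design$species, design$individual, sep = ":")] +
      rnorm(n, 0, sqrt(2))
  }, numeric(n)))
  rownames(Y) <- paste0("g", 1:G); colnames(Y) <- design$sample_id
  vp <- variance_partition(Y, design)
  fr <- colMeans(as.matrix(vp$per_sgrna[-1]))
  expect_lt(abs(fr[["species"]] - 0.25), 0.1)
  expect_lt(abs(fr[["individual"]] - 0.25), 0.1)
  expect_lt(abs(fr[["residual"]] - 0.50), 0.1)
})
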