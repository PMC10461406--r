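# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Naive O(n*m) protospacer scanner: every position, both strands, Hamming
# distance over the protospacer, PAM NGG checked verbatim.
brute_force_sites <- function(spacer, seq_chr, max_mismatch = 0L) {
  L <- nchar(spacer)
  n <- nchar(seq_chr)
  sp <- strsplit(spacer, "")[[1]]
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hits <- list()
  for (i in seq_len(n - L - 2L)) {  # 1-based start, PAM needs 3 more bases
    win <- substring(seq_chr, i, i + L - 1L)
    pam <- substring(seq_chr, i + L, i + L + 2L)
    mm <- sum(strsplit(win, "")[[1]] != sp)
    if (mm <= max_mismatch && substring(pam, 2, 3) == "GG") {
      hits[[length(hits) + 1L]] <-
        data.frame(start = i - 1L, strand = "+", mismatches = mm)
    }
  }
  rc <- revcomp(spacer)
  rcv <- strsplit(rc, "")[[1]]
  for (i in 4:(n - L + 1L)) {  # PAM (CCN) occupies i-3 .. i-1
    win <- substring(seq_chr, i, i + L - 1L)
    pam <- substring(seq_chr, i - 3L, i - 1L)
    mm <- sum(strsplit(win, "")[[1]] != rcv)
    if (mm <= max_mismatch && substring(pam, 1, 2) == "CC") {
      hits[[length(hits) + 1L]] <-
        data.frame(start = i - 1L, strand = "-", mismatches = mm)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  }
  out[order(out$start), , drop = FALSE]
}

# Reference BH step-up, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small complete screen for reuse in tests.
tiny_screen <- function(seed = 42, ...) {
  cfg <- sim_config(n_genes = 30, n_nt_guides = 60, lines_per_species = 2,
                    reps_per_line = 2, seed = seed, ...)
  simulate_screen(cfg, genomes = FALSE)
}

write_fastq <- function(path, reads) {
  lines <- unlist(lapply(seq_along(reads), function(i) {
    c(paste0("@read", i), reads[i], "+",
      strrep("I", nchar(reads[i])))
  }))
  writeLines(lines, path)
  path
}

# A 20-gene fixture exercising every candidate-selection branch. Species A
# plays the human role, B the chimpanzee role; two lines per species.
# Default FDRs (0.2 everywhere) qualify for no set and no per-line rule.
candidate_fixture <- function() {
  g <- function(gene, a_avg, b_avg, fa1 = 0.2, fa2 = 0.2, fb1 = 0.2,
                fb2 = 0.2, da1 = 0, da2 = 0, db1 = 0, db2 = 0) {
    tibble::tibble(gene = gene, a_avg = a_avg, b_avg = b_avg,
                   fdr_a1 = fa1, fdr_a2 = fa2, fdr_b1 = fb1, fdr_b2 = fb2,
                   ds_a1 = da1, ds_a2 = da2, ds_b1 = db1, ds_b2 = db2)
  }
  dplyr::bind_rows(
    g("aes1", -3, 0, fa1 = 0.01, fa2 = 0.01),           # A essential set 1
    g("aes1_shared", -3, -3, fa1 = 0.01, fa2 = 0.01),   # shared -> no label
    g("aes1_weakfdr", -3, 0, fa1 = 0.01, fa2 = 0.2),    # FDR gate fails
    g("aen1", 2, 0, fa1 = 0.01, fa2 = 0.01),            # A enriched set 1
    g("bes1", 0, -3, fb1 = 0.01, fb2 = 0.01),           # B essential set 1
    g("ben1", 0, 3, fb1 = 0.01, fb2 = 0.01),            # B enriched set 1
    g("bes_aen", 1, -1, fa1 = 0.01, fa2 = 0.01,
      fb1 = 0.01, fb2 = 0.01),                          # B ess + A enr
    g("aes_ben", -1, 1, fa1 = 0.01, fa2 = 0.01,
      fb1 = 0.01, fb2 = 0.01),                          # A ess + B enr
    g("both_a_more", -3, -1.2, fa1 = 0.01, fa2 = 0.01,
      fb1 = 0.01, fb2 = 0.01),                          # both, A stronger
    g("both_b_more", -1.1, -4, fa1 = 0.01, fa2 = 0.01,
      fb1 = 0.01, fb2 = 0.01),                          # both, B stronger
    g("rule_a", 0, 0, fa1 = 0.05, fa2 = 0.08,
      fb1 = 0.4, fb2 = 0.5),                            # 10/25 rule, A
    g("rule_b", 0, 0, fa1 = 0.4, fa2 = 0.5,
      fb1 = 0.05, fb2 = 0.08),                          # 10/25 rule, B
    g("rule_a_fail", 0, 0, fa1 = 0.05, fa2 = 0.12,
      fb1 = 0.4, fb2 = 0.5),                            # line 2 misses 10%
    g("aes2", 0, 0, da1 = 3, da2 = 3, db1 = 0, db2 = 0),   # A ess set 2
    g("aen2", 0, 0, da1 = -2, da2 = -3, db1 = -1, db2 = 0),# A enr set 2
    g("bes2_mirror", 0, 0, da1 = 3, da2 = 2,
      db1 = 5, db2 = 5),                # mirror case; set infeasible as printed
    g("ben2", 0, 0, da1 = 13, da2 = -1,
      db1 = -3, db2 = -3),                              # B enr set 2
    g("aes2_onesided", 0, 0, da1 = 5, da2 = 1,
      db1 = 0, db2 = 0),                                # per-line gate fails
    g("neutral1", 0.1, -0.1),
    g("neutral2", -0.5, 0.5)
  )
}

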