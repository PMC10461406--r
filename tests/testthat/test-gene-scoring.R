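test_that("top-k gene scores match the arithmetic oracle", {
  toy <- tibble::tibble(gene = "g", guide_id = paste0("s", 1:5),
                        lfc = c(-4, -3, -1, 0, 0))
  expect_equal(gene_score(toy, mode = "top_k", k = 3)$score, (-4 - 3 - 1) / 3)
  flat <- tibble::tibble(gene = "g", guide_id = paste0("s", 1:4),
                         lfc = c(-2, -2, -2, -2))
  expect_equal(gene_score(flat, mode = "top_k", k = 4)$score, -2)

  # permutation invariance and equality with a brute-force sort oracle
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    df <- tibble::tibble(gene = "g", guide_id = sprintf("s%02d", 1:n),
                         lfc = round(rnorm(n), 3))
    k <- sample(2:4, 1)
    got <- suppressWarnings(gene_score(df, mode = "top_k", k = k)$score)
    shuffled <- df[sample(n), ]
    got2 <- suppressWarnings(gene_score(shuffled, mode = "top_k",
                                        k = k)$score)
    oracle <- mean(df$lfc[order(-abs(df$lfc),
                                df$guide_id)][seq_len(min(k, n))])
    expect_equal(got, oracle)
    expect_identical(got, got2)
  }

  short <- tibble::tibble(gene = "g", guide_id = c("a", "b"), lfc = c(-1, -3))
  expect_warning(sc <- gene_score(short, mode = "top_k", k = 4), "fewer than")
  expect_equal(sc$score, -2)
})

test_that("retained-mean scores use only filtered significant guides", {
  df <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 3),
    guide_id = paste0("s", 1:6),
    lfc = c(-2, -4, 5, 1, 2, 3),
    retained = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  sc <- gene_score(df, mode = "retained_mean")
  expect_equal(sc$score[sc$gene == "g1"], -3)
  expect_equal(sc$n_guides[sc$gene == "g1"], 2)
  expect_true(is.na(sc$score[sc$gene == "g2"]))
})

test_that("bootstrap p-values converge to the enumeration value at m = 1", {
  # NT pool {-1, 0, 1}, observed score -1, m = 1:
  # P(|null| >= 1) = 2/3, so p -> 2/3
  scores <- tibble::tibble(gene = "g", score = -1, n_guides = 1L)
  nt <- rep(c(-1, 0, 1), 400)
  res <- suppressWarnings(
    bootstrap_gene_fdr(scores, nt, n_boot = 20000, seed = 1))
  expect_equal(res$boot_p, 2 / 3, tolerance = 0.02)

  # a zero score on a symmetric pool is unremarkable
  sym <- tibble::tibble(gene = "g", score = 0, n_guides = 3L)
  res0 <- bootstrap_gene_fdr(sym, rnorm(500), n_boot = 2000, seed = 2)
  expect_gt(res0$boot_p, 0.9)

  # genes without retained guides are excluded
  none <- tibble::tibble(gene = c("a", "b"), score = c(-1, NA),
                         n_guides = c(0L, 2L))
  resn <- bootstrap_gene_fdr(none, rnorm(100), n_boot = 100, seed = 3)
  expect_equal(nrow(resn), 0)
})

test_that("bootstrap p-values are uniform under the null", {
  set.seed(9)
  nt <- rnorm(2000, 0, 0.4)
  m <- sample(1:5, 2000, replace = TRUE)
  obs <- vapply(m, function(k) mean(sample(nt, k)), numeric(1))
  scores <- tibble::tibble(gene = paste0("g", 1:2000), score = obs,
                           n_guides = m)
  res <- bootstrap_gene_fdr(scores, nt, n_boot = 2000, seed = 4)
  ks <- suppressWarnings(ks.test(res$boot_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # BH control: FDR-called genes at q = 0.1 are rare under the null
  expect_lt(mean(res$boot_fdr < 0.1), 0.02)
})

test_that("direction scores count depleted minus enriched guides", {
  stats <- tibble::tibble(
    guide_id = paste0("s", 1:10),
    gene = rep(c("g1", "g2"), each = 5),
    species = "A",
    individual = rep(c("i1", "i2"), 5),
    call = factor(c("depleted", "depleted", "depleted", "depleted",
                    "enriched", rep("ns", 5)),
                  levels = c("depleted", "enriched", "ns"))
  )
  ds <- direction_scores(stats)
  g1 <- ds$per_screen[ds$per_screen$gene == "g1", ]
  expect_equal(sum(g1$direction_score), 3)
  expect_equal(ds$per_species$direction_score[
    ds$per_species$gene == "g2"], 0)

  # species score is the sum over that species' lines
  two_lines <- tibble::tibble(
    guide_id = paste0("s", 1:10), gene = "g", species = "A",
    individual = rep(c("i1", "i2"), each = 5),
    call = factor(c(rep("depleted", 3), rep("ns", 2),
                    rep("depleted", 2), rep("ns", 3)),
                  levels = c("depleted", "enriched", "ns"))
  )
  ds2 <- direction_scores(two_lines)
  expect_equal(ds2$per_screen$direction_score, c(3, 2))
  expect_equal(ds2$per_species$direction_score, 5)
})

test_that("essentiality classes and intersection sets follow the dual rule", {
  scores <- tidyr::expand_grid(gene = sprintf("g%02d", 1:10),
                               screen = c("s1", "s2", "s3"))
  # deterministic pattern: genes 1-3 strongly depleted everywhere,
  # gene 4 depleted in s1+s2 only, gene 5 intermediate, rest neutral
  base <- c(-5, -4.5, -4, -2.5, -1.5, 0, 0.1, 0.2, 0.3, 0.4)
  scores$score <- base[as.integer(sub("g", "", scores$gene))]
  scores$score[scores$gene == "g04" & scores$screen == "s3"] <- 0
  cls <- classify_essentiality(scores, top_n = 4)
  wide <- tidyr::pivot_wider(cls$classes, names_from = "screen",
                             values_from = "class")
  expect_equal(wide$s1[wide$gene == "g01"], "essential")
  expect_equal(wide$s3[wide$gene == "g04"], "nonessential")
  expect_equal(wide$s1[wide$gene == "g05"], "intermediate")
  expect_equal(wide$s1[wide$gene == "g06"], "nonessential")

  # essential and nonessential never overlap within a screen
  tab <- table(cls$classes$gene, cls$classes$class)
  expect_true(all(rowSums(tab > 0) <= 3))

  inter <- cls$intersections
  expect_true(all(c("g01", "g02", "g03") %in%
                    inter$gene[inter$set == "s1+s2+s3"]))
  expect_equal(inter$gene[inter$set == "s1+s2"], "g04")
  # g05 is intermediate somewhere, so it joins no set
  expect_false("g05" %in% inter$gene)

  # score thresholds gate the rank rule
  shallow <- tibble::tibble(gene = c("a", "b"), screen = "s1",
                            score = c(-2.5, 0))
  cls2 <- classify_essentiality(shallow, top_n = 2)
  expect_equal(cls2$classes$class, c("essential", "nonessential"))
})

test_that("candidate selection reproduces the hand-built truth table", {
  fx <- candidate_fixture()
  res <- candidate_selection(fx)
  expected <- list(
    aes1 = "a_essential_set1",
    aen1 = "a_enriched_set1",
    bes1 = "b_essential_set1",
    ben1 = "b_enriched_set1",
    bes_aen = "b_essential_a_enriched",
    aes_ben = "a_essential_b_enriched",
    both_a_more = "both_essential_a_more",
    both_b_more = "both_essential_b_more",
    rule_a = "fdr_rule_a",
    rule_b = "fdr_rule_b",
    aes2 = "a_essential_set2",
    aen2 = "a_enriched_set2",
    ben2 = "b_enriched_set2"
  )
  for (gene in names(expected)) {
    got <- res$labels$set[res$labels$gene == gene]
    expect_true(expected[[gene]] %in% got,
                info = sprintf("%s should carry %s (got: %s)", gene,
                               expected[[gene]],
                               paste(got, collapse = ",")))
  }
  for (gene in c("aes1_shared", "aes1_weakfdr", "rule_a_fail",
                 "aes2_onesided", "neutral1", "neutral2")) {
    expect_false(gene %in% res$candidates, info = gene)
  }
  # no gene carries a set-1 label of the wrong species
  expect_false("a_essential_set1" %in%
                 res$labels$set[res$labels$gene == "bes1"])
})

test_that("the published species-B essential set-2 criterion is infeasible", {
  # As printed, the criterion demands the species-A direction-score sum to
  # exceed 4, the B-A difference to be at least 4, and |A/B| ratio at least
  # 2 on the log2 scale; no direction-score vector satisfies all three.
  grid <- tidyr::expand_grid(ds_a1 = -6:6, ds_a2 = -6:6,
                             ds_b1 = -6:6, ds_b2 = -6:6)
  grid <- dplyr::mutate(grid, gene = sprintf("g%05d", dplyr::row_number()),
                        a_avg = 0, b_avg = 0)
  res <- suppressWarnings(candidate_selection(grid))
  expect_false("b_essential_set2" %in% res$labels$set)
})

test_that("candidate selection degrades gracefully without inputs", {
  fx <- candidate_fixture()[, c("gene", "a_avg", "b_avg")]
  expect_warning(expect_warning(res <- candidate_selection(fx),
                                "FDR"), "direction-score")
  expect_equal(nrow(res$labels), 0)
})
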