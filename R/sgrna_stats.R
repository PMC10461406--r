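#' Median-of-ratios normalization
#'
#' Computes per-sample size factors as the median, over guides with positive
#' counts in every sample, of the ratio of the guide's count to its geometric
#' mean across samples (the reference pseudo-sample). Normalized counts are
#' counts divided by the sample's size factor.
#'
#' @param counts Count tibble (first column `guide_id`) or numeric matrix
#'   with guide rownames.
#' @return List with `size_factors` (tibble sample_id, size_factor) and
#'   `normalized` (tibble, same shape as `counts`).
#' @export
#' @examples
#' toy <- tibble::tibble(guide_id = c("g1", "g2", "g3"),
#'                       s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' median_ratio_normalize(toy)$size_factors
median_ratio_normalize <- function(counts) {
  mat <- counts_to_matrix(counts)
  if (ncol(mat) < 2L) abort("Normalization needs at least 2 samples.")
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) {
    abort(paste("No guide has positive counts in every sample;",
                "consider adding a pseudocount before normalizing."))
  }
  log_geo <- rowMeans(log(mat[pos, , drop = FALSE]))
  sf <- unname(apply(mat[pos, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - log_geo))
  }))
  norm <- sweep(mat, 2, sf, "/")
  list(
    size_factors = tibble(sample_id = colnames(mat), size_factor = sf),
    normalized = matrix_to_counts(norm)
  )
}

counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  mat <- as.matrix(counts[-1])
  rownames(mat) <- counts[[1]]
  mat
}

matrix_to_counts <- function(mat) {
  bind_cols(tibble(guide_id = rownames(mat)),
            as_tibble(mat, .name_repair = "minimal"))
}

#' Per-guide log2 fold-changes
#'
#' For every (species, individual, replicate) pair of t0/tfinal samples,
#' `LFC = log2((n_tfinal + eps) / (n_t0 + eps))` on normalized counts; the
#' replicate average is the arithmetic mean. The pseudocount keeps LFCs
#' finite for zero counts and is applied here only, never inside the count
#' test.
#'
#' @param normalized Normalized count tibble or matrix.
#' @param design Sample sheet tibble.
#' @param pseudocount Added to both numerator and denominator (default 0.5).
#' @return List with `per_replicate` and `per_line` (replicate-averaged)
#'   long tibbles of LFCs.
#' @export
compute_log2fc <- function(normalized, design, pseudocount = 0.5) {
  mat <- counts_to_matrix(normalized)
  units <- design |>
    distinct(.data$species, .data$individual, .data$replicate)
  per_rep <- purrr::pmap(units, function(species, individual, replicate) {
    s0 <- design$sample_id[design$species == species &
                             design$individual == individual &
                             design$replicate == replicate &
                             design$timepoint == "t0"]
    sf <- design$sample_id[design$species == species &
                             design$individual == individual &
                             design$replicate == replicate &
                             design$timepoint == "tfinal"]
    if (length(s0) != 1L || length(sf) != 1L) {
      abort(sprintf("Missing t0/tfinal pair for %s/%s/%s.",
                    species, individual, replicate))
    }
    tibble(
      guide_id = rownames(mat),
      species = species, individual = individual, replicate = replicate,
      lfc = log2((mat[, sf] + pseudocount) / (mat[, s0] + pseudocount))
    )
  }) |> bind_rows()
  per_line <- per_rep |>
    group_by(.data$guide_id, .data$species, .data$individual) |>
    summarise(lfc = mean(.data$lfc), .groups = "drop")
  list(per_replicate = per_rep, per_line = per_line)
}

#' Fit the non-targeting mean-dispersion trend
#'
#' Estimates, per screen (one species/individual), a single overdispersion
#' alpha for the quadratic trend `Var(mu) = mu + alpha * mu^2`, pooled
#' across the non-targeting guides' replicate tfinal normalized counts.
#'
#' The default `"cml"` method maximizes the conditional
#' (Dirichlet-multinomial) likelihood of each guide's replicate counts given
#' their sum, which eliminates the unknown per-guide mean — the estimator is
#' consistent even with two replicates, where naive moment regression on the
#' observed mean is biased by the shared sampling noise. `"moments"` keeps
#' that simple regression of (sample variance - mean) on mean^2 through the
#' origin. Both are floored at zero and the trend then applies to all guides.
#'
#' @param normalized Normalized count tibble or matrix.
#' @param design Sample sheet.
#' @param nt_ids Character vector of non-targeting guide ids.
#' @param method `"cml"` (conditional likelihood, default) or `"moments"`.
#' @return Object of class `nt_null_model`: list with `trend` (tibble
#'   species, individual, alpha, n_nt) and the call's settings.
#' @export
fit_nt_null <- function(normalized, design, nt_ids,
                        method = c("cml", "moments")) {
  method <- match.arg(method)
  mat <- counts_to_matrix(normalized)
  if (length(nt_ids) < 50L) {
    warn(sprintf("Only %d non-targeting guides; the dispersion trend may be unstable (>= 50 recommended).",
                 length(nt_ids)))
  }
  nt <- mat[rownames(mat) %in% nt_ids, , drop = FALSE]
  screens <- distinct(design, .data$species, .data$individual)
  trend <- purrr::pmap(screens, function(species, individual) {
    sf <- design$sample_id[design$species == species &
                             design$individual == individual &
                             design$timepoint == "tfinal"]
    if (length(sf) < 2L) {
      abort(sprintf(
        "Screen %s/%s has %d tfinal replicate(s); >= 2 needed to estimate variance.",
        species, individual, length(sf)
      ))
    }
    x <- nt[, sf, drop = FALSE]
    keep <- rowSums(x) > 0
    a <- if (method == "cml") {
      alpha_cml(x[keep, , drop = FALSE])
    } else {
      m <- rowMeans(x)
      v <- apply(x, 1, var)
      max(0, sum((v - m)[keep] * m[keep]^2) / sum(m[keep]^4))
    }
    tibble(species = species, individual = individual,
           alpha = a, n_nt = sum(keep))
  }) |> bind_rows()
  structure(list(trend = trend, n_nt = length(nt_ids), method = method),
            class = "nt_null_model")
}

# Common-dispersion estimate from replicate counts conditional on their sum
# (Dirichlet-multinomial with symmetric parameter k = 1/alpha). Accepts
# normalized (non-integer) counts as a pseudo-likelihood; with size factors
# near 1 the conditioning argument holds to good approximation.
alpha_cml <- function(x) {
  n <- rowSums(x)
  R <- ncol(x)
  nll <- function(logk) {
    k <- exp(logk)
    -sum(lgamma(R * k) - lgamma(n + R * k) +
           rowSums(lgamma(x + k) - lgamma(k)))
  }
  opt <- optimize(nll, c(log(0.5), log(1e8)))
  alpha <- exp(-opt$minimum)
  if (alpha < 2e-8) alpha <- 0  # boundary: effectively Poisson
  alpha
}

#' @export
print.nt_null_model <- function(x, ...) {
  cat("Non-targeting null model (Var = mu + alpha * mu^2)\n")
  print(x$trend)
  invisible(x)
}

#' Two-sided negative-binomial tail p-value
#'
#' Evaluates the tail probability of a negative binomial with mean `mu` and
#' variance `mu + alpha * mu^2` at the observation `x`:
#' `p = 2 * min(P(X <= x), P(X >= x), 0.5)`, with the observed point counted
#' once in each tail. Normalized counts are not integers, so both tails use
#' the continuous gamma-Poisson mixture CDF (regularized incomplete beta /
#' gamma functions), which agrees exactly with the discrete pmf at integer
#' `x`. `alpha = 0` gives the Poisson limit.
#'
#' @param x Observed (normalized) count, vectorized.
#' @param mu Null mean, vectorized.
#' @param alpha Overdispersion of the quadratic variance trend.
#' @param two_sided If `FALSE`, return the depletion (lower) tail only.
#' @return Numeric vector of p-values in (0, 1].
#' @export
nb_tail_pvalue <- function(x, mu, alpha, two_sided = TRUE) {
  n <- max(length(x), length(mu), length(alpha))
  x <- rep_len(x, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  p <- rep(1, n)
  bad <- !(mu > 0)
  if (any(bad)) {
    warn(sprintf("%d guide(s) with non-positive null mean; p set to 1.",
                 sum(bad)))
  }
  ok <- !bad
  lo <- hi <- rep(NA_real_, n)
  pois <- ok & alpha < 1e-12
  if (any(pois)) {
    lo[pois] <- pgamma(mu[pois], shape = x[pois] + 1, lower.tail = FALSE)
    hi[pois] <- if_else(x[pois] <= 0, 1,
                        pgamma(mu[pois], shape = pmax(x[pois], 1e-12),
                               lower.tail = TRUE))
  }
  nb <- ok & !pois
  if (any(nb)) {
    size <- 1 / alpha[nb]
    prob <- size / (size + mu[nb])
    lo[nb] <- pbeta(prob, size, x[nb] + 1)
    hi[nb] <- if_else(x[nb] <= 0, 1, 1 - pbeta(prob, size, pmax(x[nb], 1e-12)))
  }
  if (two_sided) {
    p[ok] <- pmin(1, 2 * pmin(lo[ok], hi[ok], 0.5))
  } else {
    p[ok] <- pmax(lo[ok], .Machine$double.xmin)
  }
  p
}

#' Per-sgRNA null-model p-values for one screen
#'
#' Under the null of no fitness effect, a guide's expected tfinal abundance
#' equals its t0 abundance. Both are measured with noise, so the comparison
#' is made on the summed-counts scale with variance
#' `(1 + Rf/R0) * (M + (alpha/Rf) * M^2)` where `M` is the t0-derived
#' expectation of the tfinal total and `R0`, `Rf` are the replicate counts;
#' for the canonical two-replicate design this is exactly the
#' `NB(mu, mu + alpha * mu^2)` trend. The tail is evaluated with
#' [nb_tail_pvalue()] through a moment-matched effective dispersion.
#'
#' @param t0 Matrix/vector of t0 normalized counts (guides x replicates).
#' @param tfinal Matrix/vector of tfinal normalized counts.
#' @param alpha Screen overdispersion from [fit_nt_null()].
#' @param two_sided Two-sided by default; set `FALSE` for depletion-only.
#' @return Numeric vector of p-values, one per guide.
#' @export
sgrna_pvalues <- function(t0, tfinal, alpha, two_sided = TRUE) {
  t0 <- as.matrix(t0); tfinal <- as.matrix(tfinal)
  r0 <- ncol(t0); rf <- ncol(tfinal)
  m <- rowSums(t0) * (rf / r0)
  x <- rowSums(tfinal)
  v <- (1 + rf / r0) * (m + (alpha / rf) * m^2)
  alpha_eff <- if_else(m > 0, pmax(0, (v - m) / m^2), 0)
  nb_tail_pvalue(x, m, alpha_eff, two_sided = two_sided)
}

#' Calibrate the significance cutoff on non-targeting guides
#'
#' Chooses the largest p-value cutoff `c*` such that at least `target` of
#' the non-targeting guides are non-significant (p > c*), i.e. the empirical
#' `(1 - target)` quantile of the NT p-values adjusted for ties. Guides with
#' `p <= c*` are called depleted or enriched according to the sign of their
#' LFC; everything else is `ns`. The NT guarantee holds by construction on
#' every input.
#'
#' @param p P-values for all guides.
#' @param lfc Matching log2 fold-changes (for the call direction).
#' @param is_nt Logical, which entries are non-targeting.
#' @param target Desired NT non-significant fraction (default 0.95).
#' @return List with `cutoff` and `call` (factor levels depleted/enriched/ns).
#' @export
#' @examples
#' p <- c(0.001, 0.2, seq(0.01, 1, length.out = 100))
#' lfc <- c(-2, 1, rep(0, 100))
#' calibrate_significance(p, lfc, c(FALSE, FALSE, rep(TRUE, 100)))$cutoff
calibrate_significance <- function(p, lfc, is_nt, target = 0.95) {
  stopifnot(length(p) == length(lfc), length(p) == length(is_nt))
  nt_p <- p[is_nt]
  if (!length(nt_p)) abort("No non-targeting p-values to calibrate on.")
  cand <- sort(unique(c(0, nt_p)))
  feasible <- cand[vapply(cand, function(cc) mean(nt_p > cc) >= target,
                          logical(1))]
  cutoff <- max(feasible)
  sig <- p <= cutoff & cutoff > 0
  call <- rep("ns", length(p))
  call[sig & lfc < 0] <- "depleted"
  call[sig & lfc > 0] <- "enriched"
  list(cutoff = cutoff,
       call = factor(call, levels = c("depleted", "enriched", "ns")))
}

#' Per-sgRNA statistics for every screen
#'
#' End-to-end single-screen analysis: median-ratio normalization, per-line
#' replicate-averaged LFCs, the NT mean-dispersion trend, null-model tail
#' p-values and per-screen calibrated significance calls.
#'
#' @param counts Raw count tibble (guide_id + samples).
#' @param design Sample sheet.
#' @param library Guide library (for the `is_nt` flags).
#' @param target NT non-significant calibration target (default 0.95).
#' @param pseudocount LFC pseudocount (default 0.5).
#' @param two_sided Two-sided test (default) or depletion-only.
#' @return Tibble of class `sgrna_stats`: one row per guide per screen with
#'   normalized means `n0`/`nf`, `lfc`, `p`, `call`; attributes `null_model`,
#'   `cutoffs`, `size_factors`.
#' @export
analyze_screens <- function(counts, design, library, target = 0.95,
                            pseudocount = 0.5, two_sided = TRUE) {
  validate_sample_sheet(design, paired = TRUE)
  norm <- median_ratio_normalize(counts)
  mat <- counts_to_matrix(norm$normalized)
  lfc <- compute_log2fc(norm$normalized, design, pseudocount)$per_line
  nt_ids <- library$guide_id[library$is_nt]
  null_model <- fit_nt_null(norm$normalized, design, nt_ids)

  screens <- distinct(design, .data$species, .data$individual)
  cutoffs <- list()
  res <- purrr::pmap(screens, function(species, individual) {
    s0 <- design$sample_id[design$species == species &
                             design$individual == individual &
                             design$timepoint == "t0"]
    sf <- design$sample_id[design$species == species &
                             design$individual == individual &
                             design$timepoint == "tfinal"]
    a <- null_model$trend$alpha[null_model$trend$species == species &
                                  null_model$trend$individual == individual]
    p <- sgrna_pvalues(mat[, s0, drop = FALSE], mat[, sf, drop = FALSE],
                       alpha = a, two_sided = two_sided)
    scr <- tibble(
      guide_id = rownames(mat),
      species = species, individual = individual,
      n0 = rowMeans(mat[, s0, drop = FALSE]),
      nf = rowMeans(mat[, sf, drop = FALSE]),
      p = p
    ) |>
      left_join(lfc, by = c("guide_id", "species", "individual")) |>
      mutate(is_nt = .data$guide_id %in% nt_ids)
    cal <- calibrate_significance(scr$p, scr$lfc, scr$is_nt, target)
    scr$call <- cal$call
    attr(scr, "cutoff") <- cal$cutoff
    scr
  })
  cutoffs <- tibble(
    species = screens$species, individual = screens$individual,
    cutoff = vapply(res, attr, numeric(1), "cutoff")
  )
  out <- bind_rows(res)
  class(out) <- c("sgrna_stats", class(out))
  attr(out, "null_model") <- null_model
  attr(out, "cutoffs") <- cutoffs
  attr(out, "size_factors") <- norm$size_factors
  attr(out, "target") <- target
  out
}
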