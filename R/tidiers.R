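#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the non-targeting null model
#'
#' One row per screen with the fitted overdispersion.
#'
#' @param x An `nt_null_model` from [fit_nt_null()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.nt_null_model <- function(x, ...) x$trend

#' @rdname tidy.nt_null_model
#' @exportS3Method generics::glance
glance.nt_null_model <- function(x, ...) {
  tibble(n_screens = nrow(x$trend), n_nt = x$n_nt,
         alpha_median = median(x$trend$alpha))
}

#' Tidy per-screen sgRNA statistics
#'
#' @param x An `sgrna_stats` table from [analyze_screens()].
#' @param ... Unused.
#' @return The underlying tibble (tidy) or a one-row summary (glance) with
#'   per-screen calibrated cutoffs and significant-call counts.
#' @exportS3Method generics::tidy
tidy.sgrna_stats <- function(x, ...) as_tibble(x)

#' @rdname tidy.sgrna_stats
#' @exportS3Method generics::glance
glance.sgrna_stats <- function(x, ...) {
  tibble(
    n_guides = length(unique(x$guide_id)),
    n_screens = nrow(attr(x, "cutoffs")),
    target = attr(x, "target"),
    median_cutoff = median(attr(x, "cutoffs")$cutoff),
    frac_significant = mean(x$call != "ns")
  )
}

#' Tidy a species-contrast analysis
#'
#' `tidy()` returns the per-sgRNA contrast table; `glance()` a one-row
#' summary with the dispersion used, the alpha-RRA threshold and call counts.
#'
#' @param x A `crispr_contrast` from [run_validation_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.crispr_contrast <- function(x, ...) as_tibble(x$sgrna)

#' @rdname tidy.crispr_contrast
#' @exportS3Method generics::glance
glance.crispr_contrast <- function(x, ...) {
  tibble(
    n_sgrna = nrow(x$sgrna),
    n_genes = nrow(x$genes),
    alpha_dispersion = attr(x$sgrna, "alpha"),
    alpha_rra = attr(x$genes, "alpha_rra"),
    n_species_different_sgrna = sum(x$sgrna$species_different, na.rm = TRUE),
    n_called = sum(x$genes$call %in%
                     c("speciesA-specific", "speciesB-specific"))
  )
}

#' @rdname tidy.crispr_contrast
#' @exportS3Method generics::tidy
tidy.species_calls <- function(x, ...) as_tibble(x)

#' @rdname tidy.crispr_contrast
#' @exportS3Method generics::glance
glance.species_calls <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(
    n_genes = nrow(x),
    fdr_threshold = thr$fdr,
    min_pass = thr$min_pass,
    lfc_diff = thr$lfc_diff,
    n_called = sum(x$call %in% c("speciesA-specific", "speciesB-specific")),
    n_excluded_shared = sum(x$excluded_shared, na.rm = TRUE)
  )
}
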