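#' Read and write screen tables
#'
#' TSV readers/writers for the guide library, count matrix, sample sheet and
#' results tables. All tables are UTF-8 TSV with a header row and no index
#' column; missing values are forbidden in counts. Readers validate structure
#' and raise distinct errors for duplicate guide ids, non-integer or negative
#' counts, and malformed sample sheets, so that `write` then `read` is the
#' identity on valid data.
#'
#' @param path File path.
#' @param x Table to write.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
read_guide_library <- function(path) {
  lib <- readr::read_tsv(path, col_types = readr::cols(
    guide_id = readr::col_character(),
    spacer = readr::col_character(),
    gene = readr::col_character(),
    tss_offset = readr::col_integer(),
    is_nt = readr::col_logical(),
    on_target_score = readr::col_double(),
    specificity_score = readr::col_double()
  ), progress = FALSE)
  dup <- lib$guide_id[duplicated(lib$guide_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate guide ids in library: %s",
                  paste(head(unique(dup), 5), collapse = ", ")))
  }
  lib
}

#' @rdname screen_io
#' @export
write_guide_library <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_count_matrix <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    guide_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_count_matrix(counts)
  counts
}

#' @rdname screen_io
#' @export
write_count_matrix <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_sample_sheet <- function(path) {
  ss <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  validate_sample_sheet(ss)
  ss
}

#' @rdname screen_io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Validate a count matrix
#'
#' Checks that the first column is `guide_id` with no duplicates, that all
#' count entries are present, non-negative and integer-valued, and (when a
#' design is given) that every count column is a known sample.
#'
#' @param counts Tibble: `guide_id` plus one numeric column per sample.
#' @param design Optional sample sheet to check column names against.
#' @return `counts`, invisibly.
#' @export
validate_count_matrix <- function(counts, design = NULL) {
  if (names(counts)[1] != "guide_id") {
    abort("Count matrix must have `guide_id` as its first column.")
  }
  dup <- counts$guide_id[duplicated(counts$guide_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate guide ids in counts: %s",
                  paste(head(unique(dup), 5), collapse = ", ")))
  }
  mat <- as.matrix(counts[-1])
  if (anyNA(mat)) {
    ij <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing count for guide '%s', sample '%s'.",
                  counts$guide_id[ij[1]], colnames(mat)[ij[2]]))
  }
  if (any(mat < 0)) {
    ij <- which(mat < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative count for guide '%s', sample '%s'.",
                  counts$guide_id[ij[1]], colnames(mat)[ij[2]]))
  }
  if (any(mat != round(mat))) {
    ij <- which(mat != round(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-integer count for guide '%s', sample '%s'.",
                  counts$guide_id[ij[1]], colnames(mat)[ij[2]]))
  }
  if (!is.null(design)) {
    unknown <- setdiff(colnames(mat), design$sample_id)
    if (length(unknown)) {
      abort(sprintf("Samples in counts but not in the sample sheet: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  invisible(counts)
}

#' Validate a sample sheet
#'
#' Requires columns sample_id, species, individual, replicate, timepoint;
#' unique sample ids; timepoints in \{t0, tfinal\}. With `paired = TRUE`,
#' additionally requires every (species, individual, replicate) combination
#' to be present at both timepoints.
#'
#' @param design Sample sheet tibble.
#' @param paired Require both timepoints per screen unit?
#' @return `design`, invisibly.
#' @export
validate_sample_sheet <- function(design, paired = FALSE) {
  need <- c("sample_id", "species", "individual", "replicate", "timepoint")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols)) {
    abort(sprintf("Sample sheet lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate sample ids: %s", paste(dup, collapse = ", ")))
  }
  bad_tp <- setdiff(unique(design$timepoint), c("t0", "tfinal"))
  if (length(bad_tp)) {
    abort(sprintf("Unknown timepoints (expected t0/tfinal): %s",
                  paste(bad_tp, collapse = ", ")))
  }
  if (paired) {
    chk <- design |>
      dplyr::count(.data$species, .data$individual, .data$replicate,
                   .data$timepoint) |>
      tidyr::pivot_wider(names_from = "timepoint", values_from = "n",
                         values_fill = 0L)
    bad <- chk[chk$t0 == 0L | chk$tfinal == 0L, ]
    if (nrow(bad)) {
      abort(sprintf(
        "Unpaired screen unit(s): %s",
        paste(sprintf("%s/%s/%s", bad$species, bad$individual,
                      bad$replicate), collapse = ", ")
      ))
    }
  }
  invisible(design)
}

#' Read a genome FASTA
#'
#' Multi-line sequences are supported and sequences are case-folded to
#' uppercase, so lowercase (soft-masked) genomes match identically.
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet-class], names truncated at whitespace.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' @rdname read_genome_fasta
#' @param x A `DNAStringSet` to write.
#' @export
write_genome_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Count exact spacer matches in a FASTQ file
#'
#' Each read's spacer window (`spacer_start`, 1-based, of the library's
#' spacer length) is extracted and looked up exactly against the library,
#' forward orientation only. Unmatched reads are tallied, never dropped
#' silently: `total matched + unmatched = total reads`. Counting is invariant
#' to read order and deterministic. Gzipped FASTQ is read transparently.
#'
#' @param fastq Path to a FASTQ(.gz) file.
#' @param library Guide library tibble (all spacers must share one length).
#' @param spacer_start 1-based position of the spacer window within each read.
#' @return Tibble `guide_id`, `count` (one row per library guide), with
#'   attributes `unmatched` and `total_reads`.
#' @export
count_fastq_reads <- function(fastq, library, spacer_start = 1L) {
  sp_len <- unique(nchar(library$spacer))
  if (length(sp_len) != 1L) {
    abort("All library spacers must have the same length.")
  }
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  n_reads <- length(reads)
  counts <- setNames(integer(nrow(library)), library$guide_id)
  unmatched <- 0L
  if (n_reads == 0L) {
    warn(sprintf("FASTQ '%s' contains no reads; returning zero counts.",
                 fastq))
  } else {
    too_short <- which(Biostrings::width(reads) < spacer_start + sp_len - 1L)
    if (length(too_short)) {
      abort(sprintf(
        "Read(s) shorter than the spacer window (first offender: read %d).",
        too_short[1]
      ))
    }
    windows <- toupper(as.character(
      Biostrings::subseq(reads, start = spacer_start, width = sp_len)
    ))
    hit <- match(windows, library$spacer)
    unmatched <- sum(is.na(hit))
    tab <- table(factor(library$guide_id[hit[!is.na(hit)]],
                        levels = library$guide_id))
    counts <- counts + as.integer(tab)
  }
  out <- tibble(guide_id = library$guide_id, count = as.integer(counts))
  attr(out, "unmatched") <- unmatched
  attr(out, "total_reads") <- n_reads
  out
}

#' Write simulated screen artifacts to a directory
#'
#' Writes library, counts, sample sheet and ground truth as TSV and the toy
#' genomes as FASTA, matching the formats the readers expect.
#'
#' @param sim Result of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_guide_library(sim$library, file.path(dir, "library.tsv"))
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$design, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$guides, file.path(dir, "truth_guides.tsv"),
                   progress = FALSE)
  if (!is.null(sim$genome_a)) {
    write_genome_fasta(sim$genome_a, file.path(dir, "genome_a.fa"))
    write_genome_fasta(sim$genome_b, file.path(dir, "genome_b.fa"))
  }
  invisible(dir)
}
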