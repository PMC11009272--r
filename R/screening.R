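#' Thresholds for occurrence screening of read sets
#'
#' Retention rules for deciding whether a sample's amplicon reads contain
#' the query lineage. Boundary semantics follow the strict phrasing of the
#' screening protocol: a read matches only if it is strictly longer than
#' `min_read_length_bp` and shows strictly more than `min_identity_percent`
#' identity; a sample is discarded if it has fewer than `min_matching_reads`
#' matches (kept at exactly the minimum), and retained for mapping only if
#' its matching-read relative abundance strictly exceeds
#' `min_relative_abundance_percent`.
#'
#' @param min_read_length_bp Read length cutoff, bp (exclusive; default 200).
#' @param min_identity_percent Identity cutoff, percent (exclusive; default
#'   95).
#' @param min_matching_reads Minimum matching reads to keep a sample
#'   (inclusive; default 10).
#' @param min_relative_abundance_percent Relative abundance cutoff, percent
#'   (exclusive; default 0.1).
#'
#' @return A validated `nb_screening_thresholds` list.
#' @export
screening_thresholds <- function(min_read_length_bp = 200,
                                 min_identity_percent = 95,
                                 min_matching_reads = 10,
                                 min_relative_abundance_percent = 0.1) {
  check_number(min_read_length_bp, "min_read_length_bp", lower = 0,
               allow_zero_lower = FALSE)
  check_number(min_identity_percent, "min_identity_percent", lower = 0,
               upper = 100)
  check_number(min_matching_reads, "min_matching_reads", lower = 0,
               allow_zero_lower = FALSE)
  check_number(min_relative_abundance_percent,
               "min_relative_abundance_percent", lower = 0, upper = 100)
  structure(
    list(min_read_length_bp = min_read_length_bp,
         min_identity_percent = min_identity_percent,
         min_matching_reads = min_matching_reads,
         min_relative_abundance_percent = min_relative_abundance_percent),
    class = "nb_screening_thresholds"
  )
}

# Best-strand identity of one read against the query.
read_identity <- function(read, query) {
  fwd <- pairwise_identity(read, query)$identity_percent
  rev <- pairwise_identity(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(read))),
    query)$identity_percent
  max(fwd, rev)
}

#' Screen one sample's reads against a query 16S sequence
#'
#' Counts reads that match the query (strictly longer than the length
#' cutoff AND strictly above the identity cutoff under the semi-global
#' overlap alignment of [pairwise_identity()], best of both strands) and
#' classifies the sample: `discarded_low_hits` if matching reads fall below
#' the minimum, `below_abundance` if the matching-read relative abundance
#' does not strictly exceed the abundance cutoff, else `retained`.
#'
#' @param reads Character vector of read sequences, a `DNAStringSet`, or a
#'   path to a FASTA/FASTQ file.
#' @param query_16s Query 16S sequence (string).
#' @param thresholds A [screening_thresholds()] object.
#' @param sample_id Sample label for the output row.
#'
#' @return A one-row tibble: `sample_id`, `n_reads_total`,
#'   `n_matching_reads`, `relative_abundance_percent`, `status`.
#' @export
screen_sample <- function(reads, query_16s,
                          thresholds = screening_thresholds(),
                          sample_id = "sample") {
  stopifnot(inherits(thresholds, "nb_screening_thresholds"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  } else {
    reads <- as.character(reads)
  }
  if (length(reads) == 0) stop_format("Read set is empty.")
  n_total <- length(reads)

  long_enough <- nchar(reads) > thresholds$min_read_length_bp
  matches <- vapply(reads[long_enough], function(r) {
    read_identity(r, query_16s) > thresholds$min_identity_percent
  }, logical(1), USE.NAMES = FALSE)
  n_match <- sum(matches)
  rel_pct <- 100 * n_match / n_total

  status <- if (n_match < thresholds$min_matching_reads) {
    "discarded_low_hits"
  } else if (rel_pct <= thresholds$min_relative_abundance_percent) {
    "below_abundance"
  } else {
    "retained"
  }
  tibble::tibble(sample_id = sample_id, n_reads_total = n_total,
                 n_matching_reads = n_match,
                 relative_abundance_percent = rel_pct, status = status)
}

#' Keep only samples retained for spatial mapping
#'
#' Subsets [screen_sample()] results to rows with `status == "retained"`,
#' preserving input order.
#'
#' @param results Tibble of stacked [screen_sample()] rows, all screened
#'   under the same thresholds.
#' @return The retained subset, same columns and order.
#' @export
retain_for_mapping <- function(results) {
  stopifnot("status" %in% names(results))
  dplyr::filter(results, .data$status == "retained")
}
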