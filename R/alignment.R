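#' Percent identity between two nucleotide sequences
#'
#' Semi-global (free end-gap, "overlap") pairwise alignment, so a short
#' amplicon scored against a full-length 16S gene is judged over their
#' overlap only. Identity is matches divided by aligned columns (internal
#' gaps count as columns; terminal overhangs do not). Default scoring:
#' match +1, mismatch -1, linear gap -2.
#'
#' @param seq_a,seq_b Nucleotide sequences (single strings or length-1
#'   `DNAStringSet`/`DNAString`).
#' @param match,mismatch,gap Alignment scores; `gap` is the positive penalty
#'   per gapped column.
#'
#' @return A list with `identity_percent` (in `[0, 100]`) and
#'   `alignment_length` (aligned columns, terminal overhangs excluded).
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGA")   # 75%
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = 2) {
  seq_a <- as.character(seq_a)
  seq_b <- as.character(seq_b)
  if (length(seq_a) != 1L || is.na(seq_a) || nchar(seq_a) == 0 ||
      length(seq_b) != 1L || is.na(seq_b) || nchar(seq_b) == 0) {
    stop_param("Both sequences must be single non-empty strings.", "seq")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b), type = "overlap",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = gap
  )
  list(
    identity_percent = Biostrings::pid(aln, type = "PID1"),
    alignment_length = Biostrings::nchar(aln)
  )
}

#' Link a genome 16S sequence to its best-matching amplicon OTU
#'
#' Compares a MAG-derived 16S rRNA gene sequence against every OTU
#' representative sequence with [pairwise_identity()] and reports the best
#' hit. Ties on identity are broken by longer alignment, then lexicographic
#' OTU id. If the best identity is below `min_identity` the link is `NA`.
#'
#' @param mag_16s Query 16S sequence (string).
#' @param otu_seqs Named character vector or `DNAStringSet` of OTU sequences.
#' @param min_identity Minimum percent identity to accept a link.
#' @param mag_id Label for the query in the output.
#'
#' @return A one-row tibble: `mag_id`, `otu_id` (NA if no acceptable hit),
#'   `identity_percent`, `alignment_length`.
#' @export
link_mag_to_otus <- function(mag_16s, otu_seqs, min_identity = 95,
                             mag_id = "MAG") {
  otu_seqs <- setNames(as.character(otu_seqs), names(otu_seqs))
  if (length(otu_seqs) == 0) {
    stop_param("`otu_seqs` must contain at least one sequence.", "otu_seqs")
  }
  if (is.null(names(otu_seqs)) || any(names(otu_seqs) == "")) {
    stop_param("`otu_seqs` must be named by OTU id.", "otu_seqs")
  }
  hits <- purrr::imap(otu_seqs, function(s, id) {
    pi <- pairwise_identity(mag_16s, s)
    tibble::tibble(otu_id = id,
                   identity_percent = pi$identity_percent,
                   alignment_length = pi$alignment_length)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$identity_percent),
                   dplyr::desc(.data$alignment_length), .data$otu_id)
  best <- hits[1, ]
  if (best$identity_percent < min_identity) {
    return(tibble::tibble(mag_id = mag_id, otu_id = NA_character_,
                          identity_percent = best$identity_percent,
                          alignment_length = best$alignment_length))
  }
  dplyr::mutate(best, mag_id = mag_id, .before = 1)
}
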