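# TSV dialect shared by all readers: UTF-8, tab-separated, '#' comment lines
# ignored, '.' means missing numeric.
nb_read_tsv <- function(path, ...) {
  readr::read_tsv(path, comment = "#", na = c(".", "NA", ""),
                  show_col_types = FALSE, progress = FALSE, ...)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf("%s: missing mandatory column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read and write an OTU count table
#'
#' The on-disk format is a TSV whose first column is `otu_id` and whose
#' remaining columns are per-sample read counts (non-negative integers).
#' Reading validates every cell; `write_otu_table()` is the exact inverse, so
#' write-then-read is an identity.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `otu_id` first and one integer column per sample.
#' @export
read_otu_table <- function(path) {
  df <- nb_read_tsv(path)
  if (ncol(df) < 2) {
    stop_format(sprintf("%s: need an otu_id column plus at least one sample.", path))
  }
  names(df)[1] <- "otu_id"
  df$otu_id <- as.character(df$otu_id)
  if (anyDuplicated(df$otu_id)) {
    stop_format(sprintf("%s: duplicate OTU ids.", path))
  }
  if (anyDuplicated(names(df))) {
    stop_format(sprintf("%s: duplicate sample ids.", path))
  }
  for (j in seq_along(df)[-1]) {
    x <- df[[j]]
    if (!is.numeric(x)) {
      stop_format(sprintf("%s: column '%s' is not numeric.", path, names(df)[j]))
    }
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad) > 0) {
      stop_format(sprintf(
        "%s: invalid count at row %d (OTU '%s'), column '%s': must be a non-negative integer.",
        path, bad[1], df$otu_id[bad[1]], names(df)[j]))
    }
    df[[j]] <- as.integer(x)
  }
  df
}

#' @param otu_table A tibble as returned by [read_otu_table()].
#' @rdname read_otu_table
#' @export
write_otu_table <- function(otu_table, path) {
  stopifnot(names(otu_table)[1] == "otu_id")
  readr::write_tsv(otu_table, path)
  invisible(path)
}

#' Read a sample table
#'
#' Mandatory columns: `sample_id`, `core_id`, `depth_cm` (sample midpoint, cm
#' below seafloor), `qpcr_arch` and `qpcr_bac` (archaeal and bacterial 16S
#' copies per gram of sediment). Unknown columns are preserved but ignored
#' downstream. Total cells for a sample is taken as `qpcr_arch + qpcr_bac`.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_sample_table <- function(path) {
  df <- nb_read_tsv(path)
  require_columns(df, c("sample_id", "core_id", "depth_cm",
                        "qpcr_arch", "qpcr_bac"), path)
  df$sample_id <- as.character(df$sample_id)
  df$core_id <- as.character(df$core_id)
  if (anyDuplicated(df$sample_id)) {
    stop_format(sprintf("%s: duplicate sample ids.", path))
  }
  if (any(is.na(df$depth_cm)) || any(df$depth_cm < 0)) {
    stop_format(sprintf("%s: depth_cm must be present and >= 0.", path))
  }
  for (col in c("qpcr_arch", "qpcr_bac")) {
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) {
      stop_format(sprintf("%s: %s must be >= 0.", path, col))
    }
  }
  df
}

#' Read a porewater geochemistry profile table
#'
#' Mandatory columns: `core_id`, `depth_cm`. Optional concentration series:
#' `o2_uM`, `no3_uM`, `no2_uM`, `nh4_uM` (µM). Depths must be strictly
#' increasing within each core and all concentrations non-negative.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_geochem <- function(path) {
  df <- nb_read_tsv(path)
  require_columns(df, c("core_id", "depth_cm"), path)
  df$core_id <- as.character(df$core_id)
  bad <- df |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(ok = all(diff(.data$depth_cm) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop_format(sprintf("%s: depths not strictly increasing in core(s): %s",
                        path, paste(bad$core_id, collapse = ", ")))
  }
  for (col in intersect(c("o2_uM", "no3_uM", "no2_uM", "nh4_uM"), names(df))) {
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) {
      stop_format(sprintf("%s: %s has negative concentrations.", path, col))
    }
  }
  df
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read and write an OTU taxonomy table
#'
#' Two on-disk layouts are accepted: either one column per rank
#' (`domain` ... `genus`), or a single `lineage` column holding a
#' semicolon-separated lineage which is split into the six ranks. Missing or
#' short lineages are padded with `"unclassified"`. An optional `db` column
#' records the reference database label (e.g. `"SILVA 138.1"`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `otu_id`, the six ranks, and `db`.
#' @export
read_taxonomy <- function(path) {
  df <- nb_read_tsv(path)
  require_columns(df, "otu_id", path)
  df$otu_id <- as.character(df$otu_id)
  if (anyDuplicated(df$otu_id)) {
    stop_format(sprintf("%s: duplicate OTU ids.", path))
  }
  if (!all(TAX_RANKS %in% names(df))) {
    require_columns(df, "lineage", path)
    parts <- strsplit(as.character(df$lineage), ";", fixed = TRUE)
    ranks <- purrr::map(parts, function(x) {
      x <- trimws(x)
      x[x == ""] <- "unclassified"
      length(x) <- length(TAX_RANKS)
      x[is.na(x)] <- "unclassified"
      x
    })
    mat <- do.call(rbind, ranks)
    colnames(mat) <- TAX_RANKS
    df <- dplyr::bind_cols(dplyr::select(df, -"lineage"),
                           tibble::as_tibble(mat))
  }
  for (r in TAX_RANKS) {
    df[[r]] <- as.character(df[[r]])
    df[[r]][is.na(df[[r]]) | df[[r]] == ""] <- "unclassified"
  }
  if (!"db" %in% names(df)) df$db <- NA_character_
  dplyr::select(df, "otu_id", dplyr::all_of(TAX_RANKS), "db",
                dplyr::everything())
}

#' @param taxonomy A tibble as returned by [read_taxonomy()].
#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path)
  invisible(path)
}

#' Basic assembly statistics from a FASTA file
#'
#' Computes the record count, total assembly length, GC content and contig
#' N50 of a nucleotide FASTA. GC is computed over unambiguous A/C/G/T bases
#' only; ambiguity codes (including N) are excluded from both numerator and
#' denominator and their total count is reported. N50 is the largest length
#' `L` such that sequences of length >= `L` cover at least half of the total
#' assembly length.
#'
#' @param fasta_path Path to a (possibly wrapped) multi-record FASTA file.
#' @return A one-row tibble: `n_sequences`, `total_length_bp`, `gc_percent`,
#'   `n50_bp`, `n_ambiguous_bases`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ATGCGC"), fa)
#' assembly_stats(fa)
assembly_stats <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) {
    stop_format(sprintf("%s: FASTA file contains no sequences.", fasta_path))
  }
  lens <- Biostrings::width(seqs)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  n_other <- sum(freq[, "other"])
  if (n_other > 0) {
    inform(sprintf("%s: %d ambiguous/non-ACGT bases excluded from GC.",
                   basename(fasta_path), n_other))
  }
  tibble::tibble(
    n_sequences = length(seqs),
    total_length_bp = sum(lens),
    gc_percent = 100 * (acgt[["G"]] + acgt[["C"]]) / sum(acgt),
    n50_bp = n50(lens),
    n_ambiguous_bases = n_other
  )
}

n50 <- function(lengths) {
  lengths <- sort(lengths, decreasing = TRUE)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1]]
}
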