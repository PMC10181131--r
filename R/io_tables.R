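#' Read a dosage-score matrix
#'
#' Reads a delimited samples x markers table of allele-B dosage scores. The
#' first column holds sample names, the header row holds marker names, and
#' cells hold integer dosages in `{0, 1, 2, 3, 4}` or a missing token
#' (`NA`, empty, or `.`).
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the header).
#' @return A tibble with a `sample` character column followed by one integer
#'   column per marker. Duplicate sample names are allowed (they arise in
#'   homonym studies) but reported via a message.
#' @export
read_dosage_matrix <- function(path) {
  hdr <- readLines(path, n = 1)
  delim <- if (grepl("\t", hdr)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character())
  names(tab)[1] <- "sample"
  markers <- names(tab)[-1]
  out <- tab
  for (m in markers) {
    v <- tab[[m]]
    v[v %in% c("NA", "", ".")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | !num %in% 0:4))
    if (length(bad) > 0) {
      abort(sprintf(
        "read_dosage_matrix: invalid dosage '%s' for sample '%s', marker '%s'",
        v[bad[1]], tab$sample[bad[1]], m))
    }
    out[[m]] <- as.integer(num)
  }
  if (anyDuplicated(out$sample)) {
    inform(sprintf("read_dosage_matrix: duplicate sample names present (%s)",
                   paste(unique(out$sample[duplicated(out$sample)]),
                         collapse = ", ")))
  }
  inform(sprintf("read_dosage_matrix: %s: %d samples x %d markers",
                 basename(path), nrow(out), length(markers)))
  out
}

#' Write a dosage-score matrix
#'
#' @param dosage Dosage tibble (`sample` column plus marker columns).
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(dosage, path) {
  check_dosage_tbl(dosage)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(dosage, path, delim = delim, na = "NA")
  inform(sprintf("write_dosage_matrix: %s: %d samples x %d markers",
                 basename(path), nrow(dosage), ncol(dosage) - 1L))
  invisible(path)
}

check_dosage_tbl <- function(dosage) {
  if (!is.data.frame(dosage) || names(dosage)[1] != "sample") {
    abort("expected a dosage tibble whose first column is 'sample'")
  }
  vals <- unlist(dosage[-1], use.names = FALSE)
  if (any(!is.na(vals) & !vals %in% 0:4)) {
    abort("dosage values must be in {0, 1, 2, 3, 4} or NA")
  }
  invisible(dosage)
}

dosage_markers <- function(dosage) names(dosage)[-1]

#' Read or write a two-channel fluorescence signal table
#'
#' Signal tables are long-format tables with columns `sample`, `marker`,
#' `fam`, `hex` holding endpoint fluorescence intensities of the two
#' allele-specific PCR channels.
#'
#' @param path File path (CSV or TSV).
#' @return `read_signals()` returns the signal tibble; `write_signals()`
#'   returns `path` invisibly.
#' @export
read_signals <- function(path) {
  hdr <- readLines(path, n = 1)
  delim <- if (grepl("\t", hdr)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    sample = readr::col_character(), marker = readr::col_character(),
    fam = readr::col_double(), hex = readr::col_double()))
  inform(sprintf("read_signals: %s: %d records", basename(path), nrow(tab)))
  tab
}

#' @param signals Signal tibble with columns `sample`, `marker`, `fam`, `hex`.
#' @rdname read_signals
#' @export
write_signals <- function(signals, path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(signals, path, delim = delim, na = "NA")
  invisible(path)
}

#' Published dosage-class tallies for 71 potato SNP markers
#'
#' Per-marker dosage-class counts for a published panel of 71 allele-specific
#' PCR SNP markers scored on 190 autotetraploid potato varieties, together
#' with the observed heterozygosity (OH), mean A frequency (MA) and
#' polymorphic information content (PIC) values printed alongside them
#' (2-decimal precision). Columns `n0`..`n4` count varieties per dosage class
#' (0 = AAAA nulliplex ... 4 = BBBB quadruplex); `n_missing` counts failed
#' calls.
#'
#' This table is the package's reference surface for validating the marker
#' statistics: recomputing OH, MA and PIC from the counts reproduces every
#' printed value at 2-decimal rounding.
#'
#' @return A 71-row tibble with columns `marker`, `n0`..`n4`, `n_missing`,
#'   `oh_printed`, `ma_printed`, `pic_printed`.
#' @examples
#' ref <- potato_reference_markers()
#' marker_stats_from_counts(ref)
#' @export
potato_reference_markers <- function() {
  path <- system.file("extdata", "potato_marker_classes.tsv",
                      package = "tetrafinger", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), .default = readr::col_double()))
}

#' Expand per-marker dosage-class counts to a per-sample dosage matrix
#'
#' Builds a samples x markers dosage tibble whose per-marker class tallies
#' reproduce the given counts. Sample identities are synthetic (`S001`, ...):
#' the expansion preserves every per-marker statistic (MA, OH, PIC, class
#' tallies) but not the sample-wise joint structure, which count data cannot
#' encode.
#'
#' @param counts Tibble with columns `marker`, `n0`..`n4`, `n_missing`.
#' @return A dosage tibble with `max(rowSums(counts))` rows.
#' @export
counts_to_dosage_matrix <- function(counts) {
  need <- c("marker", paste0("n", 0:4), "n_missing")
  if (!all(need %in% names(counts))) {
    abort(paste0("counts_to_dosage_matrix: need columns ",
                 paste(need, collapse = ", ")))
  }
  totals <- rowSums(counts[, c(paste0("n", 0:4), "n_missing")])
  n <- max(totals)
  out <- tibble(sample = sprintf("S%03d", seq_len(n)))
  for (i in seq_len(nrow(counts))) {
    col <- rep(c(0:4, NA_integer_),
               times = c(unlist(counts[i, paste0("n", 0:4)]),
                         counts$n_missing[i] + n - totals[i]))
    out[[counts$marker[i]]] <- as.integer(col)
  }
  out
}
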