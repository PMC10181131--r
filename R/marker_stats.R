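#' Tally dosage classes in one marker column
#'
#' @param x Vector of dosage scores in `{0,1,2,3,4}` or `NA`.
#' @return Named integer vector `n0, n1, n2, n3, n4, n_missing`.
#' @export
tally_dosages <- function(x) {
  if (any(!is.na(x) & !x %in% 0:4)) {
    abort(sprintf("tally_dosages: value out of range: %s",
                  paste(unique(x[!is.na(x) & !x %in% 0:4]), collapse = ", ")))
  }
  counts <- vapply(0:4, function(d) sum(x == d, na.rm = TRUE), integer(1))
  c(setNames(counts, paste0("n", 0:4)), n_missing = sum(is.na(x)))
}

#' Per-marker dosage statistics: MA, OH and PIC
#'
#' For an autotetraploid marker scored as the number of B-allele copies
#' (dosage 0 = AAAA ... 4 = BBBB), with class counts \eqn{n_0..n_4} over the
#' \eqn{n} called samples (missing calls excluded from every denominator):
#'
#' * mean A frequency \eqn{MA = \sum_d (4-d) n_d / (4n)} — the fraction of A
#'   allele copies among all scored allele copies;
#' * observed heterozygosity \eqn{OH = (n_1+n_2+n_3)/n} — the fraction of
#'   called samples carrying both alleles;
#' * polymorphic information content \eqn{PIC = 1 - \sum_g f_g^2} with
#'   \eqn{f_g = n_g/n} — gene diversity over the five dosage classes, maximal
#'   at 0.8 when all five classes are equally frequent and 0 for a
#'   single-class (monomorphic) marker.
#'
#' @param counts Numeric vector of the five class counts `n0..n4`.
#' @return A fraction, or `NA` when no samples are called.
#' @examples
#' ma_statistic(c(4, 11, 52, 71, 39))   # 0.3164
#' oh_statistic(c(4, 11, 52, 71, 39))   # 0.7571
#' pic_statistic(c(4, 11, 52, 71, 39))  # 0.6999
#' @export
ma_statistic <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  sum((4 - 0:4) * counts) / (4 * n)
}

#' @rdname ma_statistic
#' @export
oh_statistic <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  sum(counts[2:4]) / n
}

#' @rdname ma_statistic
#' @export
pic_statistic <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  1 - sum((counts / n)^2)
}

check_counts <- function(counts) {
  if (length(counts) != 5 || any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be 5 non-negative class counts n0..n4")
  }
  as.numeric(counts)
}

#' Per-marker statistics for a dosage matrix
#'
#' Computes, for every marker column, the five dosage-class counts, the number
#' of missing calls, and the MA, OH and PIC statistics
#' (see [ma_statistic()]).
#'
#' @param dosage Dosage tibble (`sample` column plus marker columns).
#' @return A tibble with one row per marker and columns `marker`, `n0`..`n4`,
#'   `n_missing`, `n_called`, `n_classes`, `ma`, `oh`, `pic`.
#' @export
marker_stats <- function(dosage) {
  check_dosage_tbl(dosage)
  markers <- dosage_markers(dosage)
  rows <- purrr::map(markers, function(m) {
    tl <- tally_dosages(dosage[[m]])
    counts <- tl[1:5]
    tibble(marker = m, !!!as.list(tl),
           n_called = sum(counts),
           n_classes = sum(counts > 0),
           ma = ma_statistic(counts),
           oh = oh_statistic(counts),
           pic = pic_statistic(counts))
  })
  bind_rows(rows)
}

#' Marker statistics straight from class-count rows
#'
#' Same output as [marker_stats()] but starting from per-marker tallies (as
#' stored by [potato_reference_markers()]) instead of per-sample columns.
#'
#' @param counts Tibble with columns `marker`, `n0`..`n4`, `n_missing`.
#' @return Tibble as for [marker_stats()].
#' @export
marker_stats_from_counts <- function(counts) {
  cnt <- as.matrix(counts[, paste0("n", 0:4)])
  tibble(marker = counts$marker,
         n0 = cnt[, 1], n1 = cnt[, 2], n2 = cnt[, 3], n3 = cnt[, 4],
         n4 = cnt[, 5],
         n_missing = counts$n_missing,
         n_called = rowSums(cnt),
         n_classes = rowSums(cnt > 0),
         ma = apply(cnt, 1, ma_statistic),
         oh = apply(cnt, 1, oh_statistic),
         pic = apply(cnt, 1, pic_statistic))
}

#' Cohort-level summary of marker statistics
#'
#' @param stats Per-marker statistics from [marker_stats()].
#' @return A one-row tibble: marker count; min/mean/max of MA, OH and PIC
#'   (computed on unrounded per-marker values); the number of markers with a
#'   single observed dosage class, with all five classes, and with MA > 0.5.
#' @export
summarize_markers <- function(stats) {
  if (nrow(stats) == 0) abort("summarize_markers: no markers")
  tibble(n_markers = nrow(stats),
         ma_min = min(stats$ma, na.rm = TRUE),
         ma_mean = mean(stats$ma, na.rm = TRUE),
         ma_max = max(stats$ma, na.rm = TRUE),
         oh_min = min(stats$oh, na.rm = TRUE),
         oh_mean = mean(stats$oh, na.rm = TRUE),
         oh_max = max(stats$oh, na.rm = TRUE),
         pic_min = min(stats$pic, na.rm = TRUE),
         pic_mean = mean(stats$pic, na.rm = TRUE),
         pic_max = max(stats$pic, na.rm = TRUE),
         n_single_class = sum(stats$n_classes == 1),
         n_five_class = sum(stats$n_classes == 5),
         n_ma_above_half = sum(stats$ma > 0.5, na.rm = TRUE))
}

#' Drop markers with a single observed dosage class
#'
#' Monomorphic markers carry no identification information and are removed
#' before distance, clustering and fingerprint analyses.
#'
#' @param dosage Dosage tibble.
#' @param stats Optional precomputed [marker_stats()] for `dosage`.
#' @return The dosage tibble without single-class markers, order preserved.
#' @export
drop_monomorphic <- function(dosage, stats = NULL) {
  if (is.null(stats)) stats <- marker_stats(dosage)
  keep <- stats$marker[stats$n_classes != 1]
  if (length(keep) == 0) {
    warn("drop_monomorphic: all markers are monomorphic; empty matrix")
  }
  dropped <- setdiff(stats$marker, keep)
  if (length(dropped) > 0) {
    inform(sprintf("drop_monomorphic: removed %d single-class marker(s): %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  dosage[, c("sample", keep)]
}
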