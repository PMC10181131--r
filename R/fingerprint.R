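#' Select fingerprint loci by PIC
#'
#' @param stats Per-marker statistics from [marker_stats()].
#' @param pic_threshold Loci with PIC strictly above this are selected.
#' @return Character vector of marker names ordered by descending PIC, ties
#'   broken by marker name (a deterministic order).
#' @export
select_fingerprint_loci <- function(stats, pic_threshold = 0.6) {
  sel <- stats %>%
    filter(!is.na(.data$pic), .data$pic > pic_threshold) %>%
    arrange(desc(.data$pic), .data$marker)
  sel$marker
}

#' Build per-sample SNP fingerprints
#'
#' Restricts the dosage matrix to the selected loci and serialises each
#' sample's dosage vector as a compact string code (digits 0-4, `N` for a
#' missing call), in locus order.
#'
#' @param dosage Dosage tibble.
#' @param loci Character vector of marker names (subset of the dosage
#'   columns), e.g. from [select_fingerprint_loci()].
#' @return An object of class `fingerprint_table`: tibble with columns
#'   `sample` and `code`, with the locus list stored in attribute `loci`.
#' @export
build_fingerprints <- function(dosage, loci) {
  check_dosage_tbl(dosage)
  unknown <- setdiff(loci, dosage_markers(dosage))
  if (length(unknown) > 0) {
    abort(paste0("build_fingerprints: unknown locus/loci: ",
                 paste(unknown, collapse = ", ")))
  }
  m <- as.matrix(dosage[, loci, drop = FALSE])
  code <- apply(m, 1, function(v) {
    paste(ifelse(is.na(v), "N", as.character(v)), collapse = "")
  })
  structure(tibble(sample = dosage$sample, code = unname(code)),
            loci = loci, class = c("fingerprint_table", "tbl_df", "tbl",
                                   "data.frame"))
}

fingerprint_loci <- function(fp) attr(fp, "loci")

## compare two fingerprint codes; list(identical over shared, n_shared,
## differing locus indices)
compare_codes <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  shared <- ca != "N" & cb != "N"
  list(identical = all(ca[shared] == cb[shared]),
       n_shared = sum(shared),
       differing = which(shared & ca != cb))
}

#' Detect synonyms and homonyms among named varieties
#'
#' A *synonym* pair is two differently named samples whose genotypes are
#' indistinguishable: pairwise distance 0 on the full marker panel **and**
#' identical fingerprint codes on at least `min_shared_loci` loci scored in
#' both samples. A *homonym* group is a set of samples sharing one variety
#' name whose genotypes differ (any pairwise distance above 0); the loci at
#' which they differ are reported. Same-name pairs at distance 0 are
#' concordant replicates; distance-0 pairs with too few comparable
#' fingerprint loci are reported as unresolved rather than declared
#' identical.
#'
#' @param fingerprints A [build_fingerprints()] table.
#' @param distances An `ed_dist` computed on the full (post-
#'   [drop_monomorphic()]) matrix.
#' @param names Tibble mapping `sample` to `variety` name. Defaults to each
#'   sample being its own variety.
#' @param min_shared_loci Minimum comparable fingerprint loci for a synonym
#'   call.
#' @return An object of class `identity_report`: list of tibbles `synonyms`
#'   (`sample_a`, `sample_b`, `variety_a`, `variety_b`, `distance`, `code`),
#'   `homonyms` (`variety`, `sample_a`, `sample_b`, `distance`,
#'   `differing_loci`), `replicates`, and `unresolved`.
#' @export
identify_varieties <- function(fingerprints, distances, names = NULL,
                               min_shared_loci = 10) {
  smp <- fingerprints$sample
  if (is.null(names)) names <- tibble(sample = smp, variety = smp)
  if (!all(smp %in% names$sample)) {
    abort("identify_varieties: names must cover every fingerprinted sample")
  }
  variety <- names$variety[match(smp, names$sample)]
  dm <- distances$d
  if (!all(smp %in% rownames(dm))) {
    abort("identify_varieties: distance matrix must cover every sample")
  }
  loci <- fingerprint_loci(fingerprints)
  syn <- list(); hom <- list(); rep_ <- list(); unres <- list()
  n <- length(smp)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n) ) {
      d <- dm[smp[i], smp[j]]
      same_name <- variety[i] == variety[j]
      if (!same_name && !is.na(d) && d == 0) {
        cmp <- compare_codes(fingerprints$code[i], fingerprints$code[j])
        if (cmp$identical && cmp$n_shared >= min_shared_loci) {
          syn[[length(syn) + 1]] <- tibble(
            sample_a = smp[i], sample_b = smp[j],
            variety_a = variety[i], variety_b = variety[j],
            distance = d, code = fingerprints$code[i])
        } else {
          unres[[length(unres) + 1]] <- tibble(
            sample_a = smp[i], sample_b = smp[j],
            variety_a = variety[i], variety_b = variety[j],
            distance = d, n_shared_loci = cmp$n_shared,
            fingerprints_identical = cmp$identical)
        }
      } else if (same_name) {
        if (!is.na(d) && d > 0) {
          cmp <- compare_codes(fingerprints$code[i], fingerprints$code[j])
          hom[[length(hom) + 1]] <- tibble(
            variety = variety[i], sample_a = smp[i], sample_b = smp[j],
            distance = d,
            differing_loci = paste(loci[cmp$differing], collapse = ";"))
        } else if (!is.na(d)) {
          rep_[[length(rep_) + 1]] <- tibble(
            variety = variety[i], sample_a = smp[i], sample_b = smp[j])
        }
      }
    }
  }
  empty <- function(x, proto) if (length(x) > 0) bind_rows(x) else proto
  out <- structure(list(
    synonyms = empty(syn, tibble(sample_a = character(),
                                 sample_b = character(),
                                 variety_a = character(),
                                 variety_b = character(),
                                 distance = numeric(), code = character())),
    homonyms = empty(hom, tibble(variety = character(),
                                 sample_a = character(),
                                 sample_b = character(),
                                 distance = numeric(),
                                 differing_loci = character())),
    replicates = empty(rep_, tibble(variety = character(),
                                    sample_a = character(),
                                    sample_b = character())),
    unresolved = empty(unres, tibble(sample_a = character(),
                                     sample_b = character(),
                                     variety_a = character(),
                                     variety_b = character(),
                                     distance = numeric(),
                                     n_shared_loci = integer(),
                                     fingerprints_identical = logical()))),
    class = "identity_report")
  if (nrow(out$replicates) > 0) {
    inform(sprintf("identify_varieties: %d concordant replicate pair(s)",
                   nrow(out$replicates)))
  }
  out
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf(paste0("<identity_report> %d synonym pair(s), %d homonym ",
                     "pair(s), %d replicate pair(s), %d unresolved\n"),
              nrow(x$synonyms), nrow(x$homonyms), nrow(x$replicates),
              nrow(x$unresolved)))
  if (nrow(x$synonyms) > 0) { cat("Synonyms:\n"); print(x$synonyms) }
  if (nrow(x$homonyms) > 0) { cat("Homonyms:\n"); print(x$homonyms) }
  invisible(x)
}

#' @export
tidy.identity_report <- function(x, ...) {
  bind_rows(
    if (nrow(x$synonyms)) mutate(x$synonyms[, c("sample_a", "sample_b",
                                                "distance")],
                                 category = "synonym"),
    if (nrow(x$homonyms)) mutate(x$homonyms[, c("sample_a", "sample_b",
                                                "distance")],
                                 category = "homonym"),
    if (nrow(x$replicates)) mutate(x$replicates[, c("sample_a", "sample_b")],
                                   distance = 0, category = "replicate"),
    if (nrow(x$unresolved)) mutate(x$unresolved[, c("sample_a", "sample_b",
                                                    "distance")],
                                   category = "unresolved"))
}
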