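#' Partition sites into biallelic and multiallelic sets
#'
#' @param cohort A [snp_cohort()].
#' @return A list with `biallelic` and `multiallelic` cohorts; both preserve
#'   input order and their site counts sum to the input count.
#' @export
partition_biallelic <- function(cohort) {
  multi <- cohort$sites$multiallelic
  list(biallelic = subset_sites(cohort, !multi),
       multiallelic = subset_sites(cohort, multi))
}

#' Per-site quality metrics
#'
#' Computes, for every site, the call integrity (fraction of samples with a
#' genotype call), miss rate, minor allele frequency over called allele
#' copies, heterozygous-sample fraction, and — when allele depths are
#' available — read support for the cohort-minor allele.
#'
#' @param cohort A [snp_cohort()].
#' @param minor_reads_scope `"cohort"` (sum of minor-allele reads over
#'   samples) or `"per_sample"` (maximum over samples).
#' @return A tibble with one row per site: `chrom`, `pos`, `id`, `n_samples`,
#'   `n_called`, `integrity`, `miss_rate`, `maf`, `het_fraction`,
#'   `minor_reads` (NA without depth data).
#' @export
site_qc <- function(cohort, minor_reads_scope = c("cohort", "per_sample")) {
  minor_reads_scope <- match.arg(minor_reads_scope)
  ns <- length(cohort$samples)
  rows <- purrr::map(seq_len(n_sites(cohort)), function(i) {
    alleles <- lapply(cohort$gt[i, ], gt_alleles)
    called <- !vapply(alleles, is.null, logical(1))
    n_called <- sum(called)
    copies <- unlist(alleles[called], use.names = FALSE)
    n_allele <- 1L + n_alt_alleles(cohort$sites$alt[i])
    freq <- vapply(seq_len(n_allele) - 1L, function(a) sum(copies == a),
                   numeric(1))
    maf <- if (length(copies) > 0) {
      f <- freq / sum(freq)
      if (n_allele == 2L) min(f) else sort(f, decreasing = TRUE)[2]
    } else NA_real_
    het <- if (n_called > 0) {
      mean(vapply(alleles[called],
                  function(a) length(unique(a)) > 1L, logical(1)))
    } else NA_real_
    minor_reads <- NA_real_
    if (!is.null(cohort$ad) && n_allele == 2L) {
      ad <- cohort$ad[[i]]
      minor_idx <- which.min(colSums(ad))
      minor_reads <- switch(minor_reads_scope,
                            cohort = sum(ad[, minor_idx]),
                            per_sample = max(ad[, minor_idx]))
    }
    tibble(chrom = cohort$sites$chrom[i], pos = cohort$sites$pos[i],
           id = cohort$sites$id[i],
           n_samples = ns, n_called = n_called,
           integrity = n_called / ns, miss_rate = 1 - n_called / ns,
           maf = maf, het_fraction = het, minor_reads = minor_reads)
  })
  bind_rows(rows)
}

#' High-quality SNP filter
#'
#' Keeps biallelic sites whose cohort-minor-allele read support strictly
#' exceeds `min_minor_reads` and whose call integrity strictly exceeds
#' `min_integrity`. Sites at either boundary are removed.
#'
#' @param cohort A [snp_cohort()] with allele depths.
#' @param min_minor_reads Read-support threshold (strict).
#' @param min_integrity Integrity threshold (strict).
#' @param minor_reads_scope See [site_qc()].
#' @param use_read_support Set `FALSE` to filter on integrity alone when the
#'   VCF carries no AD field.
#' @return A list: `cohort` (surviving sites, input order) and `qc` (the full
#'   [site_qc()] table with a logical `kept` column).
#' @export
filter_high_quality <- function(cohort, min_minor_reads = 3,
                                min_integrity = 0.85,
                                minor_reads_scope = c("cohort", "per_sample"),
                                use_read_support = TRUE) {
  minor_reads_scope <- match.arg(minor_reads_scope)
  if (use_read_support && is.null(cohort$ad)) {
    abort(paste0("filter_high_quality: cohort has no allele depths (AD); ",
                 "pass use_read_support = FALSE to filter on integrity only"))
  }
  qc <- site_qc(cohort, minor_reads_scope)
  keep <- !cohort$sites$multiallelic & qc$integrity > min_integrity
  if (use_read_support) {
    keep <- keep & !is.na(qc$minor_reads) & qc$minor_reads > min_minor_reads
  }
  qc$kept <- keep
  inform(sprintf("filter_high_quality: kept %d / %d sites", sum(keep),
                 n_sites(cohort)))
  list(cohort = subset_sites(cohort, keep), qc = qc)
}

## 0-based half-open tiling of contigs
tile_windows <- function(contigs, size) {
  if (length(contigs) == 0) abort("no contig lengths known")
  if (any(is.na(contigs))) {
    abort(paste0("unknown contig length(s): ",
                 paste(names(contigs)[is.na(contigs)], collapse = ", ")))
  }
  bind_rows(purrr::map(names(contigs), function(cn) {
    starts <- seq(0, max(contigs[[cn]] - 1, 0), by = size)
    tibble(chrom = cn, start = starts,
           end = pmin(starts + size, contigs[[cn]]))
  }))
}

#' SNP density in fixed-size bins
#'
#' Counts variants in non-overlapping bins tiling every contig. The final
#' partial bin of a contig is kept and counted like any other. Bins are
#' reported with 0-based half-open coordinates.
#'
#' @param cohort A [snp_cohort()] whose contig lengths are known (from the
#'   VCF header or supplied via `contigs`).
#' @param bin Bin size in bases (default 1 Mb).
#' @param contigs Optional named vector of contig lengths overriding the
#'   cohort's.
#' @return A tibble `chrom`, `start`, `end`, `snp_count`.
#' @export
snp_density <- function(cohort, bin = 1e6, contigs = NULL) {
  contigs <- contigs %||% cohort$contigs
  win <- tile_windows(contigs, bin)
  unknown <- setdiff(unique(cohort$sites$chrom), names(contigs))
  if (length(unknown) > 0) {
    abort(paste0("snp_density: variants on unknown contig(s): ",
                 paste(unknown, collapse = ", ")))
  }
  win$snp_count <- 0L
  if (n_sites(cohort) > 0) {
    key_w <- paste(win$chrom, win$start %/% bin)
    hits <- table(paste(cohort$sites$chrom, (cohort$sites$pos - 1L) %/% bin))
    idx <- match(names(hits), key_w)
    if (anyNA(idx)) {
      abort("snp_density: variant position beyond stated contig length")
    }
    win$snp_count[idx] <- as.integer(hits)
  }
  win
}

#' SNP-rich windows
#'
#' Tiles contigs with fixed windows, ranks windows by SNP count across all
#' contigs, and flags the top `top_frac` fraction (at least
#' `ceiling(top_frac * n_windows)` windows) as SNP-rich. Windows tied with
#' the cutoff count are all flagged; empty windows are never flagged.
#'
#' @inheritParams snp_density
#' @param window Window size in bases (default 100 kb).
#' @param top_frac Fraction of windows to flag (default 0.01).
#' @return The window tibble from [snp_density()] plus a logical `rich`
#'   column.
#' @export
snp_rich_regions <- function(cohort, window = 1e5, top_frac = 0.01,
                             contigs = NULL) {
  win <- snp_density(cohort, bin = window, contigs = contigs)
  n_top <- ceiling(top_frac * nrow(win))
  counts <- sort(win$snp_count, decreasing = TRUE)
  cutoff <- if (n_top >= 1) counts[n_top] else Inf
  win$rich <- win$snp_count >= cutoff & win$snp_count > 0
  n_tied <- sum(win$rich)
  if (n_tied > n_top) {
    inform(sprintf(
      "snp_rich_regions: %d windows tied at the cutoff count %d (top %d requested)",
      n_tied, cutoff, n_top))
  }
  win
}

#' Select assay-ready ("perfect") SNP candidates
#'
#' Applies the four marker-conversion criteria to an (already high-quality
#' filtered) biallelic cohort: (1) minor allele frequency strictly above
#' `maf_min`, computed from called genotypes counting each sample's allele
#' copies; (2) miss rate strictly below `miss_max`; (3) heterozygous-sample
#' fraction strictly below `het_max`; (4) no other variant record within
#' `flank_bp` bases (inclusive) on the same contig, the input cohort itself
#' serving as the variation catalogue. The criteria are independent, so the
#' surviving set does not depend on the order of application.
#'
#' @param cohort A [snp_cohort()].
#' @param maf_min,miss_max,het_max,flank_bp Thresholds (all strict).
#' @return A list: `candidates` (cohort of selected sites), `report` (one row
#'   per site with the QC metrics, per-criterion pass flags, and a
#'   `failed` string naming the criteria each rejected site failed).
#' @export
select_perfect_snps <- function(cohort, maf_min = 0.4, miss_max = 0.2,
                                het_max = 0.4, flank_bp = 100) {
  qc <- site_qc(cohort)
  pass_maf <- !is.na(qc$maf) & qc$maf > maf_min
  pass_miss <- qc$miss_rate < miss_max
  pass_het <- !is.na(qc$het_fraction) & qc$het_fraction < het_max
  pass_flank <- !has_flanking_variant(cohort$sites, flank_bp)
  biallelic <- !cohort$sites$multiallelic
  keep <- biallelic & pass_maf & pass_miss & pass_het & pass_flank
  failed <- purrr::pmap_chr(
    list(biallelic, pass_maf, pass_miss, pass_het, pass_flank),
    function(b, m, mi, h, f) {
      paste(c(if (!b) "multiallelic", if (!m) "maf", if (!mi) "miss_rate",
              if (!h) "heterozygosity", if (!f) "flanking_variant"),
            collapse = ";")
    })
  report <- qc %>%
    mutate(pass_maf = pass_maf, pass_miss = pass_miss, pass_het = pass_het,
           pass_flank = pass_flank, selected = keep, failed = failed)
  inform(sprintf("select_perfect_snps: %d / %d candidates", sum(keep),
                 n_sites(cohort)))
  list(candidates = subset_sites(cohort, keep), report = report)
}

## TRUE when another record lies within +/- flank_bp (inclusive), same contig
has_flanking_variant <- function(sites, flank_bp) {
  out <- logical(nrow(sites))
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    pos <- sort(sites$pos[idx])
    near <- vapply(sites$pos[idx], function(p) {
      any(pos != p & abs(pos - p) <= flank_bp) ||
        sum(pos == p) > 1L
    }, logical(1))
    out[idx] <- near
  }
  out
}
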