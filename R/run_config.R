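#' Pipeline run configuration
#'
#' Collects every tunable threshold of the marker-discovery and genotyping
#' pipeline in one validated list. Defaults are the values used throughout the
#' package: a cohort-minor-allele read support of more than 3 reads and a call
#' integrity above 85% for the high-quality SNP filter; MAF > 0.4,
#' miss rate < 0.2, heterozygous fraction < 0.4 and a variant-free flank of
#' 100 bp for assay-ready ("perfect") SNP selection; a PIC threshold of 0.6
#' for fingerprint loci; a posterior threshold of 0.6 and a peak threshold of
#' 1 for the dosage caller; 1 Mb density bins and 100 kb SNP-rich windows with
#' a top fraction of 1%.
#'
#' All comparisons against these thresholds are strict inequalities
#' (`> min_minor_reads`, `> min_integrity`, `> maf_min`, `< miss_max`,
#' `< het_max`, `> pic_threshold`).
#'
#' @param min_minor_reads Minimum cohort-wide read support for the minor
#'   allele (strictly exceeded to pass). Count of reads.
#' @param min_integrity Minimum fraction of samples with a genotype call
#'   (strictly exceeded to pass).
#' @param maf_min Minor allele frequency lower bound (strict).
#' @param miss_max Missing-call rate upper bound (strict).
#' @param het_max Heterozygous-sample fraction upper bound (strict).
#' @param flank_bp Flanking window, in bases, that must be free of any other
#'   variant for a perfect SNP (inclusive at both endpoints).
#' @param pic_threshold PIC lower bound (strict) for fingerprint loci.
#' @param posterior_threshold Minimum posterior probability (strict) for a
#'   dosage call to be assigned.
#' @param peak_threshold Largest mixture-component fraction above which a
#'   marker is flagged non-segregating; the default of 1 disables the flag.
#' @param density_bin Bin size in bases for SNP density.
#' @param rich_window Window size in bases for SNP-rich region detection.
#' @param rich_top_frac Fraction of highest-count windows flagged SNP-rich.
#' @param minor_reads_scope `"cohort"` sums minor-allele reads over all
#'   samples; `"per_sample"` requires a single sample to exceed the bound.
#' @param rng_seed Integer seed used by stochastic pipeline stages.
#'
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config()
#' cfg$maf_min
#' @export
run_config <- function(min_minor_reads = 3,
                       min_integrity = 0.85,
                       maf_min = 0.4,
                       miss_max = 0.2,
                       het_max = 0.4,
                       flank_bp = 100,
                       pic_threshold = 0.6,
                       posterior_threshold = 0.6,
                       peak_threshold = 1.0,
                       density_bin = 1e6,
                       rich_window = 1e5,
                       rich_top_frac = 0.01,
                       minor_reads_scope = c("cohort", "per_sample"),
                       rng_seed = 1L) {
  minor_reads_scope <- match.arg(minor_reads_scope)
  fracs <- c(min_integrity = min_integrity, maf_min = maf_min,
             miss_max = miss_max, het_max = het_max,
             pic_threshold = pic_threshold,
             posterior_threshold = posterior_threshold,
             rich_top_frac = rich_top_frac)
  if (any(fracs < 0 | fracs > 1)) {
    bad <- names(fracs)[fracs < 0 | fracs > 1]
    abort(paste0("run_config: fractions must lie in [0, 1]: ",
                 paste(bad, collapse = ", ")))
  }
  sizes <- c(flank_bp = flank_bp, density_bin = density_bin,
             rich_window = rich_window)
  if (any(sizes <= 0)) {
    abort("run_config: flank_bp, density_bin and rich_window must be positive")
  }
  if (min_minor_reads < 0) abort("run_config: min_minor_reads must be >= 0")
  structure(
    list(min_minor_reads = min_minor_reads,
         min_integrity = min_integrity,
         maf_min = maf_min,
         miss_max = miss_max,
         het_max = het_max,
         flank_bp = flank_bp,
         pic_threshold = pic_threshold,
         posterior_threshold = posterior_threshold,
         peak_threshold = peak_threshold,
         density_bin = density_bin,
         rich_window = rich_window,
         rich_top_frac = rich_top_frac,
         minor_reads_scope = minor_reads_scope,
         rng_seed = as.integer(rng_seed)),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
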