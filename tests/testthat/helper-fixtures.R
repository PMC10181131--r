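## run an expression with package progress messages silenced
quietly <- function(expr) suppressWarnings(suppressMessages(expr))

## minimal snp_cohort built in code: biallelic tetraploid sites with optional
## allele depths
toy_cohort <- function(gt, ad = NULL, chrom = "chr1",
                       pos = seq_len(nrow(gt)) * 1000L,
                       contigs = c(chr1 = 1e6)) {
  n_sites <- nrow(gt)
  sites <- tibble::tibble(chrom = rep_len(chrom, n_sites), pos = pos,
                          id = ".", ref = "A", alt = "C")
  samples <- colnames(gt) %||% paste0("s", seq_len(ncol(gt)))
  colnames(gt) <- samples
  snp_cohort(sites, gt, ad, samples, contigs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## uniform allele-depth list: every sample depth `dp`, ALT share by dosage
toy_ad <- function(gt, dp = 10L) {
  lapply(seq_len(nrow(gt)), function(i) {
    t(vapply(gt[i, ], function(g) {
      if (is.na(g) || grepl("\\.", g)) return(c(0L, 0L))
      a <- as.integer(strsplit(g, "/")[[1]])
      alt <- as.integer(round(dp * mean(a == 1L)))
      c(dp - alt, alt)
    }, integer(2)))
  })
}

## small dosage tibble from a plain matrix
toy_dosage <- function(m, samples = NULL) {
  samples <- samples %||% sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% sprintf("M%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample = samples), tibble::as_tibble(m))
}

## reference marker fixture, loaded once
ref_markers <- potato_reference_markers()
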