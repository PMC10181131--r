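#' SNP cohort container
#'
#' A lightweight container for a cohort of SNP sites: a site table plus
#' per-sample genotype strings and (optionally) per-sample allele read depths.
#' Positions are 1-based as in VCF; all internal window arithmetic elsewhere in
#' the package converts to 0-based half-open coordinates.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (comma-separated string for multiallelic sites).
#' @param gt Character matrix, sites x samples, of VCF genotype strings
#'   (ploidy 2 or 4, e.g. `"0/1"` or `"0/0/1/1"`; missing as `"./."` or `NA`).
#' @param ad Optional list (one element per site) of integer matrices,
#'   samples x alleles, of allele read depths; `NULL` when the source VCF
#'   carried no AD field.
#' @param samples Character vector of sample names.
#' @param contigs Named numeric vector of contig lengths (NA when unknown).
#'
#' @return An object of class `snp_cohort`.
#' @export
snp_cohort <- function(sites, gt, ad = NULL, samples = character(),
                       contigs = numeric()) {
  sites <- as_tibble(sites)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(sites))) {
    abort(paste0("snp_cohort: sites must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(sites) > 0 && any(sites$pos < 1)) {
    abort("snp_cohort: positions must be 1-based (pos >= 1)")
  }
  gt <- as.matrix(gt)
  if (nrow(sites) > 0) {
    stopifnot(nrow(gt) == nrow(sites), ncol(gt) == length(samples))
    if (!is.null(ad)) stopifnot(length(ad) == nrow(sites))
  }
  sites$multiallelic <- n_alt_alleles(sites$alt) > 1L
  structure(list(sites = sites, gt = gt, ad = ad,
                 samples = as.character(samples),
                 contigs = contigs),
            class = "snp_cohort")
}

n_alt_alleles <- function(alt) {
  if (length(alt) == 0) return(integer())
  out <- lengths(strsplit(ifelse(is.na(alt) | alt == ".", "", alt), ",",
                          fixed = TRUE))
  as.integer(out)
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat(sprintf("<snp_cohort> %d sites x %d samples (%d multiallelic)%s\n",
              nrow(x$sites), length(x$samples),
              sum(x$sites$multiallelic),
              if (is.null(x$ad)) ", no allele depths" else ""))
  if (nrow(x$sites) > 0) print(head(x$sites, 5))
  invisible(x)
}

#' @export
tidy.snp_cohort <- function(x, ...) x$sites

n_sites <- function(x) nrow(x$sites)

#' Subset a SNP cohort by site index
#'
#' @param cohort A [snp_cohort()].
#' @param idx Integer or logical index over sites.
#' @return A `snp_cohort` with the selected sites, input order preserved.
#' @export
subset_sites <- function(cohort, idx) {
  if (is.logical(idx)) idx <- which(idx)
  snp_cohort(cohort$sites[idx, setdiff(names(cohort$sites), "multiallelic")],
             cohort$gt[idx, , drop = FALSE],
             if (!is.null(cohort$ad)) cohort$ad[idx],
             cohort$samples, cohort$contigs)
}

#' Read a cohort VCF
#'
#' Reads a VCF 4.x file (plain text or gzip) into a [snp_cohort()]. Genotypes
#' (GT) are required; allele depths (AD) are used when present. Multiallelic
#' sites are preserved as-is. Contig lengths are taken from `##contig` header
#' lines when available.
#'
#' @param path Path to a VCF file.
#' @return A [snp_cohort()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("read_vcf: no such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  contigs <- parse_contig_meta(meta)
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    smp <- colnames(vcf@gt)
    smp <- smp[smp != "FORMAT"]
    inform(sprintf("read_vcf: %s: 0 records", basename(path)))
    return(snp_cohort(tibble(chrom = character(), pos = integer(),
                             id = character(), ref = character(),
                             alt = character()),
                      matrix(character(), 0, length(smp)),
                      NULL, smp, contigs))
  }
  sites <- tibble(chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]),
                  id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                  ref = fix[, "REF"],
                  alt = fix[, "ALT"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  has_ad <- any(grepl("AD", vcf@gt[, "FORMAT"], fixed = TRUE))
  ad <- NULL
  if (has_ad) {
    ad_chr <- vcfR::extract.gt(vcf, element = "AD")
    n_all <- 1L + n_alt_alleles(sites$alt)
    ad <- lapply(seq_len(nrow(sites)), function(i) {
      parse_ad_strings(ad_chr[i, ], n_all[i])
    })
  } else {
    warn(paste0("read_vcf: ", basename(path),
                " has no AD field; read-support filters are unavailable"))
  }
  inform(sprintf("read_vcf: %s: %d records, %d samples", basename(path),
                 nrow(sites), length(samples)))
  snp_cohort(sites, gt, ad, samples, contigs)
}

parse_contig_meta <- function(meta) {
  lines <- meta[grepl("^##contig=", meta)]
  if (length(lines) == 0) return(numeric())
  ids <- sub(".*ID=([^,>]+).*", "\\1", lines)
  lens <- ifelse(grepl("length=", lines),
                 as.numeric(sub(".*length=([0-9]+).*", "\\1", lines)), NA_real_)
  setNames(lens, ids)
}

parse_ad_strings <- function(x, n_alleles) {
  out <- matrix(0L, nrow = length(x), ncol = n_alleles,
                dimnames = list(names(x), NULL))
  ok <- !is.na(x) & x != "."
  if (any(ok)) {
    parts <- strsplit(x[ok], ",", fixed = TRUE)
    for (j in seq_along(parts)) {
      v <- suppressWarnings(as.integer(parts[[j]]))
      v[is.na(v)] <- 0L
      out[which(ok)[j], seq_len(min(length(v), n_alleles))] <-
        v[seq_len(min(length(v), n_alleles))]
    }
  }
  out
}

#' Write a cohort VCF
#'
#' Writes a [snp_cohort()] back to a plain-text VCF 4.2 file with GT and
#' (when present) AD per-sample fields.
#'
#' @param cohort A [snp_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tetrafinger")
  if (length(cohort$contigs) > 0) {
    hdr <- c(hdr, ifelse(
      is.na(cohort$contigs),
      sprintf("##contig=<ID=%s>", names(cohort$contigs)),
      sprintf("##contig=<ID=%s,length=%d>", names(cohort$contigs),
              as.integer(cohort$contigs))))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  has_ad <- !is.null(cohort$ad)
  if (has_ad) {
    hdr <- c(hdr, paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                         "Description=\"Allele read depths\">"))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", cohort$samples), collapse = "\t"))
  body <- character(0)
  if (n_sites(cohort) > 0) {
    fmt <- if (has_ad) "GT:AD" else "GT"
    body <- vapply(seq_len(n_sites(cohort)), function(i) {
      s <- cohort$sites[i, ]
      gt_i <- cohort$gt[i, ]
      gt_i[is.na(gt_i)] <- "./."
      cells <- gt_i
      if (has_ad) {
        ad_i <- apply(cohort$ad[[i]], 1, paste, collapse = ",")
        cells <- paste(gt_i, ad_i, sep = ":")
      }
      paste(c(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".", fmt,
              cells), collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  inform(sprintf("write_vcf: %s: %d records", basename(path),
                 n_sites(cohort)))
  invisible(path)
}

#' Read a reference genome FASTA
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A named character vector of upper-case sequences, one per contig.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) abort("read_genome: duplicate contig names")
  out <- setNames(toupper(as.character(seqs)), nm)
  if (any(nchar(out) == 0)) abort("read_genome: empty sequence")
  inform(sprintf("read_genome: %s: %d contigs", basename(path), length(out)))
  out
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

## -- genotype-string helpers ------------------------------------------------

gt_is_missing <- function(gt) {
  is.na(gt) | gt == "." | grepl("\\.", gt)
}

## allele indices per genotype string; NULL for missing
gt_alleles <- function(gt) {
  if (is.na(gt) || grepl("\\.", gt)) return(NULL)
  as.integer(strsplit(gt, "[/|]")[[1]])
}

## matrix row of genotype strings -> integer ALT-allele dosage (biallelic),
## scaled to tetraploid dosage 0..4 for diploid calls
gt_alt_dosage <- function(gt_row) {
  vapply(gt_row, function(g) {
    a <- gt_alleles(g)
    if (is.null(a)) return(NA_real_)
    d <- sum(a == 1L)
    if (length(a) == 2L) d * 2 else d
  }, numeric(1), USE.NAMES = FALSE)
}
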