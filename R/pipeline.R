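#' End-to-end marker discovery: cohort VCF to assay-ready SNPs
#'
#' Composes [read_vcf()], [filter_high_quality()], [partition_biallelic()]
#' and [select_perfect_snps()] under one configuration, writes the candidate
#' VCF and TSV reports when `out_dir` is given, and returns a run manifest
#' with per-stage record counts.
#'
#' @param vcf Path to the cohort VCF.
#' @param fasta Optional path to the reference FASTA (supplies contig
#'   lengths for the density stages when the VCF header lacks them).
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list: `candidates` ([snp_cohort()]), `report` (per-site
#'   criterion report), `qc` (high-quality filter QC), `density`,
#'   `rich_windows`, `manifest`.
#' @export
run_marker_discovery <- function(vcf, fasta = NULL, config = run_config(),
                                 out_dir = NULL) {
  cohort <- read_vcf(vcf)
  contigs <- cohort$contigs
  if (!is.null(fasta)) {
    genome <- read_genome(fasta)
    contigs <- setNames(nchar(genome), names(genome))
    cohort$contigs <- contigs
  }
  hq <- filter_high_quality(cohort,
                            min_minor_reads = config$min_minor_reads,
                            min_integrity = config$min_integrity,
                            minor_reads_scope = config$minor_reads_scope,
                            use_read_support = !is.null(cohort$ad))
  parts <- partition_biallelic(hq$cohort)
  perfect <- select_perfect_snps(parts$biallelic,
                                 maf_min = config$maf_min,
                                 miss_max = config$miss_max,
                                 het_max = config$het_max,
                                 flank_bp = config$flank_bp)
  density <- NULL
  rich <- NULL
  if (length(contigs) > 0 && !anyNA(contigs)) {
    density <- snp_density(cohort, bin = config$density_bin)
    rich <- snp_rich_regions(cohort, window = config$rich_window,
                             top_frac = config$rich_top_frac)
  }
  manifest <- list(
    config = unclass(config),
    inputs = c(vcf = unname(tools::md5sum(vcf)),
               fasta = if (!is.null(fasta)) unname(tools::md5sum(fasta))),
    counts = list(input_sites = n_sites(cohort),
                  high_quality = n_sites(hq$cohort),
                  biallelic = n_sites(parts$biallelic),
                  multiallelic = n_sites(parts$multiallelic),
                  perfect = n_sites(perfect$candidates)),
    version = as.character(utils::packageVersion("tetrafinger")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(perfect$candidates, file.path(out_dir, "perfect_snps.vcf"))
    readr::write_tsv(perfect$report, file.path(out_dir, "perfect_report.tsv"))
    readr::write_tsv(hq$qc, file.path(out_dir, "site_qc.tsv"))
    if (!is.null(density)) {
      readr::write_tsv(density, file.path(out_dir, "snp_density.tsv"))
      readr::write_tsv(rich, file.path(out_dir, "snp_rich_windows.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(candidates = perfect$candidates, report = perfect$report, qc = hq$qc,
       density = density, rich_windows = rich, manifest = manifest)
}

#' End-to-end genotype analysis: signals or dosages to identity report
#'
#' Composes dosage calling ([call_dosages()], when fluorescence signals are
#' supplied), [marker_stats()], [drop_monomorphic()],
#' [euclidean_distances()], [upgma()], [pca_scores()],
#' [select_fingerprint_loci()], [build_fingerprints()] and
#' [identify_varieties()].
#'
#' @param signals Optional signal tibble (`sample`, `marker`, `fam`, `hex`).
#' @param dosage Optional dosage tibble; exactly one of `signals` / `dosage`
#'   must be given.
#' @param names Optional `sample` to `variety` mapping for identity calls.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for the result tables, Newick
#'   tree and manifest.
#' @return A list: `dosage`, `stats`, `summary`, `kept` (post-monomorphic
#'   matrix), `distances`, `tree`, `pca`, `loci`, `fingerprints`,
#'   `identity`, `manifest`. With a single sample the distance, tree, PCA
#'   and identity stages are skipped with a warning.
#' @export
run_genotype_analysis <- function(signals = NULL, dosage = NULL,
                                  names = NULL, config = run_config(),
                                  out_dir = NULL) {
  if (is.null(signals) == is.null(dosage)) {
    abort("run_genotype_analysis: supply exactly one of signals or dosage")
  }
  calls <- NULL
  if (!is.null(signals)) {
    calls <- call_dosages(signals,
                          posterior_threshold = config$posterior_threshold,
                          peak_threshold = config$peak_threshold,
                          seed = config$rng_seed)
    dosage <- calls_to_matrix(calls)
  }
  stats <- marker_stats(dosage)
  summary <- summarize_markers(stats)
  kept <- drop_monomorphic(dosage, stats)
  loci <- select_fingerprint_loci(stats, config$pic_threshold)
  fingerprints <- build_fingerprints(dosage, loci)
  distances <- NULL; tree <- NULL; pca <- NULL; identity <- NULL
  if (nrow(dosage) >= 2 && length(dosage_markers(kept)) >= 1) {
    distances <- euclidean_distances(kept)
    if (!anyNA(distances$d)) {
      tree <- upgma(distances)
    } else {
      warn("run_genotype_analysis: missing pairwise distances; tree skipped")
    }
    pca <- pca_scores(kept, n_components = min(2, nrow(kept)))
    identity <- identify_varieties(fingerprints, distances, names)
  } else {
    warn(paste0("run_genotype_analysis: fewer than 2 samples or no ",
                "polymorphic markers; distance stages skipped"))
  }
  manifest <- list(
    config = unclass(config),
    counts = list(samples = nrow(dosage),
                  markers = length(dosage_markers(dosage)),
                  markers_kept = length(dosage_markers(kept)),
                  fingerprint_loci = length(loci),
                  synonym_pairs = if (!is.null(identity))
                    nrow(identity$synonyms) else NA,
                  homonym_pairs = if (!is.null(identity))
                    nrow(identity$homonyms) else NA),
    version = as.character(utils::packageVersion("tetrafinger")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dosage_matrix(dosage, file.path(out_dir, "dosages.tsv"))
    readr::write_tsv(stats, file.path(out_dir, "marker_stats.tsv"))
    readr::write_tsv(as_tibble(fingerprints),
                     file.path(out_dir, "fingerprints.tsv"))
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "upgma.nwk"))
    if (!is.null(identity)) {
      jsonlite::write_json(lapply(unclass(identity), as.data.frame),
                           file.path(out_dir, "identity.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(calls = calls, dosage = dosage, stats = stats, summary = summary,
       kept = kept, distances = distances, tree = tree, pca = pca,
       loci = loci, fingerprints = fingerprints, identity = identity,
       manifest = manifest)
}
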