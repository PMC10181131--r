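#' Simulate a tetraploid dosage matrix under Hardy-Weinberg equilibrium
#'
#' Per marker `j`, an allele-B frequency `q_j` is drawn from `q_dist` and
#' each sample's dosage is drawn independently as `Binomial(4, q_j)` —
#' tetraploid Hardy-Weinberg sampling of allele copies. Cells are then set
#' missing independently with probability `missing_rate`.
#'
#' @param n_samples,n_markers Matrix dimensions (>= 1).
#' @param q_dist Allele-B frequency specification: a single number, a vector
#'   of length `n_markers`, or a function `f(n)` returning `n` frequencies.
#' @param missing_rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `dosage` (tibble, samples `S001`... by markers `M001`...)
#'   and `truth` (`sim_truth` with the drawn `q` and the pre-missingness
#'   `dosage_true` matrix).
#' @export
simulate_dosage_matrix <- function(n_samples, n_markers, q_dist = 0.5,
                                   missing_rate = 0, seed = 1L) {
  if (n_samples < 1 || n_markers < 1) {
    abort("simulate_dosage_matrix: n_samples and n_markers must be >= 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("simulate_dosage_matrix: missing_rate must be in [0, 1)")
  }
  set.seed(seed)
  q <- draw_q(q_dist, n_markers)
  d_true <- vapply(q, function(qj) rbinom(n_samples, 4, qj),
                   integer(n_samples))
  d_true <- matrix(d_true, nrow = n_samples)
  d_obs <- d_true
  if (missing_rate > 0) {
    d_obs[matrix(runif(length(d_obs)) < missing_rate,
                 nrow = n_samples)] <- NA_integer_
  }
  samples <- sprintf("S%03d", seq_len(n_samples))
  markers <- sprintf("M%03d", seq_len(n_markers))
  as_dosage <- function(m) {
    colnames(m) <- markers
    bind_cols(tibble(sample = samples), as_tibble(m))
  }
  truth <- new_sim_truth(q = setNames(q, markers),
                         dosage_true = as_dosage(d_true), seed = seed)
  list(dosage = as_dosage(d_obs), truth = truth)
}

draw_q <- function(q_dist, n) {
  if (is.function(q_dist)) {
    q <- q_dist(n)
  } else if (is.numeric(q_dist) && length(q_dist) %in% c(1L, n)) {
    q <- rep_len(q_dist, n)
  } else {
    abort(paste0("invalid q_dist: supply a number, a vector of length ",
                 "n_markers, or a function(n)"))
  }
  if (any(q < 0 | q > 1)) abort("q_dist produced frequencies outside [0, 1]")
  q
}

new_sim_truth <- function(q = numeric(), dosage_true = NULL,
                          perfect_ids = character(),
                          synonym_pairs = NULL, homonym_groups = NULL,
                          seed = NA_integer_) {
  structure(list(q = q, dosage_true = dosage_true,
                 perfect_ids = perfect_ids,
                 synonym_pairs = synonym_pairs,
                 homonym_groups = homonym_groups, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>",
      if (!is.null(x$dosage_true)) sprintf("%dx%d dosage matrix;",
                                           nrow(x$dosage_true),
                                           ncol(x$dosage_true) - 1),
      sprintf("%d perfect ids;", length(x$perfect_ids)),
      sprintf("seed %d\n", x$seed))
  invisible(x)
}

#' Simulate two-channel fluorescence signals from a dosage matrix
#'
#' Emulates endpoint reads of a competitive allele-specific PCR assay: with
#' B dosage `d`, `FAM = gain_a * (4 - d) * exp(e1) + bg` and
#' `HEX = gain_b * d * exp(e2) + bg`, with `e ~ Normal(0, noise_sd^2)`
#' multiplicative log-normal noise and a small positive background `bg`
#' added to both channels so the signal ratio is defined (and strictly
#' inside (0, 1)) at dosages 0 and 4. Missing dosages yield near-background
#' signal in both channels.
#'
#' @param dosage Dosage tibble.
#' @param gain_a,gain_b Per-channel amplification gains (> 0).
#' @param noise_sd Log-scale noise standard deviation (> 0).
#' @param background Additive background as a fraction of `gain` (> 0).
#' @param seed Integer seed.
#' @return A signal tibble `sample`, `marker`, `fam`, `hex`.
#' @export
simulate_signals <- function(dosage, gain_a = 1, gain_b = 1,
                             noise_sd = 0.05, background = 0.02, seed = 1L) {
  check_dosage_tbl(dosage)
  if (noise_sd <= 0 || gain_a <= 0 || gain_b <= 0 || background <= 0) {
    abort("simulate_signals: gains, noise_sd and background must be > 0")
  }
  set.seed(seed)
  long <- tidyr::pivot_longer(dosage, -"sample", names_to = "marker",
                              values_to = "dosage")
  n <- nrow(long)
  d <- long$dosage
  a_copies <- ifelse(is.na(d), 0, 4 - d)
  b_copies <- ifelse(is.na(d), 0, d)
  long$fam <- gain_a * a_copies * exp(rnorm(n, 0, noise_sd)) +
    background * gain_a * exp(rnorm(n, 0, noise_sd))
  long$hex <- gain_b * b_copies * exp(rnorm(n, 0, noise_sd)) +
    background * gain_b * exp(rnorm(n, 0, noise_sd))
  long[, c("sample", "marker", "fam", "hex")]
}

#' Simulate a toy cohort VCF with planted assay-ready SNPs
#'
#' Emits a small two-contig genome and a cohort VCF in which a known subset
#' of sites satisfies all four marker-conversion criteria by construction
#' (realised MAF in (0.4, 0.5], miss rate below 0.2, heterozygous fraction
#' below 0.4, no other variant within the flanking window), a further subset
#' satisfies criteria 1-3 but has a companion variant planted within the
#' flank (flank violators), and the remaining sites violate at least one of
#' criteria 1-3 (low MAF, excess missingness, or excess heterozygosity).
#' Per-sample allele depths are Poisson(`mean_depth`) totals split
#' binomially by the sample's allele fraction; genotypes of background sites
#' with zero depth are missing, so low `mean_depth` drives sites below the
#' integrity bound of the high-quality filter.
#'
#' @param n_samples,n_sites Cohort dimensions.
#' @param planted_perfect Number of sites meeting all four criteria.
#' @param flank_violators Number of sites failing only the flank criterion;
#'   each consumes one additional background site as its companion, so
#'   `planted_perfect + 2 * flank_violators <= n_sites` is required.
#' @param mean_depth Mean per-sample read depth.
#' @param flank_bp Flank window the planted sites respect (default 100).
#' @param contig_length,n_contigs Toy genome geometry (default 2 x 100 kb).
#' @param dir Directory for the output files (created if needed).
#' @param seed Integer seed.
#' @return A list: `vcf` and `fasta` file paths, and `truth` (a `sim_truth`
#'   whose `perfect_ids` are `chrom:pos` keys of the planted perfect sites).
#' @export
simulate_cohort_vcf <- function(n_samples = 40, n_sites = 50,
                                planted_perfect = 5, flank_violators = 3,
                                mean_depth = 10, flank_bp = 100,
                                contig_length = 1e5, n_contigs = 2,
                                dir = tempfile("cohort"), seed = 1L) {
  if (planted_perfect + 2 * flank_violators > n_sites) {
    abort(paste0("simulate_cohort_vcf: need planted_perfect + 2 * ",
                 "flank_violators <= n_sites"))
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- setNames(rep(contig_length, n_contigs),
                      sprintf("contig%02d", seq_len(n_contigs)))
  genome <- vapply(contigs, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))

  ## place site "units" in slots spaced so distinct units never fall within
  ## flank_bp of one another; a violator unit holds two records
  n_units <- n_sites - flank_violators
  slot <- 2 * flank_bp + 60
  slots_per_contig <- floor((contig_length - slot) / slot)
  if (n_units > slots_per_contig * n_contigs) {
    abort("simulate_cohort_vcf: genome too short for the requested sites")
  }
  base_k <- n_units %/% n_contigs
  k_c <- base_k + (seq_len(n_contigs) <= n_units %% n_contigs)
  unit_contig <- rep(names(contigs), times = k_c)
  unit_slot <- unlist(lapply(k_c, function(k) sort(sample(slots_per_contig, k))))
  unit_pos <- unit_slot * slot + sample(10:40, n_units, replace = TRUE)

  roles <- c(rep("perfect", planted_perfect),
             rep("violator", flank_violators),
             rep("background", n_units - planted_perfect - flank_violators))
  roles <- sample(roles)

  records <- list()
  truth_ids <- character()
  for (u in seq_len(n_units)) {
    chrom <- unit_contig[u]
    pos <- unit_pos[u]
    ref <- substr(genome[[chrom]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    if (roles[u] == "background") {
      rec <- sim_site_background(n_samples, mean_depth)
      records[[length(records) + 1]] <- c(list(chrom = chrom, pos = pos,
                                               ref = ref, alt = alt), rec)
    } else {
      rec <- sim_site_perfect(n_samples, mean_depth)
      records[[length(records) + 1]] <- c(list(chrom = chrom, pos = pos,
                                               ref = ref, alt = alt), rec)
      if (roles[u] == "perfect") {
        truth_ids <- c(truth_ids, paste0(chrom, ":", pos))
      } else {
        ## companion junk variant inside the flank window
        cpos <- pos + sample(20:flank_bp, 1)
        cref <- substr(genome[[chrom]], cpos, cpos)
        calt <- sample(setdiff(c("A", "C", "G", "T"), cref), 1)
        crec <- sim_site_background(n_samples, mean_depth)
        records[[length(records) + 1]] <- c(list(chrom = chrom, pos = cpos,
                                                 ref = cref, alt = calt),
                                            crec)
      }
    }
  }
  ord <- order(vapply(records, `[[`, character(1), "chrom"),
               vapply(records, `[[`, numeric(1), "pos"))
  records <- records[ord]

  samples <- sprintf("S%03d", seq_len(n_samples))
  sites <- bind_rows(purrr::map(records, function(r) {
    tibble(chrom = r$chrom, pos = as.integer(r$pos), id = ".",
           ref = r$ref, alt = r$alt)
  }))
  gt <- do.call(rbind, purrr::map(records, "gt"))
  colnames(gt) <- samples
  ad <- purrr::map(records, "ad")
  cohort <- snp_cohort(sites, gt, ad, samples, contigs)

  fasta <- file.path(dir, "genome.fa")
  vcf <- file.path(dir, "cohort.vcf")
  write_genome(genome, fasta)
  write_vcf(cohort, vcf)
  truth <- new_sim_truth(perfect_ids = sort(truth_ids), seed = seed)
  list(vcf = vcf, fasta = fasta, truth = truth, cohort = cohort)
}

## genotype block meeting MAF/miss/het criteria with certainty:
## duplex fraction ~0.3 (heterozygous), remainder split between nulliplex and
## quadruplex so the realised B frequency lies in (0.4, 0.5]
sim_site_perfect <- function(n_samples, mean_depth) {
  n_miss <- floor(runif(1, 0, 0.15) * n_samples)
  nc <- n_samples - n_miss
  n_het <- floor(0.3 * nc)
  target_b <- runif(1, 0.41, 0.49)
  n4 <- round((target_b * 4 * nc - 2 * n_het) / 4)
  ## nudge until the realised frequency is strictly inside (0.4, 0.5]
  repeat {
    f <- (2 * n_het + 4 * n4) / (4 * nc)
    if (f > 0.4 && f <= 0.5) break
    n4 <- n4 + ifelse(f <= 0.4, 1, -1)
  }
  n0 <- nc - n_het - n4
  stopifnot(n0 >= 0)
  dosage <- sample(rep(c(0L, 2L, 4L), times = c(n0, n_het, n4)))
  gt_strings <- c("0/0/0/0", NA, "0/0/1/1", NA, "1/1/1/1")
  gt <- c(gt_strings[dosage + 1L], rep(NA_character_, n_miss))
  gt <- sample(gt)
  sim_depths(gt, n_samples, mean_depth, force_called_depth = TRUE)
}

## background junk: violates at least one of the MAF / miss / het criteria
sim_site_background <- function(n_samples, mean_depth) {
  mode <- sample(c("low_maf", "high_miss", "high_het"), 1)
  gt <- switch(mode,
    low_maf = {
      n_alt <- max(1L, round(0.05 * n_samples))
      sample(c(rep("0/0/0/1", n_alt),
               rep("0/0/0/0", n_samples - n_alt)))
    },
    high_miss = {
      n_miss <- ceiling(runif(1, 0.3, 0.5) * n_samples)
      sample(c(rep(NA_character_, n_miss),
               rep(c("0/0/1/1", "0/0/0/0", "1/1/1/1"),
                   length.out = n_samples - n_miss)))
    },
    high_het = {
      sample(c("0/0/0/1", "0/0/1/1", "0/1/1/1"), n_samples, replace = TRUE)
    })
  sim_depths(gt, n_samples, mean_depth, force_called_depth = FALSE)
}

## depths: Poisson totals split binomially by the genotype's ALT fraction;
## missing genotypes carry zero depth. When force_called_depth, called
## samples get depth >= 1 so planted sites keep their integrity guarantee.
sim_depths <- function(gt, n_samples, mean_depth, force_called_depth) {
  depth <- rpois(n_samples, mean_depth)
  called <- !is.na(gt)
  if (force_called_depth) depth[called] <- pmax(depth[called], 1L)
  gt[called & depth == 0] <- NA_character_
  called <- !is.na(gt)
  depth[!called] <- 0L
  alt_frac <- vapply(gt, function(g) {
    if (is.na(g)) return(0)
    a <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
    mean(a == 1L)
  }, numeric(1), USE.NAMES = FALSE)
  alt_reads <- rbinom(n_samples, depth, alt_frac)
  ad <- cbind(depth - alt_reads, alt_reads)
  list(gt = gt, ad = ad)
}

#' Plant synonym and homonym cases in a dosage matrix
#'
#' Synonym: an existing sample's dosage row is duplicated under a new sample
#' id and a new variety name (genotype distance 0, names differ). Homonym:
#' an existing variety name is reassigned to a genotypically distinct
#' sample, so one name labels two samples at distance > 0.
#'
#' @param dosage Dosage tibble.
#' @param names Optional tibble `sample`, `variety`; defaults to variety =
#'   sample id.
#' @param n_synonyms,n_homonyms Number of planted cases;
#'   `2 * (n_synonyms + n_homonyms)` distinct source samples are required.
#' @param seed Integer seed.
#' @return A list: `dosage` (augmented), `names` (updated mapping), `truth`
#'   (`sim_truth` whose `synonym_pairs` is a tibble of variety-name pairs and
#'   `homonym_groups` a tibble of name / sample-id groups).
#' @export
inject_identity_cases <- function(dosage, names = NULL, n_synonyms = 0,
                                  n_homonyms = 0, seed = 1L) {
  check_dosage_tbl(dosage)
  if (is.null(names)) {
    names <- tibble(sample = dosage$sample, variety = dosage$sample)
  }
  n <- nrow(dosage)
  if (2 * (n_synonyms + n_homonyms) > n) {
    abort("inject_identity_cases: more cases requested than samples support")
  }
  set.seed(seed)
  pool <- sample(dosage$sample, 2 * (n_synonyms + n_homonyms))
  syn_src <- pool[seq_len(n_synonyms)]
  hom_pairs <- matrix(pool[n_synonyms + seq_len(2 * n_homonyms)], ncol = 2)
  syn <- list()
  for (i in seq_len(n_synonyms)) {
    src <- syn_src[i]
    new_id <- sprintf("SYN%02d", i)
    new_var <- sprintf("SynonymVariety%02d", i)
    row <- dosage[dosage$sample == src, ]
    row$sample <- new_id
    dosage <- bind_rows(dosage, row)
    names <- bind_rows(names, tibble(sample = new_id, variety = new_var))
    syn[[i]] <- tibble(variety_a = names$variety[names$sample == src],
                       sample_a = src, variety_b = new_var,
                       sample_b = new_id)
  }
  hom <- list()
  for (i in seq_len(n_homonyms)) {
    a <- hom_pairs[i, 1]; b <- hom_pairs[i, 2]
    va <- names$variety[names$sample == a]
    ## ensure the two columns actually differ; monomorphic collisions are
    ## vanishingly rare at realistic marker counts but guard anyway
    da <- unlist(dosage[dosage$sample == a, -1])
    db <- unlist(dosage[dosage$sample == b, -1])
    ok <- !is.na(da) & !is.na(db)
    if (!any(da[ok] != db[ok])) {
      abort("inject_identity_cases: drawn homonym pair is not distinct; reseed")
    }
    names$variety[names$sample == b] <- va
    hom[[i]] <- tibble(variety = va, sample_a = a, sample_b = b)
  }
  truth <- new_sim_truth(
    synonym_pairs = if (n_synonyms > 0) bind_rows(syn) else NULL,
    homonym_groups = if (n_homonyms > 0) bind_rows(hom) else NULL,
    seed = seed)
  list(dosage = dosage, names = names, truth = truth)
}
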