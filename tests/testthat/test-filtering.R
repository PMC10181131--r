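test_that("biallelic partition splits by ALT allele count and keeps order", {
  gt <- matrix("0/0/0/1", 10, 4)
  co <- toy_cohort(gt)
  co$sites$alt[c(2, 5, 9)] <- "C,T"
  co$sites$multiallelic <- tetrafinger:::n_alt_alleles(co$sites$alt) > 1
  parts <- partition_biallelic(co)
  expect_equal(nrow(parts$biallelic$sites), 7)
  expect_equal(nrow(parts$multiallelic$sites), 3)
  expect_equal(parts$multiallelic$sites$pos, co$sites$pos[c(2, 5, 9)])
  expect_equal(sort(c(parts$biallelic$sites$pos, parts$multiallelic$sites$pos)),
               co$sites$pos)

  empty <- subset_sites(co, integer(0))
  parts0 <- partition_biallelic(empty)
  expect_equal(nrow(parts0$biallelic$sites), 0)
  expect_equal(nrow(parts0$multiallelic$sites), 0)
})

test_that("high-quality filter applies both criteria as strict inequalities", {
  ## 20 samples; site 1: integrity exactly 0.85 (17/20) -> removed
  ## site 2: integrity 0.90, minor reads 4 -> kept
  ## site 3: integrity 0.90, minor reads exactly 3 -> removed
  n <- 20
  gt <- rbind(c(rep("0/0/1/1", 17), rep(NA, 3)),
              c(rep("0/0/0/0", 17), "0/0/0/1", rep(NA, 2)),
              c(rep("0/0/0/0", 17), "0/0/0/1", rep(NA, 2)))
  ad_rows <- function(...) do.call(rbind, list(...))
  ad <- list(
    t(vapply(gt[1, ], function(g) if (is.na(g)) c(0L, 0L) else c(5L, 5L),
             integer(2))),
    ad_rows(matrix(rep(c(8L, 0L), 17), ncol = 2, byrow = TRUE),
            c(4L, 4L), c(0L, 0L), c(0L, 0L)),
    ad_rows(matrix(rep(c(8L, 0L), 17), ncol = 2, byrow = TRUE),
            c(5L, 3L), c(0L, 0L), c(0L, 0L)))
  co <- toy_cohort(gt, ad)
  res <- quietly(filter_high_quality(co))
  expect_equal(res$qc$kept, c(FALSE, TRUE, FALSE))
  expect_equal(res$cohort$sites$pos, co$sites$pos[2])
  expect_equal(res$qc$integrity[1], 0.85)
  expect_equal(res$qc$minor_reads[3], 3)
})

test_that("missing depth data triggers an instructive error", {
  co <- toy_cohort(matrix("0/0/0/1", 2, 3))
  expect_error(filter_high_quality(co), "use_read_support")
  res <- quietly(filter_high_quality(co, use_read_support = FALSE))
  expect_equal(sum(res$qc$kept), 2)
})

test_that("low-depth cohorts match a brute-force filter oracle", {
  sim <- quietly(simulate_cohort_vcf(n_samples = 30, n_sites = 40,
                                     planted_perfect = 4,
                                     flank_violators = 2, mean_depth = 1,
                                     seed = 13, dir = withr::local_tempdir()))
  co <- quietly(read_vcf(sim$vcf))
  res <- quietly(filter_high_quality(co))
  ## independent re-application, site by site, straight from the definitions
  expected <- vapply(seq_len(nrow(co$sites)), function(i) {
    gts <- co$gt[i, ]
    called <- !is.na(gts) & !grepl("\\.", gts)
    integrity <- mean(called)
    minor <- min(colSums(co$ad[[i]]))
    length(strsplit(co$sites$alt[i], ",")[[1]]) == 1 &&
      integrity > 0.85 && minor > 3
  }, logical(1))
  expect_equal(res$qc$kept, expected)
  expect_true(any(!expected))  # depth 1 must sink some sites
})

test_that("snp density tallies per bin with half-open windows", {
  co <- toy_cohort(matrix("0/1", 1, 2), pos = 1L,
                   contigs = c(chr1 = 10e6))
  dens <- snp_density(co, bin = 1e6)
  expect_equal(nrow(dens), 10)
  expect_equal(dens$snp_count, c(1, rep(0, 9)))

  ## uniform: 100 variants, 10 per bin
  co2 <- toy_cohort(matrix("0/1", 100, 2),
                    pos = as.integer(seq(1, 10e6, length.out = 100)),
                    contigs = c(chr1 = 10e6))
  dens2 <- snp_density(co2, bin = 1e6)
  expect_equal(dens2$snp_count, rep(10, 10))

  ## random positions against a brute-force tally
  set.seed(4)
  pos <- sort(sample.int(2e6, 300))
  co3 <- toy_cohort(matrix("0/1", 300, 2), pos = as.integer(pos),
                    contigs = c(chr1 = 2e6))
  dens3 <- snp_density(co3, bin = 1e5)
  brute <- vapply(seq(0, 2e6 - 1e5, by = 1e5), function(s) {
    sum(pos - 1 >= s & pos - 1 < s + 1e5)
  }, numeric(1))
  expect_equal(dens3$snp_count, as.integer(brute))
  expect_equal(sum(dens3$snp_count), 300)
})

test_that("variants on unknown contigs are an error", {
  co <- toy_cohort(matrix("0/1", 1, 2), chrom = "chrX",
                   contigs = c(chr1 = 1e6))
  expect_error(snp_density(co), "unknown contig")
})

test_that("snp-rich windows flag the top fraction with tie inclusion", {
  ## planted hotspot: one window with 10x background density
  set.seed(8)
  bg_pos <- sample.int(1e6, 200)
  hot_pos <- 300000L + sample.int(1e5, 200)
  pos <- sort(unique(c(bg_pos, hot_pos)))
  co <- toy_cohort(matrix("0/1", length(pos), 2), pos = as.integer(pos),
                   contigs = c(chr1 = 1e6))
  rich <- quietly(snp_rich_regions(co, window = 1e5, top_frac = 0.01))
  expect_equal(sum(rich$rich), 1)
  expect_equal(rich$start[rich$rich], 3e5)

  ## all windows tied -> all flagged
  co2 <- toy_cohort(matrix("0/1", 10, 2),
                    pos = as.integer(seq(5e4, 9.5e5, by = 1e5)),
                    contigs = c(chr1 = 1e6))
  expect_message(rich2 <- snp_rich_regions(co2, window = 1e5,
                                           top_frac = 0.01), "tied")
  expect_true(all(rich2$rich))

  ## zero variants -> nothing flagged
  co3 <- subset_sites(co2, integer(0))
  co3$contigs <- c(chr1 = 1e6)
  rich3 <- quietly(snp_rich_regions(co3, window = 1e5))
  expect_false(any(rich3$rich))
})

test_that("perfect-SNP criteria are strict and mutually exclusive on flanks", {
  ## two sites 50 bp apart, both passing criteria 1-3 -> both flank-rejected
  gt_pass <- c(rep("0/0/0/0", 8), rep("0/0/1/1", 6), rep("1/1/1/1", 6))
  co <- toy_cohort(rbind(gt_pass, gt_pass), pos = c(1000L, 1050L))
  res <- quietly(select_perfect_snps(co))
  expect_equal(nrow(res$candidates$sites), 0)
  expect_true(all(grepl("flanking_variant", res$report$failed)))
  expect_true(all(res$report$pass_maf & res$report$pass_miss &
                    res$report$pass_het))

  ## maf exactly at the bound is rejected
  gt_exact <- c(rep("1/1/1/1", 4), rep("0/0/0/0", 6))  # B freq 16/40 = 0.4
  co2 <- toy_cohort(matrix(gt_exact, nrow = 1), pos = 5000L)
  res2 <- quietly(select_perfect_snps(co2))
  expect_equal(tetrafinger::site_qc(co2)$maf, 0.4)
  expect_false(res2$report$selected)
  expect_match(res2$report$failed, "maf")
})

test_that("planted perfect SNPs are recovered exactly", {
  sim <- quietly(simulate_cohort_vcf(n_samples = 40, n_sites = 50,
                                     planted_perfect = 5,
                                     flank_violators = 3, mean_depth = 10,
                                     seed = 11, dir = withr::local_tempdir()))
  co <- quietly(read_vcf(sim$vcf))
  res <- quietly(select_perfect_snps(co))
  got <- paste0(res$candidates$sites$chrom, ":", res$candidates$sites$pos)
  expect_setequal(got, sim$truth$perfect_ids)
  ## every rejected site names at least one failed criterion
  rejected <- res$report[!res$report$selected, ]
  expect_true(all(nchar(rejected$failed) > 0))
})

test_that("the criteria commute: any application order gives the same set", {
  sim <- quietly(simulate_cohort_vcf(n_samples = 30, n_sites = 40,
                                     planted_perfect = 4,
                                     flank_violators = 2, seed = 17,
                                     dir = withr::local_tempdir()))
  co <- quietly(read_vcf(sim$vcf))
  res <- quietly(select_perfect_snps(co))
  flags <- res$report[, c("pass_maf", "pass_miss", "pass_het", "pass_flank")]
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    surviving <- rep(TRUE, nrow(flags))
    for (j in perm) surviving <- surviving & flags[[j]]
    expect_equal(surviving & !co$sites$multiallelic, res$report$selected)
  }
  ## selection is a subset of the input
  expect_true(all(res$candidates$sites$pos %in% co$sites$pos))
})
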