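test_that("fingerprint loci are the 21 markers with PIC strictly above 0.6", {
  st <- marker_stats_from_counts(ref_markers)
  loci <- select_fingerprint_loci(st, 0.6)
  expect_length(loci, 21)
  expect_true(all(st$pic[match(loci, st$marker)] > 0.6))
  ## the marker printed at 0.60 sits just below the strict bound
  expect_false("StSNP80" %in% loci)
  expect_true("StSNP54" %in% loci)
  ## descending-PIC deterministic order
  expect_equal(loci, loci[order(-st$pic[match(loci, st$marker)],
                                loci, method = "radix")])
  expect_length(select_fingerprint_loci(st, 1.0), 0)
  all_poly <- select_fingerprint_loci(st, 0)
  expect_setequal(all_poly, st$marker[st$pic > 0])
})

test_that("raising the PIC threshold never adds loci", {
  st <- marker_stats_from_counts(ref_markers)
  sizes <- vapply(seq(0, 0.8, by = 0.1),
                  function(th) length(select_fingerprint_loci(st, th)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("fingerprint codes serialise dosages with N for missing", {
  dm <- toy_dosage(matrix(c(0L, 0L, 4L, 4L, 2L, NA), 2),
                   samples = c("a", "b"))
  fp <- build_fingerprints(dm, c("M01", "M02", "M03"))
  expect_equal(fp$code, c("042", "04N"))
  ## duplicated sample rows give identical codes
  dm2 <- dplyr::bind_rows(dm, dplyr::mutate(dm[1, ], sample = "c"))
  fp2 <- build_fingerprints(dm2, c("M01", "M02", "M03"))
  expect_equal(fp2$code[3], fp2$code[1])
  expect_error(build_fingerprints(dm, "M99"), "unknown locus")
})

test_that("planted synonyms and homonyms are recovered exactly", {
  sim <- simulate_dosage_matrix(50, 69,
                                q_dist = function(n) runif(n, 0.15, 0.85),
                                missing_rate = 0.01, seed = 61)
  inj <- inject_identity_cases(sim$dosage, n_synonyms = 3, n_homonyms = 2,
                               seed = 62)
  st <- marker_stats(inj$dosage)
  kept <- quietly(drop_monomorphic(inj$dosage, st))
  dist <- euclidean_distances(kept)
  fp <- build_fingerprints(inj$dosage, select_fingerprint_loci(st))
  rep <- quietly(identify_varieties(fp, dist, inj$names))

  truth_syn <- inj$truth$synonym_pairs
  expect_equal(nrow(rep$synonyms), 3)
  got_syn <- apply(rep$synonyms[, c("sample_a", "sample_b")], 1,
                   function(p) paste(sort(p), collapse = "|"))
  want_syn <- apply(truth_syn[, c("sample_a", "sample_b")], 1,
                    function(p) paste(sort(p), collapse = "|"))
  expect_setequal(got_syn, want_syn)

  truth_hom <- inj$truth$homonym_groups
  expect_equal(nrow(rep$homonyms), 2)
  got_hom <- apply(rep$homonyms[, c("sample_a", "sample_b")], 1,
                   function(p) paste(sort(p), collapse = "|"))
  want_hom <- apply(truth_hom[, c("sample_a", "sample_b")], 1,
                    function(p) paste(sort(p), collapse = "|"))
  expect_setequal(got_hom, want_hom)
  expect_equal(nrow(rep$unresolved), 0)
})

test_that("unique distinct samples yield an empty identity report", {
  sim <- simulate_dosage_matrix(20, 40, q_dist = 0.5, seed = 71)
  st <- marker_stats(sim$dosage)
  kept <- quietly(drop_monomorphic(sim$dosage, st))
  dist <- euclidean_distances(kept)
  fp <- build_fingerprints(sim$dosage, select_fingerprint_loci(st))
  rep <- quietly(identify_varieties(fp, dist))
  expect_equal(nrow(rep$synonyms), 0)
  expect_equal(nrow(rep$homonyms), 0)
})

test_that("concordant same-name duplicates are replicates, not homonyms", {
  sim <- simulate_dosage_matrix(10, 30, q_dist = 0.5, seed = 81)
  dup <- sim$dosage[1, ]
  dup$sample <- "S001b"
  dm <- dplyr::bind_rows(sim$dosage, dup)
  names <- tibble::tibble(sample = dm$sample,
                          variety = c(dm$sample[1:10], dm$sample[1]))
  st <- marker_stats(dm)
  kept <- quietly(drop_monomorphic(dm, st))
  dist <- euclidean_distances(kept)
  fp <- build_fingerprints(dm, select_fingerprint_loci(st))
  rep <- quietly(identify_varieties(fp, dist, names))
  expect_equal(nrow(rep$replicates), 1)
  expect_equal(nrow(rep$synonyms), 0)
  expect_equal(nrow(rep$homonyms), 0)
})

test_that("distance-0 pairs with too few shared loci stay unresolved", {
  ## two samples overlap at only 3 informative loci, identical there
  m <- rbind(c(0L, 1L, 2L, rep(NA_integer_, 7)),
             c(0L, 1L, 2L, rep(NA_integer_, 7)),
             c(4L, 3L, 0L, rep(2L, 7)))
  dm <- toy_dosage(m, samples = c("a", "b", "c"))
  st <- marker_stats(dm)
  fp <- build_fingerprints(dm, dosage_markers(dm))
  dist <- euclidean_distances(dm)
  rep <- quietly(identify_varieties(fp, dist, min_shared_loci = 5))
  expect_equal(nrow(rep$synonyms), 0)
  expect_equal(nrow(rep$unresolved), 1)
  expect_equal(sort(unlist(rep$unresolved[1, c("sample_a", "sample_b")],
                           use.names = FALSE)), c("a", "b"))
})
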