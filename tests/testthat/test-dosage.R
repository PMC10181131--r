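test_that("signal ratio handles symmetric, zero and uncallable records", {
  expect_equal(signal_ratio(7, 7), 0.5)
  expect_equal(signal_ratio(5, 0), 0)
  expect_equal(signal_ratio(100, 300), 0.75)
  expect_true(is.na(signal_ratio(0, 0)))
  expect_equal(ratio_transform(0.5), asin(sqrt(0.5)))
})

test_that("identical ratios collapse to one component called with certainty", {
  sig <- tibble::tibble(sample = sprintf("s%02d", 1:12), marker = "M1",
                        fam = 50, hex = 50)
  calls <- quietly(call_dosages(sig, seed = 1))
  expect_equal(glance(calls)$k, 1)
  expect_true(all(calls$calls$posterior == 1))
  expect_length(unique(calls$calls$dosage), 1)
  expect_false(anyNA(calls$calls$dosage))
})

test_that("markers with too few callable records are reported uncalled", {
  sig <- tibble::tibble(sample = sprintf("s%d", 1:5), marker = "M1",
                        fam = c(10, 20, 0, 5, 8), hex = c(1, 2, 0, 30, 4))
  calls <- quietly(call_dosages(sig, min_callable = 10, seed = 1))
  expect_false(glance(calls)$called)
  expect_true(all(is.na(calls$calls$dosage)))
})

test_that("simulated five-class signals are recovered above 99% accuracy", {
  truth <- rep(0:4, each = 100)
  dm <- toy_dosage(matrix(truth, ncol = 1))
  sig <- simulate_signals(dm, noise_sd = 0.05, seed = 21)
  calls <- quietly(call_dosages(sig, seed = 22))
  called <- calls$calls$dosage
  ok <- !is.na(called)
  expect_gt(mean(ok), 0.95)
  expect_gt(mean(called[ok] == truth[ok]), 0.99)
  ## any confusion is between adjacent dosage classes only
  expect_lte(max(abs(called[ok] - truth[ok])), 1)
  ## fitted class means recover the empirical class centres
  y <- ratio_transform(signal_ratio(sig$fam, sig$hex))
  centres <- tapply(y, truth, mean)
  comp <- tidy(calls)
  expect_equal(nrow(comp), 5)
  expect_lt(max(abs(comp$mean - centres[as.character(comp$dosage)])), 0.02)
})

test_that("component means are increasing and posteriors normalised", {
  sim <- simulate_dosage_matrix(150, 4,
                                q_dist = function(n) runif(n, 0.2, 0.8),
                                seed = 31)
  sig <- simulate_signals(sim$dosage, seed = 32)
  calls <- quietly(call_dosages(sig, seed = 33))
  comp <- tidy(calls)
  for (m in unique(comp$marker)) {
    mu <- comp$mean[comp$marker == m]
    expect_true(all(diff(mu) > 0))
    d <- comp$dosage[comp$marker == m]
    expect_true(all(diff(d) > 0))
  }
  ## posteriors over components sum to one
  fit <- attr(calls$models[[1]], "fit")
  y <- seq(0.1, 1.4, by = 0.1)
  post <- tetrafinger:::mixture_posteriors(y, fit$w, fit$mu, fit$sigma)
  expect_equal(rowSums(post), rep(1, length(y)))
})

test_that("a sample midway between two equal components has posterior 1/2", {
  post <- tetrafinger:::mixture_posteriors(0.5, w = c(0.5, 0.5),
                                           mu = c(0.3, 0.7), sigma = 0.05)
  expect_equal(as.numeric(post), c(0.5, 0.5))
  ## at the default threshold of 0.6 such a sample stays uncalled
  expect_false(0.5 > 0.6)
})

test_that("lowering the posterior threshold never loses calls", {
  sim <- simulate_dosage_matrix(120, 3, q_dist = 0.5, seed = 41)
  sig <- simulate_signals(sim$dosage, noise_sd = 0.25, seed = 42)
  thresholds <- c(0.9, 0.6, 0.3)
  n_called <- vapply(thresholds, function(th) {
    calls <- quietly(call_dosages(sig, posterior_threshold = th, seed = 43))
    sum(!is.na(calls$calls$dosage))
  }, numeric(1))
  expect_true(all(diff(n_called) >= 0))
})

test_that("calls reshape to a matrix with missing cells preserved", {
  calls <- tibble::tibble(sample = c("a", "a", "b", "b"),
                          marker = c("M1", "M2", "M1", "M2"),
                          dosage = c(0L, 4L, 2L, NA))
  m <- calls_to_matrix(calls)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m$M1, c(0L, 2L))
  expect_true(is.na(m$M2[2]))
  expect_error(calls_to_matrix(dplyr::bind_rows(calls, calls[1, ])),
               "duplicate")
})

test_that("the full signals-to-matrix path matches simulation truth", {
  sim <- simulate_dosage_matrix(150, 5,
                                q_dist = function(n) runif(n, 0.25, 0.75),
                                missing_rate = 0.03, seed = 51)
  sig <- simulate_signals(sim$dosage, noise_sd = 0.05, seed = 52)
  calls <- quietly(call_dosages(sig, seed = 53))
  m <- calls_to_matrix(calls)
  m <- m[match(sim$dosage$sample, m$sample), ]
  got <- as.matrix(m[, -1])[, colnames(sim$dosage[, -1])]
  want <- as.matrix(sim$truth$dosage_true[, -1])
  obs <- as.matrix(sim$dosage[, -1])
  confident <- !is.na(got) & !is.na(obs)
  expect_gt(mean(got[confident] == want[confident]), 0.99)
})
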