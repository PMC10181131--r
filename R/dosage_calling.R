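#' Allele-signal ratio and its variance-stabilising transform
#'
#' The endpoint read of a competitive allele-specific PCR assay is a pair of
#' fluorescence intensities (FAM for one allele, HEX for the other). The
#' B-allele signal fraction `hex / (fam + hex)` increases with B dosage; the
#' arcsine-square-root transform spreads the cluster spacing near 0 and 1 and
#' is the scale on which the mixture model is fitted.
#'
#' @param fam,hex Non-negative channel intensities (vectorised).
#' @return `signal_ratio()` returns the raw ratio in `[0, 1]` (`NA` when both
#'   channels are zero, which marks the record uncallable);
#'   `ratio_transform()` returns `asin(sqrt(r))`.
#' @examples
#' signal_ratio(100, 300)  # 0.75
#' @export
signal_ratio <- function(fam, hex) {
  tot <- fam + hex
  ifelse(tot > 0, hex / tot, NA_real_)
}

#' @param r Raw ratio in `[0, 1]`.
#' @rdname signal_ratio
#' @export
ratio_transform <- function(r) asin(sqrt(r))

## anchor positions of the five dosage classes on the transformed scale
dosage_anchors <- function() ratio_transform((0:4) / 4)

## ---------------------------------------------------------------------------
## order-constrained univariate Gaussian mixture, tied variance, EM
## ---------------------------------------------------------------------------

## log-likelihood matrix n x k
mixture_loglik_matrix <- function(y, w, mu, sigma) {
  sapply(seq_along(mu), function(c) log(w[c]) + dnorm(y, mu[c], sigma,
                                                      log = TRUE))
}

## posterior responsibilities, rows sum to 1
mixture_posteriors <- function(y, w, mu, sigma) {
  ll <- mixture_loglik_matrix(y, w, mu, sigma)
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = length(y))
  mx <- apply(ll, 1, max)
  p <- exp(ll - mx)
  p / rowSums(p)
}

fit_gaussian_mixture_k <- function(y, k, max_iter = 500, tol = 1e-8) {
  n <- length(y)
  sd_floor <- 1e-6
  best <- NULL
  ## deterministic initialisations: every increasing subset of the five
  ## theoretical class positions, plus a quantile-based start
  anchor_inits <- lapply(seq_len(ncol(combn(5, k))), function(j) {
    dosage_anchors()[combn(5, k)[, j]]
  })
  qs <- (seq_len(k) - 0.5) / k
  inits <- c(anchor_inits, list(sort(as.numeric(quantile(y, qs, type = 7)))))
  for (mu0 in inits) {
    mu <- mu0
    sigma <- max(min(sd(y) / max(k, 1), 0.1), 0.02, sd_floor)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- sapply(seq_len(k), function(c) w[c] * dnorm(y, mu[c], sigma))
      if (is.null(dim(dens))) dens <- matrix(dens, nrow = n)
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      ll <- sum(log(tot))
      resp <- dens / tot
      nk <- colSums(resp)
      w <- nk / n
      mu_new <- colSums(resp * y) / pmax(nk, 1e-12)
      ## tied variance pooled across components
      sigma <- sqrt(sum(resp * outer(y, mu_new, "-")^2) / n)
      sigma <- max(sigma, sd_floor)
      ## tied variance makes label sorting an exact relabeling
      ord <- order(mu_new)
      mu <- mu_new[ord]
      w <- w[ord]
      if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    n_par <- 2 * k  # (k-1) weights + k means + 1 tied sd
    fit <- list(k = k, w = w, mu = mu, sigma = sigma, loglik = ll,
                bic = -2 * ll + n_par * log(n), converged = converged,
                n = n)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

## best strictly-increasing assignment of k components to dosage classes 0..4,
## minimising weighted squared distance to the class anchors
assign_dosage_classes <- function(mu, w) {
  k <- length(mu)
  anchors <- dosage_anchors()
  combos <- combn(5, k)
  costs <- apply(combos, 2, function(ix) sum(w * (mu - anchors[ix])^2))
  combos[, which.min(costs)] - 1L
}

#' Call tetraploid allele dosages from fluorescence signals
#'
#' Per marker, the B-allele signal fractions are arcsine-square-root
#' transformed and fitted with one-dimensional Gaussian mixtures of 1 to
#' `max_components` components (tied variance, ordered means, EM started
#' deterministically from every increasing subset of the theoretical class
#' positions plus a quantile-based start, best log-likelihood kept). The
#' component count is
#' selected by BIC. Components are mapped to dosage classes 0..4 by the
#' increasing assignment closest to the theoretical class positions
#' `asin(sqrt(d/4))`, so unobserved classes are allowed when fewer than five
#' components are supported. Each sample receives the maximum-posterior
#' dosage when that posterior strictly exceeds `posterior_threshold`, and a
#' missing call otherwise. When the largest component holds a sample fraction
#' above `peak_threshold` the marker is flagged non-segregating (the default
#' of 1 disables the flag).
#'
#' @param signals Signal tibble with columns `sample`, `marker`, `fam`,
#'   `hex`.
#' @param max_components Largest number of mixture components (dosage
#'   classes) considered.
#' @param posterior_threshold Minimum posterior (strict) for an assigned
#'   call.
#' @param peak_threshold Largest-component fraction above which a marker is
#'   flagged non-segregating.
#' @param orientation `"fam-is-A"` (default): the FAM channel reads the A
#'   allele, so high HEX fraction means high B dosage. `"hex-is-A"` flips
#'   the ratio. MA statistics downstream depend on this choice.
#' @param min_callable Markers with fewer callable records are reported
#'   uncalled.
#' @param seed Integer seed for the EM restarts.
#' @return An object of class `dosage_calls`: a list with `calls` (tibble
#'   `sample`, `marker`, `ratio`, `dosage`, `posterior`) and `models`
#'   (per-marker fit summaries). `tidy()` returns per-component parameters,
#'   `glance()` per-marker model summaries.
#' @export
call_dosages <- function(signals, max_components = 5,
                         posterior_threshold = 0.6, peak_threshold = 1.0,
                         orientation = c("fam-is-A", "hex-is-A"),
                         min_callable = 10, seed = 1L) {
  orientation <- match.arg(orientation)
  need <- c("sample", "marker", "fam", "hex")
  if (!all(need %in% names(signals))) {
    abort("call_dosages: signals need columns sample, marker, fam, hex")
  }
  set.seed(seed)
  markers <- unique(signals$marker)
  calls <- list()
  models <- list()
  for (m in markers) {
    sig <- signals[signals$marker == m, ]
    r <- signal_ratio(sig$fam, sig$hex)
    if (orientation == "hex-is-A") r <- 1 - r
    callable <- !is.na(r)
    out <- tibble(sample = sig$sample, marker = m, ratio = r,
                  dosage = NA_integer_, posterior = NA_real_)
    if (sum(callable) < min_callable) {
      models[[m]] <- tibble(marker = m, k = NA_integer_, sigma = NA_real_,
                            loglik = NA_real_, bic = NA_real_,
                            converged = NA, called = FALSE,
                            non_segregating = NA, n_callable = sum(callable))
      calls[[m]] <- out
      next
    }
    y <- ratio_transform(r[callable])
    k_max <- min(max_components, length(unique(y)))
    fits <- lapply(seq_len(k_max), function(k) fit_gaussian_mixture_k(y, k))
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    fit <- fits[[which.min(bics)]]
    dosage_of_comp <- assign_dosage_classes(fit$mu, fit$w)
    post <- mixture_posteriors(y, fit$w, fit$mu, fit$sigma)
    top <- max.col(post, ties.method = "first")
    top_post <- post[cbind(seq_along(y), top)]
    d <- dosage_of_comp[top]
    d[top_post <= posterior_threshold] <- NA_integer_
    if (!fit$converged) d[] <- NA_integer_  # calls withheld on EM failure
    out$dosage[callable] <- as.integer(d)
    out$posterior[callable] <- top_post
    models[[m]] <- tibble(marker = m, k = fit$k, sigma = fit$sigma,
                          loglik = fit$loglik, bic = fit$bic,
                          converged = fit$converged, called = fit$converged,
                          non_segregating = max(fit$w) > peak_threshold,
                          n_callable = fit$n)
    attr(models[[m]], "fit") <- c(fit, list(dosage_of_comp = dosage_of_comp))
    calls[[m]] <- out
  }
  structure(list(calls = bind_rows(calls), models = models,
                 posterior_threshold = posterior_threshold,
                 orientation = orientation, seed = seed),
            class = "dosage_calls")
}

#' @export
print.dosage_calls <- function(x, ...) {
  n_assigned <- sum(!is.na(x$calls$dosage))
  cat(sprintf(
    "<dosage_calls> %d markers, %d records, %d assigned (posterior > %.2f)\n",
    length(x$models), nrow(x$calls), n_assigned, x$posterior_threshold))
  invisible(x)
}

#' @export
tidy.dosage_calls <- function(x, ...) {
  bind_rows(purrr::map(x$models, function(m) {
    fit <- attr(m, "fit")
    if (is.null(fit)) return(NULL)
    tibble(marker = m$marker, component = seq_len(fit$k),
           dosage = fit$dosage_of_comp, weight = fit$w, mean = fit$mu,
           sd = fit$sigma)
  }))
}

#' @export
glance.dosage_calls <- function(x, ...) {
  bind_rows(purrr::map(x$models, function(m) {
    m2 <- m
    attr(m2, "fit") <- NULL
    m2
  }))
}

#' Reshape dosage calls into a samples x markers matrix
#'
#' @param calls A `dosage_calls` object from [call_dosages()], or its `calls`
#'   tibble.
#' @return A dosage tibble (`sample` column plus marker columns); sample and
#'   marker combinations without an assigned call are missing.
#' @export
calls_to_matrix <- function(calls) {
  if (inherits(calls, "dosage_calls")) calls <- calls$calls
  if (anyDuplicated(calls[, c("sample", "marker")])) {
    dup <- calls[duplicated(calls[, c("sample", "marker")]), ]
    abort(sprintf("calls_to_matrix: duplicate call for sample '%s', marker '%s'",
                  dup$sample[1], dup$marker[1]))
  }
  wide <- tidyr::pivot_wider(calls[, c("sample", "marker", "dosage")],
                             names_from = "marker", values_from = "dosage")
  wide$sample <- as.character(wide$sample)
  wide
}
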