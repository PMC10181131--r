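#' Pairwise Euclidean distances between dosage vectors
#'
#' For samples `x` and `y`, `d(x, y) = sqrt(sum_j (x_j - y_j)^2)` over the
#' loci non-missing in both samples (pairwise-complete deletion). The number
#' of shared loci per pair is recorded; a pair with no shared loci gets a
#' missing distance. Distances are not rescaled by the shared-locus count
#' unless `scale_by_shared = TRUE`, which rescales each pair to the
#' full-panel locus count.
#'
#' @param dosage Dosage tibble (`sample` column plus marker columns). Sample
#'   names must be unique; append a suffix upstream if replicates share a
#'   name.
#' @param scale_by_shared Rescale squared distances by
#'   `n_loci / n_shared` before the square root.
#' @return An object of class `ed_dist`: list with `d` (symmetric distance
#'   matrix), `shared` (shared-locus counts), `samples`. `tidy()` returns a
#'   long tibble of unordered pairs.
#' @export
euclidean_distances <- function(dosage, scale_by_shared = FALSE) {
  check_dosage_tbl(dosage)
  if (nrow(dosage) < 2) abort("euclidean_distances: need >= 2 samples")
  if (anyDuplicated(dosage$sample)) {
    abort("euclidean_distances: duplicate sample names; disambiguate first")
  }
  m <- as.matrix(dosage[, -1])
  rownames(m) <- dosage$sample
  n <- nrow(m)
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  ## pairwise-complete sums of squares via matrix products
  shared <- obs %*% t(obs)
  sq <- (m0^2) %*% t(obs) + obs %*% t(m0^2) - 2 * m0 %*% t(m0)
  sq[sq < 0] <- 0
  if (scale_by_shared) sq <- sq * ncol(m) / shared
  d <- sqrt(sq)
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  structure(list(d = d, shared = shared, samples = dosage$sample),
            class = "ed_dist")
}

#' @export
print.ed_dist <- function(x, ...) {
  cat(sprintf("<ed_dist> %d samples; distance range [%.3g, %.3g]\n",
              length(x$samples), min(x$d, na.rm = TRUE),
              max(x$d, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.ed_dist <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(sample_a = x$samples[idx[, 1]], sample_b = x$samples[idx[, 2]],
         distance = x$d[idx], shared_loci = x$shared[idx])
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomerative clustering: at each step the two clusters at
#' the smallest mean cross-pair distance are merged, and the merge is placed
#' at half that distance, so the tree is ultrametric and the path height
#' between two leaves equals their cluster distance. Ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its alphabetically first member).
#'
#' @param distances An `ed_dist` from [euclidean_distances()], a `dist`, or a
#'   complete symmetric matrix with dimnames.
#' @return An object of class `upgma` with `merge`, `height` (half merge
#'   distances, `hclust` convention), `labels` and `order`;
#'   `as.hclust()`/`ape::as.phylo()` conversions apply.
#' @examples
#' d <- euclidean_distances(tibble::tibble(
#'   sample = c("X", "Y", "Z"), m1 = c(0, 0, 4), m2 = c(0, 2, 4)))
#' upgma(d)$height  # first merge at 1, root at ~2.532
#' @export
upgma <- function(distances) {
  d <- if (inherits(distances, "ed_dist")) distances$d
       else as.matrix(distances)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  if (anyNA(d)) {
    abort(paste0("upgma: distance matrix has missing entries ",
                 "(pairs with no shared loci); impute or drop samples"))
  }
  n <- nrow(d)
  if (n < 2) abort("upgma: need >= 2 samples")
  labels <- rownames(d)
  ## active clusters: id (negative leaf / positive merge row), size, label
  id <- -seq_len(n)
  size <- rep(1L, n)
  lab <- labels
  act <- seq_len(n)
  dd <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    k <- length(act)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        dij <- dd[i, j]
        key <- sort(c(lab[i], lab[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- best$d / 2
    ## size-weighted average linkage update
    new_row <- (size[i] * dd[i, ] + size[j] * dd[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    id <- c(id[keep], s)
    size <- c(size[keep], size[i] + size[j])
    lab <- c(lab[keep], min(best$key))
    act <- seq_len(k - 1)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 order = leaf_order(merge, n)),
            class = "upgma")
}

leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' @export
print.upgma <- function(x, ...) {
  cat(sprintf("<upgma> %d leaves, root height %.4g\n", length(x$labels),
              max(x$height)))
  invisible(x)
}

#' @export
as.hclust.upgma <- function(x, ...) {
  ## hclust records the full merging distance; the upgma object stores the
  ## half-distance (ultrametric node depth)
  structure(list(merge = x$merge, height = x$height * 2, order = x$order,
                 labels = x$labels, method = "upgma",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Cophenetic distances of a UPGMA tree
#'
#' @param tree A `upgma` object.
#' @return Symmetric matrix of leaf-to-leaf tree distances (twice the merge
#'   height, i.e. the cluster distance at which two leaves first co-cluster).
#' @export
cophenetic_distances <- function(tree) {
  as.matrix(stats::cophenetic(as.hclust.upgma(tree)))
}

#' @export
plot.upgma <- function(x, ...) {
  plot(as.hclust.upgma(x), ...)
}

#' Write a dendrogram as a Newick string
#'
#' Branch lengths are printed with 6 significant digits; labels are quoted
#' per Newick rules when they contain metacharacters. A single-leaf tree is
#' written as `"A;"`.
#'
#' @param tree A `upgma` object, an `hclust`, or an `ape::phylo`.
#' @param path Optional output file; when `NULL` the string is returned.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.character(tree) && length(tree) == 1) {
    ## degenerate single-leaf tree, given as its label
    txt <- paste0(quote_newick_label(tree), ";")
    if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
    return(txt)
  }
  if (inherits(tree, "upgma")) tree <- as.hclust.upgma(tree)
  if (inherits(tree, "hclust")) {
    if (length(tree$labels) == 1) {
      txt <- paste0(quote_newick_label(tree$labels), ";")
      if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
      return(txt)
    }
    tree <- ape::as.phylo(tree)
  }
  if (!inherits(tree, "phylo")) abort("write_newick: unsupported tree class")
  txt <- ape::write.tree(tree, digits = 6)
  if (!is.null(path)) {
    writeLines(txt, path)
    inform(sprintf("write_newick: %s: %d leaves", basename(path),
                   length(tree$tip.label)))
    return(invisible(txt))
  }
  txt
}

quote_newick_label <- function(x) {
  needs <- grepl("[ ()\\[\\]:;,']", x)
  ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
}

#' Principal component scores of a dosage matrix
#'
#' Missing cells are imputed with the per-marker mean dosage (reported via a
#' message), columns are centred (not scaled), and the matrix is decomposed
#' by singular values. The sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param dosage Dosage tibble.
#' @param n_components Number of components to return.
#' @return An object of class `dosage_pca`: list with `scores` (tibble
#'   `sample`, `PC1`, ...), `explained_variance` (fractions), `loadings`.
#' @export
pca_scores <- function(dosage, n_components = 2) {
  check_dosage_tbl(dosage)
  m <- as.matrix(dosage[, -1])
  if (nrow(m) < 2) abort("pca_scores: need >= 2 samples")
  if (n_components > nrow(m)) {
    abort("pca_scores: more components requested than samples")
  }
  n_imp <- sum(is.na(m))
  if (n_imp > 0) {
    inform(sprintf("pca_scores: imputing %d missing cells with marker means",
                   n_imp))
    for (j in seq_len(ncol(m))) {
      mj <- m[, j]
      mu <- mean(mj, na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      m[is.na(mj), j] <- mu
    }
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  tot <- sum(pc$sdev^2)
  ev <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = bind_cols(tibble(sample = dosage$sample),
                       as_tibble(scores)),
    explained_variance = ev[seq_len(k)],
    loadings = load), class = "dosage_pca")
}

#' @export
print.dosage_pca <- function(x, ...) {
  cat(sprintf("<dosage_pca> %d samples, %d components (%s%% variance)\n",
              nrow(x$scores), length(x$explained_variance),
              paste(round(100 * x$explained_variance, 1), collapse = "/")))
  invisible(x)
}

#' @export
tidy.dosage_pca <- function(x, ...) x$scores
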