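#' Pairwise identity-by-state distance matrix
#'
#' IBS similarity between two individuals is the mean, over markers typed
#' in both, of the shared-allele fraction (0, 0.5 or 1 per marker); the
#' distance is one minus that. Missing genotypes are handled
#' pairwise-complete: a marker missing in either member of a pair is
#' excluded for that pair only.
#'
#' Computed via indicator-matrix cross-products, which is algebraically
#' identical to the per-marker definition but runs through BLAS.
#'
#' @param data A [geno_data()] object with at least two individuals.
#' @return Symmetric numeric matrix (zero diagonal) with sample ids as
#'   dimnames; values in \[0, 1\]. `NaN` for pairs with no co-typed marker.
#' @export
ibs_distance <- function(data) {
  stopifnot(inherits(data, "geno_data"), nrow(data$geno) >= 2)
  g <- data$geno
  M <- !is.na(g)
  I0 <- (g == 0L) & M; I1 <- (g == 1L) & M; I2 <- (g == 2L) & M
  storage.mode(M) <- storage.mode(I0) <- "double"
  storage.mode(I1) <- storage.mode(I2) <- "double"
  # sum over co-typed markers of |g_i - g_j|
  d01 <- tcrossprod(I0, I1)
  d12 <- tcrossprod(I1, I2)
  sumdiff <- d01 + t(d01) + d12 + t(d12) + 2 * (tcrossprod(I0, I2) +
                                                  tcrossprod(I2, I0))
  cotyped <- tcrossprod(M)
  dist <- sumdiff / (2 * cotyped)
  diag(dist) <- 0
  dimnames(dist) <- list(data$samples$sample_id, data$samples$sample_id)
  dist
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric distance matrix in `k` dimensions by
#' double-centering the squared distances and taking the top-`k`
#' eigenvectors, the classical MDS of Torgerson. Axes are ordered by
#' eigenvalue; each axis is oriented so its largest-magnitude coordinate
#' is positive, making the output deterministic. Negative eigenvalues
#' (non-Euclidean input) are truncated with a warning.
#'
#' @param dist Symmetric distance matrix (or `dist` object).
#' @param k Number of dimensions (default 2); must be < n.
#' @return n x k coordinate matrix with eigenvalues attached as attribute
#'   `"eig"`.
#' @export
classical_mds <- function(dist, k = 2) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist), nrow(dist) > k)
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    abort("distance matrix must be symmetric")
  }
  fit <- cmdscale(stats::as.dist(dist), k = k, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    warn("distance matrix is non-Euclidean; negative eigenvalues truncated")
  }
  pts <- fit$points
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    m <- which.max(abs(pts[, j]))
    if (length(m) == 1 && pts[m, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("C", seq_len(ncol(pts)))
  attr(pts, "eig") <- fit$eig
  pts
}

#' IBS-distance MDS of a genotype dataset
#'
#' Convenience wrapper chaining [ibs_distance()] and [classical_mds()],
#' returning a fitted object with broom-style [tidy()]/[glance()] methods
#' and an [ggplot2::autoplot()] method.
#'
#' @param data A [geno_data()] object.
#' @param k Number of MDS dimensions (default 2).
#' @return Object of class `ibs_mds` with elements `points` (tibble of
#'   `sample_id`, `population` and coordinates `C1..Ck`) and `eig`.
#' @export
#' @examples
#' sim <- simulate_goat_cohort(sim_config(n_markers = 500, n_chromosomes = 2,
#'   pop_sizes = c(A = 6, B = 6), target_f = c(A = 0, B = 0), fst = 0.2),
#'   seed = 7)
#' fit <- mds_ibs(sim$data)
#' glance(fit)
mds_ibs <- function(data, k = 2) {
  d <- ibs_distance(data)
  pts <- classical_mds(d, k = k)
  points <- dplyr::bind_cols(data$samples,
                             tibble::as_tibble(unclass(pts[, , drop = FALSE])))
  structure(list(points = points, eig = attr(pts, "eig"), k = k,
                 n = nrow(points)),
            class = "ibs_mds")
}

#' @export
print.ibs_mds <- function(x, ...) {
  cat(sprintf("<ibs_mds> %d individuals in %d dimensions\n", x$n, x$k))
  ev <- x$eig[x$eig > 0]
  cat(sprintf("  variance on first %d axes: %.1f%%\n", x$k,
              100 * sum(x$eig[seq_len(x$k)]) / sum(ev)))
  invisible(x)
}

#' Tidy MDS coordinates
#' @param x An `ibs_mds` object.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `population` and coordinate columns.
#' @method tidy ibs_mds
#' @export
tidy.ibs_mds <- function(x, ...) x$points

#' One-row MDS summary
#' @param x An `ibs_mds` object.
#' @param ... Unused.
#' @return Tibble with `n`, `k`, proportion of (positive) eigenvalue mass
#'   on the retained axes, and the count of negative eigenvalues.
#' @method glance ibs_mds
#' @export
glance.ibs_mds <- function(x, ...) {
  pos <- x$eig[x$eig > 0]
  tibble::tibble(
    n = x$n, k = x$k,
    prop_variance = sum(x$eig[seq_len(x$k)]) / sum(pos),
    n_negative_eig = sum(x$eig < 0)
  )
}
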