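#' Fuzzy c-means soft clustering of standardized expression profiles
#'
#' Minimizes \eqn{\sum_i \sum_j u_{ij}^m \|x_i - c_j\|^2} by alternating
#' membership and centroid updates until the largest centroid coordinate
#' shift is below `tol` or `max_iter` is reached. Initialization picks `C`
#' distinct gene profiles as starting centroids; with `nstart > 1` the best
#' of several seeded restarts (lowest objective) is returned, so results are
#' deterministic given the seed.
#'
#' @param z standardized gene x sample matrix (rows mean 0, s.d. 1).
#' @param C number of clusters (>= 2, < number of genes).
#' @param m fuzzifier (> 1); the MFuzz-typical 1.25 is the default.
#' @param seed integer seed for the initialization stream.
#' @param nstart number of seeded restarts.
#' @param tol convergence threshold on the max absolute centroid shift.
#' @param max_iter iteration cap; non-convergence returns the best state
#'   with `converged = FALSE` and a warning.
#' @return object of class `soft_clustering`: list with `membership`
#'   (gene x cluster, rows sum to 1), `centroids` (cluster x sample),
#'   `cluster` (hard assignment = argmax membership, ties to the lowest
#'   index), `m`, `objective`, `converged`.
#' @export
fuzzy_cmeans <- function(z, C, m = 1.25, seed = 1L, nstart = 3L,
                         tol = 1e-6, max_iter = 1000L) {
  z <- as.matrix(z)
  if (C < 2L) stop("C must be >= 2")
  if (C >= nrow(z)) stop("C must be smaller than the number of genes")
  if (m <= 1) stop("fuzzifier m must be > 1")
  best <- NULL
  for (r in seq_len(nstart)) {
    set.seed(derive_seed(seed, "cluster", rep = r))
    fit <- .fcm_once(z, C, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged) warning("fuzzy c-means did not converge; returning best state")
  best
}

.fcm_once <- function(z, C, m, tol, max_iter) {
  centroids <- z[sample.int(nrow(z), C), , drop = FALSE]
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- .sq_dist(z, centroids)
    u <- .fcm_membership(d2, m)
    um <- u^m
    new_centroids <- crossprod(um, z) / colSums(um)
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift < tol) { converged <- TRUE; break }
  }
  d2 <- .sq_dist(z, centroids)
  u <- .fcm_membership(d2, m)
  hard <- max.col(u, ties.method = "first")
  rownames(centroids) <- colnames(u) <- paste0("C", seq_len(C))
  rownames(u) <- rownames(z)
  colnames(centroids) <- colnames(z)
  structure(list(membership = u, centroids = centroids, cluster = hard,
                 m = m, objective = sum(u^m * d2), converged = converged),
            class = "soft_clustering")
}

# squared Euclidean distances, genes x centroids
.sq_dist <- function(z, centroids) {
  outer(rowSums(z^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(z)), rowSums(centroids^2)) - 2 * z %*% t(centroids)
}

.fcm_membership <- function(d2, m) {
  d2 <- pmax(d2, 0)
  zero <- d2 < .Machine$double.eps
  inv <- d2^(-1 / (m - 1))
  u <- inv / rowSums(inv)
  hit <- which(rowSums(zero) > 0)
  if (length(hit)) {
    u[hit, ] <- 0
    for (i in hit) u[i, which(zero[i, ])[1L]] <- 1
  }
  u
}

#' Select the number of clusters by the minimum centroid distance curve
#'
#' Fits fuzzy c-means for every C in `C_range` and records the minimum
#' pairwise centroid distance D_min(C). The returned C is the knee of the
#' decreasing curve: the largest C maximizing the local curvature
#' `2 D(C) - D(C-1) - D(C+1)`, i.e. the last C before the curve flattens.
#'
#' @inheritParams fuzzy_cmeans
#' @param C_range contiguous integer range of candidate C (min >= 2).
#' @return list with `C` (selected), `curve` (data.frame C, d_min).
#' @export
select_cluster_number <- function(z, C_range, m = 1.25, seed = 1L,
                                  nstart = 3L) {
  C_range <- sort(unique(as.integer(C_range)))
  if (min(C_range) < 2L) stop("C_range must start at 2 or more")
  d_min <- vapply(C_range, function(C) {
    fit <- fuzzy_cmeans(z, C, m = m, seed = seed, nstart = nstart)
    min(dist(fit$centroids))
  }, numeric(1))
  curve <- data.frame(C = C_range, d_min = d_min)
  if (length(C_range) == 1L) {
    warning("C_range has a single value; returning it")
    return(list(C = C_range, curve = curve))
  }
  if (length(C_range) == 2L) {
    return(list(C = C_range[which.max(-diff(d_min))], curve = curve))
  }
  n <- length(C_range)
  curvature <- 2 * d_min[2:(n - 1)] - d_min[1:(n - 2)] - d_min[3:n]
  best <- max(which(curvature == max(curvature))) + 1L
  list(C = C_range[best], curve = curve)
}

#' Temporal ordering and the major-cluster rule
#'
#' Orders clusters by expression onset (first sample whose centroid exceeds
#' the onset threshold; ties broken by peak time, then cluster index) and
#' flags as non-major every cluster with <= `min_terms` enriched terms or
#' centroid above threshold in <= `min_regen_samples` regenerating samples.
#'
#' @param clustering a `soft_clustering`.
#' @param samples data.frame with a logical `regenerating` column aligned
#'   with the centroid columns.
#' @param enriched_terms named integer vector: number of significantly
#'   enriched terms per cluster (names "C1", ... or bare indices).
#' @param onset_threshold centroid value counting as "expressed".
#' @param min_terms,min_regen_samples strict lower bounds of the rule
#'   (defaults: > 1 term, > 1 regenerating sample).
#' @return data.frame per cluster: cluster, onset, peak, order, n_terms,
#'   n_regen_expressed, major.
#' @export
order_and_filter_major <- function(clustering, samples, enriched_terms,
                                   onset_threshold = 0, min_terms = 1L,
                                   min_regen_samples = 1L) {
  stopifnot(inherits(clustering, "soft_clustering"))
  if (is.null(enriched_terms)) stop("enrichment table is required")
  cen <- clustering$centroids
  if (nrow(samples) != ncol(cen)) stop("samples do not align with centroids")
  C <- nrow(cen)
  terms <- rep(0L, C)
  idx <- if (is.null(names(enriched_terms))) seq_along(enriched_terms) else
    match(names(enriched_terms), rownames(cen))
  terms[idx] <- as.integer(enriched_terms)

  onset <- apply(cen, 1L, function(x) {
    i <- which(x > onset_threshold)
    if (length(i)) min(i) else ncol(cen) + 1L
  })
  peak <- apply(cen, 1L, which.max)
  n_regen <- vapply(seq_len(C), function(j) {
    sum(cen[j, samples$regenerating] > onset_threshold)
  }, integer(1))
  ord <- order(onset, peak, seq_len(C))
  data.frame(cluster = rownames(cen), onset = onset, peak = peak,
             order = match(seq_len(C), ord), n_terms = terms,
             n_regen_expressed = n_regen,
             major = terms > min_terms & n_regen > min_regen_samples,
             stringsAsFactors = FALSE)[ord, ]
}
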