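#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM procedure: a reference
#' sample is chosen as the one whose 75th-percentile proportion is closest to
#' the mean across samples; for every other sample the factor is the
#' inverse-variance weighted mean of gene-wise log2 proportion ratios
#' (M-values), after trimming 30% of M-values and 5% of A-values on each
#' side and excluding genes with a zero count in either sample. Factors are
#' geometric-mean centered so their product is 1.
#'
#' @param counts nonnegative gene x sample count matrix (>= 2 samples).
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A.
#' @return numeric vector of positive factors, one per sample, product 1.
#'   The normalized value of gene g in sample s is
#'   `counts[g, s] / (lib_size[s] * factor[s])` rescaled to TPM-like units.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("negative values in count matrix")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  prop <- sweep(counts, 2L, lib, "/")
  f75 <- apply(prop, 2L, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    .tmm_pair(counts[, s], counts[, ref], lib[s], lib[ref],
              logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# factor of sample `obs` against reference `ref` (both count vectors)
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_obs <- obs / n_obs; p_ref <- ref / n_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  # asymptotic (delta-method) variance of M as inverse-variance weight
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Apply TMM factors and rescale to TPM-like units
#'
#' @param counts gene x sample matrix.
#' @param factors output of [tmm_factors()].
#' @return matrix of normalized abundances summing to 1e6 per effective
#'   library.
#' @export
tmm_normalize <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) stop("factors do not align with samples")
  eff <- colSums(counts) * factors
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Log-transform and per-gene standardize an expression matrix
#'
#' Normalizes (when factors are given), applies `log2(x + 1)`, then centers
#' each gene to mean 0 and scales to s.d. 1. Genes with zero variance are
#' dropped and reported.
#'
#' @param mat gene x sample matrix of nonnegative abundances.
#' @param factors optional TMM factors; when `NULL` values are used as-is.
#' @return list with `z` (standardized matrix) and `dropped` (gene ids with
#'   zero variance).
#' @export
transform_standardize <- function(mat, factors = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(factors)) mat <- tmm_normalize(mat, factors)
  x <- log2(mat + 1)
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  dropped <- rownames(x)[s == 0 | is.na(s)]
  keep <- s > 0 & !is.na(s)
  if (!any(keep)) stop("all genes have zero variance")
  z <- (x[keep, , drop = FALSE] - mu[keep]) / s[keep]
  list(z = z, dropped = dropped)
}
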