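#' @keywords internal
"_PACKAGE"

#' @importFrom stats p.adjust phyper pbinom dbinom quantile rnorm rlnorm rpois
#'   runif rbinom cor sd setNames pnorm dist rgamma
#' @importFrom utils read.delim write.table combn head
NULL

# Derive a reproducible substream seed from a global seed and a stage tag.
# Offsets are fixed so partial reruns of a stage see the same stream.
.stage_offsets <- c(
  timecourse = 101L, karyotype = 211L, annotations = 307L, repeats = 401L,
  degs = 503L, cluster = 601L, permutation = 701L, pipeline = 811L
)

derive_seed <- function(seed, stage, rep = 0L) {
  if (!stage %in% names(.stage_offsets)) {
    stop("unknown stage tag: ", stage)
  }
  # keep well inside 32-bit integer range
  (as.integer(seed) %% 1000000L) * 1009L + .stage_offsets[[stage]] + 7L * as.integer(rep)
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Empirical permutation p-value
#'
#' Bias-avoiding estimator \code{(r + 1) / (N + 1)} where \code{r} is the
#' number of null replicates at least as extreme as the observed statistic.
#'
#' @param observed observed statistic (scalar or vector).
#' @param null matrix of null statistics with one row per replicate (or a
#'   vector when `observed` is scalar).
#' @return p-values on the attainable grid \code{[1/(N+1), 1]}.
#' @export
empirical_pvalue <- function(observed, null) {
  if (is.null(dim(null))) null <- matrix(null, ncol = length(observed))
  n_rep <- nrow(null)
  r <- colSums(null >= matrix(observed, n_rep, length(observed), byrow = TRUE))
  (r + 1) / (n_rep + 1)
}
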