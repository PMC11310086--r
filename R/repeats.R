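#' Convert repeat divergence to insertion age
#'
#' Age in Myr under a molecular-clock reading of the Kimura divergence to
#' the family consensus: `age_years = divergence / rate`, the consensus
#' standing in for the ancestral sequence.
#'
#' @param divergence divergence to consensus as a fraction (0.02 = 2%).
#' @param rate neutral substitution rate per bp per year; the default is the
#'   brittle-star estimate 1.885e-9.
#' @return age in Myr (linear in divergence).
#' @export
divergence_to_age <- function(divergence, rate = 1.885e-9) {
  if (any(rate <= 0)) stop("rate must be > 0")
  if (any(divergence < 0)) stop("divergence must be >= 0")
  divergence / rate / 1e6
}

#' Repeat landscape: genome coverage per divergence bin per class
#'
#' @param repeats data.frame with `start`, `end` (0-based half-open),
#'   `class`, `divergence` (Kimura %).
#' @param genome_length total genome length in bp.
#' @param bin_width divergence bin width in percent (default 1).
#' @param min_length copies shorter than this are dropped (default 50 bp).
#' @return data.frame (bin_lower, class, coverage); overlapping copies are
#'   double-counted (each copy contributes its full length).
#' @export
repeat_landscape <- function(repeats, genome_length, bin_width = 1,
                             min_length = 50L) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  len <- repeats$end - repeats$start
  keep <- len >= min_length
  r <- repeats[keep, , drop = FALSE]; len <- len[keep]
  bin <- floor(r$divergence / bin_width) * bin_width
  agg <- stats::aggregate(len, by = list(bin_lower = bin, class = r$class),
                          FUN = sum)
  data.frame(bin_lower = agg$bin_lower, class = agg$class,
             coverage = agg$x / genome_length)[order(agg$bin_lower), ]
}

#' Binomial test for repeat-family expansion within a region
#'
#' For each family with `n` genome-wide copies and `k` copies starting
#' inside the region, the one-sided binomial tail `P(X >= k)` with success
#' probability `region_length / genome_length`; BH across families.
#'
#' @param repeats data.frame with `family`, `start`, `end`.
#' @param region numeric length-2 `c(start, end)` of the tested region.
#' @param genome_length total genome length in bp.
#' @param alpha BH threshold for the `significant` flag.
#' @return data.frame (family, n, k, pvalue, padj, significant).
#' @export
region_expansion_test <- function(repeats, region, genome_length,
                                  alpha = 0.05) {
  if (region[2L] <= region[1L]) stop("invalid region")
  if (region[1L] < 0 || region[2L] > genome_length) {
    stop("region must lie within the genome")
  }
  prob <- (region[2L] - region[1L]) / genome_length
  fams <- split(repeats, repeats$family)
  fams <- fams[vapply(fams, nrow, integer(1)) > 0L]
  rows <- lapply(names(fams), function(f) {
    d <- fams[[f]]
    n <- nrow(d)
    k <- sum(d$start >= region[1L] & d$start < region[2L])
    data.frame(family = f, n = n, k = k,
               pvalue = pbinom(k - 1L, n, prob, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out$significant <- out$padj < alpha
  out[order(out$pvalue), ]
}

#' Permutation test for repeat association with breakpoints
#'
#' Statistic: number of a family's copies whose span intersects any
#' breakpoint +/- `window`. Null: `n_perm` uniform re-placements of the
#' family's copies within the region (lengths preserved). Empirical
#' p = (r + 1)/(N + 1); BH across families.
#'
#' @param repeats data.frame with `family`, `start`, `end`.
#' @param breakpoints positions within the region.
#' @param region_length analysis region length in bp.
#' @param window half-width in bp around each breakpoint (default 10 kb).
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @param alpha BH threshold for the `significant` flag.
#' @return data.frame (family, n, observed, pvalue, padj, significant).
#' @export
breakpoint_association_test <- function(repeats, breakpoints, region_length,
                                        window = 10000L, n_perm = 1000L,
                                        seed = 1L, alpha = 0.05) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (any(breakpoints < 0 | breakpoints > region_length)) {
    stop("breakpoints must lie inside the region")
  }
  lens <- repeats$end - repeats$start
  if (any(lens > region_length)) stop("region shorter than the longest copy")
  near <- function(start, len) {
    hit <- rep(FALSE, length(start))
    for (b in breakpoints) {
      hit <- hit | (start <= b + window & start + len >= b - window)
    }
    sum(hit)
  }
  set.seed(derive_seed(seed, "repeats"))
  fams <- split(seq_len(nrow(repeats)), repeats$family)
  rows <- lapply(names(fams), function(f) {
    idx <- fams[[f]]
    len <- lens[idx]
    obs <- near(repeats$start[idx], len)
    null <- vapply(seq_len(n_perm), function(b) {
      near(runif(length(idx), 0, region_length - len), len)
    }, numeric(1))
    data.frame(family = f, n = length(idx), observed = obs,
               pvalue = (sum(null >= obs) + 1) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out$significant <- out$padj < alpha
  out[order(out$pvalue), ]
}

#' Differential-activity filter for repetitive elements
#'
#' Retains families with `|log2FC| > lfc` and adjusted p below `alpha`
#' (strict inequalities). When only raw p-values are present they are
#' BH-adjusted first.
#'
#' @param stats data.frame with `family` (or first column), `log2fc`, and
#'   `padj` (or `pvalue`).
#' @param alpha adjusted-p cutoff (default 0.001).
#' @param lfc absolute log2 fold-change cutoff (default 1).
#' @return the retained rows.
#' @export
repeat_de_filter <- function(stats, alpha = 0.001, lfc = 1) {
  if (!"log2fc" %in% names(stats)) stop("missing log2fc column")
  if (!"padj" %in% names(stats)) {
    if (!"pvalue" %in% names(stats)) stop("missing padj / pvalue column")
    stats$padj <- p.adjust(stats$pvalue, method = "BH")
  }
  stats[abs(stats$log2fc) > lfc & stats$padj < alpha, , drop = FALSE]
}
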