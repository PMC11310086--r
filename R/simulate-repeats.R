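#' Simulate a repeat-annotated region with breakpoints, and explant DE tables
#'
#' Repeat copies of the first simulated family ("associated" when the
#' clustering weight pi is positive) are placed within +/- window of a
#' breakpoint with probability pi and uniformly otherwise; all other
#' families are uniform. Differential-expression tables for a distal /
#' proximal explant design are drawn from a normal error model around
#' planted true categories.
#'
#' @param config a [sim_config()]; uses the `repeat_region` element.
#' @param n_per_category genes planted per DEG category (shared, opposite,
#'   distal_only, proximal_only, null).
#' @param effect true absolute log2 fold change of non-null genes.
#' @param se standard error of the realized log2 fold change.
#' @return list with
#'   \item{repeats}{data.frame copy_id, family, class, chromosome, start,
#'     end, divergence (Kimura %)}
#'   \item{breakpoints}{integer positions within the region}
#'   \item{region_length}{bp}
#'   \item{degs}{data.frame gene_id, contrast (distal/proximal), timepoint,
#'     log2fc, pvalue, padj}
#'   \item{truth}{list: `repeat_assoc` (family, associated),
#'     `deg_category` (gene_id, category)}
#' @export
simulate_repeats_and_degs <- function(config, n_per_category = 40L,
                                      effect = 2, se = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  rr <- config$repeat_region
  if (rr$length_bp <= 0) stop("region length must be > 0")
  set.seed(derive_seed(config$seed, "repeats"))

  L <- rr$length_bp
  w <- rr$window_bp
  breakpoints <- round(seq(0.2, 0.8, length.out = rr$n_breakpoints) * L)
  if (any(breakpoints <= 0 | breakpoints >= L)) {
    stop("breakpoints must lie inside the region")
  }

  fams <- sprintf("repfam%02d", seq_len(rr$n_families))
  classes <- sample(c("DNA", "LINE", "SINE", "LTR", "Unknown"),
                    rr$n_families, replace = TRUE)
  rows <- lapply(seq_along(fams), function(fi) {
    n <- rr$copies_per_family
    len <- round(runif(n, 100, 1000))
    near <- (fi == 1L) & (runif(n) < rr$clustering_weight)
    start <- integer(n)
    for (i in seq_len(n)) {
      if (near[i]) {
        bp <- sample(breakpoints, 1L)
        lo <- max(0, bp - w); hi <- min(L - len[i], bp + w)
        start[i] <- round(runif(1, lo, max(lo, hi)))
      } else {
        start[i] <- round(runif(1, 0, L - len[i]))
      }
    }
    data.frame(copy_id = sprintf("%s_c%03d", fams[fi], seq_len(n)),
               family = fams[fi], class = classes[fi], chromosome = "chr1",
               start = start, end = start + len,
               divergence = stats::rgamma(n, shape = 2, scale = 5),
               stringsAsFactors = FALSE)
  })
  repeats <- do.call(rbind, rows)

  # explant DE layer -------------------------------------------------------
  set.seed(derive_seed(config$seed, "degs"))
  categories <- c("shared", "opposite", "distal_only", "proximal_only", "null")
  cat_vec <- rep(categories, each = n_per_category)
  n_genes <- length(cat_vec)
  gene_ids <- sprintf("deg_g%04d", seq_len(n_genes))
  base_sign <- sample(c(-1, 1), n_genes, replace = TRUE)

  true_lfc <- function(contrast) {
    vapply(seq_len(n_genes), function(i) {
      switch(cat_vec[i],
             shared = base_sign[i] * effect,
             opposite = (if (contrast == "distal") -1 else 1) * base_sign[i] * effect,
             distal_only = if (contrast == "distal") base_sign[i] * effect else 0,
             proximal_only = if (contrast == "proximal") base_sign[i] * effect else 0,
             null = 0)
    }, numeric(1))
  }
  # realized estimate keeps the planted sign (|noise| < |effect| by rejection)
  realize <- function(mu) {
    out <- mu + rnorm(n_genes, sd = se)
    bad <- which(mu != 0 & sign(out) != sign(mu))
    while (length(bad)) {
      out[bad] <- mu[bad] + rnorm(length(bad), sd = se)
      bad <- bad[sign(out[bad]) != sign(mu[bad])]
    }
    out
  }
  degs <- do.call(rbind, lapply(c("distal", "proximal"), function(contrast) {
    mu <- true_lfc(contrast)
    lfc <- realize(mu)
    p <- 2 * pnorm(-abs(lfc / se))
    data.frame(gene_id = gene_ids, contrast = contrast, timepoint = "3dpa",
               log2fc = lfc, pvalue = p,
               padj = p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  }))

  list(repeats = repeats, breakpoints = breakpoints, region_length = L,
       degs = degs,
       truth = list(
         repeat_assoc = data.frame(family = fams,
                                   associated = seq_along(fams) == 1L &
                                     rr$clustering_weight > 0,
                                   stringsAsFactors = FALSE),
         deg_category = data.frame(gene_id = gene_ids, category = cat_vec,
                                   stringsAsFactors = FALSE)
       ))
}
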