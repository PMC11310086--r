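#' Threshold filter for differential-expression tables
#'
#' Retains genes with adjusted p below `alpha` and `|log2FC|` strictly
#' greater than `lfc`, split into up- and down-regulated sets per contrast.
#'
#' @param table data.frame with `gene_id`, `contrast`, `log2fc` and `padj`
#'   (or `pvalue` with `adjust = TRUE`).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc absolute log2 fold-change cutoff (default 1, strict).
#' @param adjust BH-adjust raw p-values when `padj` is absent.
#' @return named list per contrast with `up` and `down` gene id vectors.
#' @export
deg_filter <- function(table, alpha = 0.05, lfc = 1, adjust = FALSE) {
  needed <- c("gene_id", "contrast", "log2fc")
  if (!all(needed %in% names(table))) {
    stop("missing columns: ", paste(setdiff(needed, names(table)),
                                    collapse = ", "))
  }
  if (!"padj" %in% names(table)) {
    if (!adjust || !"pvalue" %in% names(table)) {
      stop("missing padj column (set adjust = TRUE to BH-adjust pvalue)")
    }
    table$padj <- stats::ave(table$pvalue, table$contrast,
                             FUN = function(p) p.adjust(p, method = "BH"))
  }
  lapply(split(table, table$contrast), function(d) {
    sig <- !is.na(d$padj) & d$padj < alpha
    list(up = sort(d$gene_id[sig & d$log2fc > lfc]),
         down = sort(d$gene_id[sig & d$log2fc < -lfc]))
  })
}

#' Categorize distal vs proximal differentially expressed genes
#'
#' Per gene in the union of the four sets: `distal_specific`,
#' `proximal_specific`, `shared` (same direction in both segments) or
#' `opposite` (up in one segment, down in the other).
#'
#' @param distal,proximal lists with `up` and `down` gene id vectors from
#'   the same timepoint (as produced by [deg_filter()]).
#' @return list with `categories` (data.frame gene_id, category) and
#'   `summary` (fraction of proximal DEGs shared with distal; fraction of
#'   distal DEGs that are distal-specific).
#' @export
categorize_degs <- function(distal, proximal) {
  if (length(intersect(distal$up, distal$down)) ||
      length(intersect(proximal$up, proximal$down))) {
    stop("a gene cannot be both up and down in one segment")
  }
  d_all <- c(distal$up, distal$down)
  p_all <- c(proximal$up, proximal$down)
  genes <- sort(unique(c(d_all, p_all)))
  category <- vapply(genes, function(g) {
    in_d <- g %in% d_all; in_p <- g %in% p_all
    if (in_d && !in_p) return("distal_specific")
    if (!in_d && in_p) return("proximal_specific")
    same <- (g %in% distal$up) == (g %in% proximal$up)
    if (same) "shared" else "opposite"
  }, character(1))
  categories <- data.frame(gene_id = genes, category = unname(category),
                           stringsAsFactors = FALSE)
  summary <- data.frame(
    prop_proximal_shared = if (length(p_all))
      sum(category[genes %in% p_all] %in% c("shared", "opposite")) /
      length(unique(p_all)) else NA_real_,
    prop_distal_specific = if (length(d_all))
      sum(category == "distal_specific") / length(unique(d_all)) else NA_real_
  )
  list(categories = categories, summary = summary)
}

#' Enrichment of DEG sets against time-course clusters
#'
#' For every (DEG set, cluster) pair, a hypergeometric enrichment test with
#' all clustered genes as background; BH correction within each DEG set.
#'
#' @param deg_sets named list of gene id vectors (e.g. distal_up, ...).
#' @param cluster_assignment named vector of hard cluster assignments
#'   covering a superset of the DEG genes.
#' @param alpha BH threshold for the `significant` flag.
#' @return data.frame (deg_set, cluster, k, n, K, M, pvalue, padj,
#'   significant); empty DEG sets are skipped and reported in the
#'   `skipped_sets` attribute.
#' @export
deg_cluster_enrichment <- function(deg_sets, cluster_assignment,
                                   alpha = 0.05) {
  cluster_assignment <- .as_assignment(cluster_assignment)
  background <- names(cluster_assignment)
  annotations <- data.frame(gene_id = background,
                            term_id = as.character(unname(cluster_assignment)),
                            stringsAsFactors = FALSE)
  empty <- names(deg_sets)[lengths(deg_sets) == 0L]
  out <- lapply(setdiff(names(deg_sets), empty), function(nm) {
    fg <- intersect(deg_sets[[nm]], background)
    if (!length(fg)) return(NULL)
    res <- hypergeom_test(fg, background, annotations,
                          direction = "enrich", min_size = 1L)
    names(res)[names(res) == "term_id"] <- "cluster"
    cbind(deg_set = nm, res)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  else {
    out$significant <- out$padj < alpha
    rownames(out) <- NULL
  }
  attr(out, "skipped_sets") <- empty
  out
}
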