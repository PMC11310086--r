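#' Cross-species cluster overlap counts
#'
#' For every cluster pair (i, j), counts the species-1 genes hard-assigned
#' to cluster i that have at least one family member hard-assigned to
#' cluster j in species 2. Each species-1 gene contributes at most once per
#' (i, j) even when several of its homologues sit in the same cluster.
#'
#' @param clust1,clust2 named vectors (or 1-column data.frames) of hard
#'   cluster assignments, names = gene ids, for species 1 and 2.
#' @param families data.frame (family_id, species, gene_id), already
#'   filtered; only genes present in the clusterings are used.
#' @param sp1,sp2 species names as used in `families`.
#' @return list with `counts` (cluster1 x cluster2 integer matrix),
#'   `coverage` (genes clustered but absent from any family, per species),
#'   and the internal incidence structures reused by [permutation_test()].
#' @export
count_cluster_overlaps <- function(clust1, clust2, families, sp1, sp2) {
  clust1 <- .as_assignment(clust1)
  clust2 <- .as_assignment(clust2)
  f1 <- families[families$species == sp1, c("family_id", "gene_id")]
  f2 <- families[families$species == sp2, c("family_id", "gene_id")]
  f1 <- f1[f1$gene_id %in% names(clust1), , drop = FALSE]
  f2 <- f2[f2$gene_id %in% names(clust2), , drop = FALSE]

  # species-1 gene -> species-2 partner genes through the family
  partners <- merge(f1, f2, by = "family_id", suffixes = c("1", "2"))
  genes2 <- sort(unique(f2$gene_id))
  lab2 <- clust2[genes2]
  levels1 <- sort(unique(unname(clust1)))
  levels2 <- sort(unique(unname(clust2)))

  genes1 <- sort(unique(partners$gene_id1))
  # sparse incidence: species-1 genes x species-2 genes
  B <- Matrix::sparseMatrix(
    i = match(partners$gene_id1, genes1),
    j = match(partners$gene_id2, genes2),
    x = 1, dims = c(length(genes1), length(genes2))
  )
  counts <- .overlap_from_labels(B, lab2, clust1[genes1], levels1, levels2)

  structure(list(
    counts = counts,
    coverage = list(
      sp1_unmatched = setdiff(names(clust1), f1$gene_id),
      sp2_unmatched = setdiff(names(clust2), f2$gene_id)
    ),
    incidence = B, genes1 = genes1, genes2 = genes2,
    clust1 = clust1, lab2 = lab2, levels1 = levels1, levels2 = levels2,
    sp1 = sp1, sp2 = sp2, partners = partners
  ), class = "cluster_overlap")
}

.as_assignment <- function(x) {
  if (is.data.frame(x)) x <- setNames(x[[2L]], x[[1L]])
  if (is.null(names(x))) stop("cluster assignments must be named by gene id")
  x
}

# n_ij from an incidence matrix and species-2 labels
.overlap_from_labels <- function(B, lab2, lab1, levels1, levels2) {
  C2 <- Matrix::sparseMatrix(i = seq_along(lab2),
                             j = match(lab2, levels2), x = 1,
                             dims = c(length(lab2), length(levels2)))
  P <- as.matrix(B %*% C2) > 0          # gene1 has >=1 partner in cluster j
  C1 <- Matrix::sparseMatrix(i = seq_along(lab1),
                             j = match(lab1, levels1), x = 1,
                             dims = c(length(lab1), length(levels1)))
  counts <- as.matrix(Matrix::crossprod(C1, P))
  dimnames(counts) <- list(as.character(levels1), as.character(levels2))
  storage.mode(counts) <- "integer"
  counts
}

#' Constrained permutation test for cluster overlap conservation
#'
#' Builds the null distribution of every overlap count by permuting the
#' species-2 gene labels over the fixed multiset of cluster assignments
#' (cluster sizes and family structure preserved), recomputing all n_ij per
#' replicate. Empirical p = (r + 1)/(N + 1) with r the replicates whose
#' null count is >= the observed count; BH correction is applied across all
#' cluster pairs of the comparison.
#'
#' @param overlap result of [count_cluster_overlaps()].
#' @param n_perm number of randomizations (default 10000).
#' @param seed integer seed.
#' @param alpha significance level on BH-adjusted p (default 0.05).
#' @param keep_null also return the full null count samples (an
#'   `n_perm x clusters1 x clusters2` array); off by default to save memory.
#' @return object of class `overlap_test`: list with `counts`, `pvalue`,
#'   `padj`, `significant` matrices, `alpha`, `n_perm`, and
#'   `conserved_genes` — for each significant pair (i, j), the species-1
#'   genes of cluster i with a partner in species-2 cluster j.
#' @export
permutation_test <- function(overlap, n_perm = 10000L, seed = 1L,
                             alpha = 0.05, keep_null = FALSE) {
  stopifnot(inherits(overlap, "cluster_overlap"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  observed <- overlap$counts
  lab1 <- overlap$clust1[overlap$genes1]
  set.seed(derive_seed(seed, "permutation"))
  n2 <- length(overlap$lab2)

  r <- matrix(0L, nrow(observed), ncol(observed))
  null_store <- if (keep_null) {
    array(NA_integer_, c(n_perm, nrow(observed), ncol(observed)))
  }
  for (b in seq_len(n_perm)) {
    null_counts <- .overlap_from_labels(
      overlap$incidence, overlap$lab2[sample.int(n2)], lab1,
      overlap$levels1, overlap$levels2)
    r <- r + (null_counts >= observed)
    if (keep_null) null_store[b, , ] <- null_counts
  }
  pvalue <- (r + 1) / (n_perm + 1)
  if (all(observed == 0)) pvalue[] <- 1
  padj <- matrix(p.adjust(pvalue, method = "BH"), nrow(pvalue),
                 dimnames = dimnames(observed))
  dimnames(pvalue) <- dimnames(observed)
  significant <- padj < alpha

  conserved <- list()
  if (any(significant)) {
    hits <- which(significant, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      i <- rownames(observed)[hits[h, 1L]]
      j <- colnames(observed)[hits[h, 2L]]
      p <- overlap$partners
      genes <- unique(p$gene_id1[
        overlap$clust1[p$gene_id1] == i &
          overlap$lab2[p$gene_id2] == j])
      conserved[[paste(i, j, sep = "|")]] <- sort(genes)
    }
  }
  structure(list(counts = observed, pvalue = pvalue, padj = padj,
                 significant = significant, alpha = alpha, n_perm = n_perm,
                 conserved_genes = conserved, null = null_store,
                 sp1 = overlap$sp1, sp2 = overlap$sp2),
            class = "overlap_test")
}

#' Focal clusters consistent across two pairwise comparisons
#'
#' A focal cluster is consistent iff it belongs to at least one significant
#' pair in both comparisons; the conserved gene set is the intersection of
#' the focal genes appearing in significant-pair gene lists of both.
#'
#' @param result_ab,result_ac `overlap_test` results sharing species 1.
#' @return list with `clusters` (consistent focal cluster ids) and `genes`.
#' @export
threeway_consistency <- function(result_ab, result_ac) {
  if (!identical(result_ab$sp1, result_ac$sp1)) {
    stop("comparisons do not share the focal species")
  }
  sig_cl <- function(res) {
    if (!any(res$significant)) character(0) else
      unique(rownames(res$counts)[which(res$significant, arr.ind = TRUE)[, 1L]])
  }
  genes <- function(res) unique(unlist(res$conserved_genes, use.names = FALSE))
  cl <- intersect(sig_cl(result_ab), sig_cl(result_ac))
  g <- intersect(genes(result_ab), genes(result_ac))
  list(clusters = sort(cl), genes = sort(g))
}

#' Breakdown of conserved genes against a third species
#'
#' Partitions the conserved genes of one comparison into: no homologue in
#' species C; homologue present but not in a matched significant cluster
#' (divergent expression); or also conserved with C.
#'
#' @param result_ab `overlap_test` whose conserved genes are partitioned.
#' @param result_ac `overlap_test` of the same focal species against C.
#' @param families_with_c family table including species C.
#' @param sp1,spc focal and third species names in `families_with_c`.
#' @return data.frame (category, n, fraction); fractions sum to 1.
#' @export
homology_breakdown <- function(result_ab, result_ac, families_with_c,
                               sp1, spc) {
  genes <- unique(unlist(result_ab$conserved_genes, use.names = FALSE))
  if (!length(genes)) {
    return(data.frame(category = c("no_homologue", "divergent_expression",
                                   "conserved"),
                      n = c(0L, 0L, 0L), fraction = c(NA, NA, NA)))
  }
  fam_c <- unique(families_with_c$family_id[families_with_c$species == spc])
  fam_of_gene <- families_with_c[families_with_c$species == sp1, ]
  gene_fam <- setNames(fam_of_gene$family_id, fam_of_gene$gene_id)
  has_hom <- !is.na(gene_fam[genes]) & gene_fam[genes] %in% fam_c
  conserved_c <- genes %in% unlist(result_ac$conserved_genes, use.names = FALSE)
  category <- ifelse(!has_hom, "no_homologue",
                     ifelse(conserved_c, "conserved", "divergent_expression"))
  tab <- table(factor(category, levels = c("no_homologue",
                                           "divergent_expression",
                                           "conserved")))
  data.frame(category = names(tab), n = as.integer(tab),
             fraction = as.integer(tab) / length(genes))
}

#' Heterochrony report: temporal concordance of matched clusters
#'
#' Kendall rank correlation of the temporal ranks of significant cluster
#' pairs, with leave-one-out outlier ranking: the pair whose removal
#' increases the correlation the most is reported first.
#'
#' @param result an `overlap_test`.
#' @param order1,order2 named vectors giving the temporal rank of each
#'   cluster in species 1 and 2.
#' @return list with `tau` (NA when < 2 significant pairs), `pairs`
#'   (cluster1, cluster2, rank1, rank2), `outliers` (pairs ordered by
#'   leave-one-out tau gain).
#' @export
heterochrony_report <- function(result, order1, order2) {
  if (!any(result$significant)) {
    return(list(tau = NA_real_,
                pairs = data.frame(cluster1 = character(0),
                                   cluster2 = character(0)),
                outliers = data.frame()))
  }
  hits <- which(result$significant, arr.ind = TRUE)
  pairs <- data.frame(
    cluster1 = rownames(result$counts)[hits[, 1L]],
    cluster2 = colnames(result$counts)[hits[, 2L]],
    stringsAsFactors = FALSE
  )
  pairs$rank1 <- unname(order1[pairs$cluster1])
  pairs$rank2 <- unname(order2[pairs$cluster2])
  if (nrow(pairs) < 2L) {
    return(list(tau = NA_real_, pairs = pairs, outliers = data.frame()))
  }
  tau <- cor(pairs$rank1, pairs$rank2, method = "kendall")
  gain <- vapply(seq_len(nrow(pairs)), function(i) {
    if (nrow(pairs) <= 2L) return(NA_real_)
    cor(pairs$rank1[-i], pairs$rank2[-i], method = "kendall") - tau
  }, numeric(1))
  ord <- order(-gain)
  outliers <- cbind(pairs[ord, , drop = FALSE], tau_gain = gain[ord])
  list(tau = tau, pairs = pairs, outliers = outliers)
}
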