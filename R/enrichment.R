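#' Propagate gene-level annotations to families
#'
#' Annotates each family with the union of the terms of its member genes,
#' optionally restricted to a subset of donor species.
#'
#' @param gene_annotations data.frame (gene_id, term_id).
#' @param families data.frame (family_id, species, gene_id).
#' @param species_subset optional character vector of donor species.
#' @return data.frame (family_id, term_id), unique rows.
#' @export
propagate_to_families <- function(gene_annotations, families,
                                  species_subset = NULL) {
  fam <- families
  if (!is.null(species_subset)) {
    fam <- fam[fam$species %in% species_subset, , drop = FALSE]
  }
  m <- merge(fam[, c("family_id", "gene_id")], gene_annotations,
             by = "gene_id")
  unique(m[, c("family_id", "term_id")])
}

#' Hypergeometric enrichment / depletion tests
#'
#' One-sided hypergeometric tail per term (upper tail for enrichment, lower
#' for depletion) of the foreground hit count against the background, with
#' BH correction across all tested terms. Terms with fewer than `min_size`
#' background hits are skipped and reported.
#'
#' @param foreground,background entity id vectors, foreground a subset of
#'   background.
#' @param annotations data.frame with entity ids in the first column and
#'   term ids in the second.
#' @param direction "enrich" or "deplete".
#' @param min_size minimum background hits for a term to be tested.
#' @return data.frame (term_id, k, n, K, M, direction, pvalue, padj) plus a
#'   `skipped` attribute listing untested terms.
#' @export
hypergeom_test <- function(foreground, background, annotations,
                           direction = c("enrich", "deplete"),
                           min_size = 3L) {
  direction <- match.arg(direction)
  foreground <- unique(foreground)
  background <- unique(background)
  extra <- setdiff(foreground, background)
  if (length(extra)) {
    stop("foreground not contained in background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  if (!length(background)) stop("empty background")
  names(annotations)[1:2] <- c("entity_id", "term_id")
  ann <- annotations[annotations$entity_id %in% background, , drop = FALSE]
  M <- length(background)
  n <- length(foreground)
  K_tab <- table(ann$term_id)
  k_tab <- table(ann$term_id[ann$entity_id %in% foreground])
  terms <- names(K_tab)
  K <- as.integer(K_tab)
  k <- as.integer(k_tab[terms]); k[is.na(k)] <- 0L

  test <- K >= min_size
  skipped <- terms[!test]
  terms <- terms[test]; K <- K[test]; k <- k[test]
  p <- if (direction == "enrich") {
    phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, M - K, n, lower.tail = TRUE)
  }
  out <- data.frame(term_id = terms, k = k, n = n, K = K, M = M,
                    direction = direction, pvalue = p,
                    padj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' Per-cluster gene-age and curated-list enrichment
#'
#' Runs [hypergeom_test()] for every cluster, with the cluster's genes as
#' foreground and all clustered genes as background (or a caller-supplied
#' conservation-aware background). BH correction is applied within each
#' cluster's test set.
#'
#' @param cluster_assignment named vector of hard cluster assignments.
#' @param annotations data.frame (gene_id, term_id) — age strata or curated
#'   list memberships both fit this shape.
#' @param background optional custom background (default: all clustered
#'   genes); must contain every foreground.
#' @param direction "enrich" or "deplete".
#' @param alpha BH-FDR threshold used for the `significant` flag.
#' @param min_size minimum background hits per term.
#' @return data.frame with a `cluster` column prepended to the
#'   [hypergeom_test()] output, plus `significant`.
#' @export
age_and_list_enrichment <- function(cluster_assignment, annotations,
                                    background = NULL,
                                    direction = "enrich", alpha = 0.05,
                                    min_size = 3L) {
  cluster_assignment <- .as_assignment(cluster_assignment)
  if (is.null(background)) background <- names(cluster_assignment)
  if (!length(background)) stop("empty background")
  out <- lapply(sort(unique(unname(cluster_assignment))), function(cl) {
    fg <- intersect(names(cluster_assignment)[cluster_assignment == cl],
                    background)
    if (!length(fg)) return(NULL)
    res <- hypergeom_test(fg, background, annotations,
                          direction = direction, min_size = min_size)
    if (!nrow(res)) return(NULL)
    cbind(cluster = cl, res)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(cluster = character(0), term_id = character(0)))
  }
  out$significant <- out$padj < alpha
  rownames(out) <- NULL
  out
}
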