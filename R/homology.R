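#' Reciprocal best hits from similarity score tables
#'
#' A pair (a, b) is kept iff b is the unique best-scoring target of a in the
#' 1->2 table and a is the unique best-scoring target of b in the 2->1
#' table. Score ties for the best hit discard all tied candidates, keeping
#' strict one-to-one semantics.
#'
#' @param scores_1to2,scores_2to1 data.frames with columns `query`, `target`,
#'   `score` (higher is better).
#' @return data.frame (gene1, gene2) of one-to-one ortholog pairs, each gene
#'   appearing at most once.
#' @export
reciprocal_best_hits <- function(scores_1to2, scores_2to1) {
  b12 <- .unique_best(scores_1to2)
  b21 <- .unique_best(scores_2to1)
  if (!length(b12) || !length(b21)) {
    return(data.frame(gene1 = character(0), gene2 = character(0)))
  }
  back <- b21[b12]
  keep <- !is.na(back) & back == names(b12)
  out <- data.frame(gene1 = names(b12)[keep], gene2 = unname(b12[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$gene1), , drop = FALSE]
}

# named vector query -> unique best target (ties dropped)
.unique_best <- function(hits) {
  needed <- c("query", "target", "score")
  if (!all(needed %in% names(hits))) stop("hit table needs query/target/score")
  if (!nrow(hits)) return(character(0))
  out <- vapply(split(hits, hits$query), function(h) {
    top <- h$score == max(h$score)
    if (sum(top) != 1L) NA_character_ else h$target[top]
  }, character(1))
  out[!is.na(out)]
}

#' Filter homologous families by per-species gene counts
#'
#' Keeps families whose gene count in each of the two compared species lies
#' in `[min_per_species, max_per_species]`. The defaults (1 and 4) retain
#' families represented in both species with fewer than 5 genes in each.
#'
#' @param families data.frame (family_id, species, gene_id).
#' @param sp1,sp2 the two compared species.
#' @param min_per_species,max_per_species inclusive bounds.
#' @return list with `families` (the retained subset, all species columns
#'   kept) and `summary` (retained family and per-species gene counts).
#' @export
filter_families <- function(families, sp1, sp2, min_per_species = 1L,
                            max_per_species = 4L) {
  if (min_per_species > max_per_species) stop("min_per_species > max_per_species")
  n1 <- table(factor(families$family_id[families$species == sp1],
                     levels = unique(families$family_id)))
  n2 <- table(factor(families$family_id[families$species == sp2],
                     levels = unique(families$family_id)))
  ok <- n1 >= min_per_species & n1 <= max_per_species &
    n2 >= min_per_species & n2 <= max_per_species
  keep_ids <- names(n1)[ok]
  out <- families[families$family_id %in% keep_ids, , drop = FALSE]
  list(
    families = out,
    summary = data.frame(
      n_families = length(keep_ids),
      n_genes_sp1 = sum(out$species == sp1),
      n_genes_sp2 = sum(out$species == sp2)
    )
  )
}

#' Phylostratigraphic gene-age assignment
#'
#' A focal gene's stratum is the node on the focal-species root-path at
#' which its most distantly related family member branches off, i.e. the
#' most ancient of the MRCAs of the focal species with each other species
#' in the family; families containing only the focal species get the
#' youngest (lineage-specific) stratum. Strata are named by the tree's
#' internal node labels.
#'
#' @param families data.frame (family_id, species, gene_id).
#' @param tree a `phylo` species tree (or newick string) whose internal node
#'   labels name the strata; unlabeled nodes get "node<N>" labels.
#' @param focal focal species (must be a leaf).
#' @param youngest label used for focal-only families.
#' @return data.frame (gene_id, family_id, stratum) for focal genes, plus a
#'   `strata_levels` attribute ordered youngest to oldest.
#' @export
assign_phylostrata <- function(families, tree, focal,
                               youngest = "lineage-specific") {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!focal %in% tree$tip.label) stop("focal species not in tree: ", focal)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label))) {
    tree$node.label <- paste0("node", seq_len(tree$Nnode) + ntip)
  }
  node_name <- function(n) tree$node.label[n - ntip]
  focal_tip <- match(focal, tree$tip.label)
  path <- ape::nodepath(tree, from = root, to = focal_tip)
  path <- path[path > ntip]                     # internal nodes, root first
  # species under each path node
  clade_sp <- lapply(path, function(n) {
    ape::extract.clade(tree, n)$tip.label
  })
  names(clade_sp) <- vapply(path, node_name, character(1))
  levels_y2o <- c(youngest, rev(names(clade_sp)))

  # MRCA(focal, s) = last root-path node whose clade still contains s
  mrca_index <- function(s) max(which(vapply(clade_sp, function(sp)
    s %in% sp, logical(1))))

  fam_sp <- split(families$species, families$family_id)
  focal_rows <- families[families$species == focal, , drop = FALSE]
  stratum <- vapply(focal_rows$family_id, function(f) {
    others <- setdiff(unique(fam_sp[[f]]), focal)
    if (!length(others)) return(youngest)
    if (!all(others %in% tree$tip.label)) {
      stop("family species not in tree: ",
           paste(setdiff(others, tree$tip.label), collapse = ", "))
    }
    names(clade_sp)[min(vapply(others, mrca_index, numeric(1)))]
  }, character(1))
  out <- data.frame(gene_id = focal_rows$gene_id,
                    family_id = focal_rows$family_id,
                    stratum = stratum, stringsAsFactors = FALSE)
  attr(out, "strata_levels") <- levels_y2o
  out
}
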