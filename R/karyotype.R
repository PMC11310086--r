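#' Propagate ancestral linkage-group labels through one-to-one orthologs
#'
#' @param reference_labels named vector gene_id -> ALG label in the
#'   reference species.
#' @param orthologs data.frame (gene1 = reference gene, gene2 = target gene)
#'   of one-to-one pairs.
#' @return named vector target gene_id -> ALG label (unpaired or unlabeled
#'   genes absent).
#' @export
propagate_alg_labels <- function(reference_labels, orthologs) {
  if (!nrow(orthologs)) return(setNames(character(0), character(0)))
  if (anyDuplicated(orthologs$gene1) || anyDuplicated(orthologs$gene2)) {
    stop("duplicate genes in ortholog pairs violate one-to-one mapping")
  }
  lab <- reference_labels[orthologs$gene1]
  keep <- !is.na(lab)
  setNames(unname(lab[keep]), orthologs$gene2[keep])
}

#' Fisher-exact macrosynteny painting
#'
#' For every (chromosome, ALG) cell, a one-sided Fisher exact test (upper
#' hypergeometric tail) of the 2x2 table splitting labeled genes by on/off
#' chromosome and this/other ALG; BH correction across all cells; a
#' chromosome is painted with every ALG whose adjusted p is below the
#' threshold.
#'
#' @param labels named vector gene_id -> ALG label.
#' @param genome data.frame (gene_id, chromosome, position).
#' @param threshold adjusted-p threshold for assignment (default 1e-5).
#' @return object of class `painting`: list with `cells` (chromosome, alg,
#'   n, pvalue, padj, assigned), `assignments` (chromosome -> assigned ALG
#'   set), `unlabeled_chromosomes`.
#' @export
fisher_painting <- function(labels, genome, threshold = 1e-5) {
  lab <- labels[genome$gene_id]
  keep <- !is.na(lab)
  if (!any(keep)) stop("no labeled gene in the genome table")
  chrom <- genome$chromosome[keep]
  lab <- unname(lab[keep])
  tot <- length(lab)
  tab <- table(chrom, lab)
  chroms <- rownames(tab); algs <- colnames(tab)
  chr_tot <- rowSums(tab); alg_tot <- colSums(tab)

  cells <- expand.grid(chromosome = chroms, alg = algs,
                       stringsAsFactors = FALSE)
  cells$n <- as.integer(tab[cbind(cells$chromosome, cells$alg)])
  K <- alg_tot[cells$alg]          # genes with this ALG genome-wide
  nn <- chr_tot[cells$chromosome]  # labeled genes on this chromosome
  cells$pvalue <- phyper(cells$n - 1L, K, tot - K, nn, lower.tail = FALSE)
  cells$padj <- p.adjust(cells$pvalue, method = "BH")
  cells$assigned <- cells$padj < threshold

  assignments <- lapply(split(cells[cells$assigned, ],
                              cells$chromosome[cells$assigned]),
                        function(d) sort(d$alg))
  unlabeled <- setdiff(unique(genome$chromosome), chroms)
  structure(list(cells = cells, assignments = assignments,
                 threshold = threshold,
                 unlabeled_chromosomes = unlabeled),
            class = "painting")
}

#' Dollo reconstruction of the ancestral linkage groups
#'
#' Treats every "join" (two reference ALGs significantly co-assigned to one
#' chromosome of a taxon) as a binary character gained once: the gain is
#' placed on the branch to the MRCA of the taxa showing the join (Dollo, no
#' reversal of the gain). Joins whose gain lies at or above the ingroup
#' ancestor are ancestral and merge reference ALGs into ancestral units;
#' younger joins are per-lineage fusion events.
#'
#' @param paintings named list of `painting` objects (or plain
#'   chromosome -> ALG-set lists), one per taxon, in a common reference ALG
#'   vocabulary.
#' @param tree `phylo` or newick string containing all painted taxa.
#' @param outgroups character vector of outgroup taxa; the ingroup ancestor
#'   is the MRCA of all non-outgroup painted taxa.
#' @param reference_algs character vector of all reference ALG ids.
#' @return object of class `alg_model`: list with `ancestral_units` (list of
#'   merged reference-ALG sets, with descriptive "A + B" names),
#'   `n_ancestral`, `events` (data.frame branch, type, join), `joins`.
#' @export
reconstruct_ancestral <- function(paintings, tree, outgroups,
                                  reference_algs) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  taxa <- names(paintings)
  if (!all(taxa %in% tree$tip.label)) stop("painted taxa missing from tree")
  ingroup <- setdiff(taxa, outgroups)
  if (length(ingroup) < 2L) stop("need >= 2 ingroup taxa")
  if (!length(intersect(outgroups, tree$tip.label))) {
    stop("need >= 1 outgroup leaf in the tree")
  }
  ntip <- ape::Ntip(tree)
  ingroup_anc <- ape::getMRCA(tree, ingroup)

  taxon_joins <- lapply(paintings, function(p) {
    sets <- if (inherits(p, "painting")) p$assignments else p
    joins <- unlist(lapply(sets, function(algs) {
      if (length(algs) < 2L) return(NULL)
      combn(sort(algs), 2L, paste, collapse = "|")
    }), use.names = FALSE)
    unique(joins)
  })
  all_joins <- sort(unique(unlist(taxon_joins, use.names = FALSE)))

  events <- list()
  ancestral_joins <- character(0)
  node_label <- function(n) {
    if (n <= ntip) tree$tip.label[n] else paste0("node", n)
  }
  for (jn in all_joins) {
    carriers <- taxa[vapply(taxon_joins, function(x) jn %in% x, logical(1))]
    gain_node <- if (length(carriers) == 1L) {
      match(carriers, tree$tip.label)
    } else {
      ape::getMRCA(tree, carriers)
    }
    # ancestral iff the gain covers the ingroup ancestor
    anc_path <- if (ingroup_anc == ntip + 1L) ingroup_anc else
      ape::nodepath(tree, from = ntip + 1L, to = ingroup_anc)
    if (gain_node %in% anc_path) {
      ancestral_joins <- c(ancestral_joins, jn)
    } else {
      events[[length(events) + 1L]] <- data.frame(
        branch = node_label(gain_node), type = "fusion", join = jn,
        stringsAsFactors = FALSE)
    }
  }

  # merge reference ALGs connected by ancestral joins (union-find)
  parent <- setNames(reference_algs, reference_algs)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (jn in ancestral_joins) {
    ab <- strsplit(jn, "|", fixed = TRUE)[[1L]]
    parent[[find(ab[1L])]] <- find(ab[2L])
  }
  comp <- vapply(reference_algs, find, character(1))
  units <- split(reference_algs, comp)
  names(units) <- vapply(units, paste, character(1), collapse = " + ")
  units <- units[order(names(units))]

  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(0), type = character(0),
               join = character(0))
  structure(list(ancestral_units = units, n_ancestral = length(units),
                 events = events_df, joins = taxon_joins,
                 ancestral_joins = ancestral_joins),
            class = "alg_model")
}

#' Count interchromosomal rearrangement events from a painting
#'
#' Builds the bipartite graph between ancestral linkage groups and extant
#' chromosomes from the significant assignments; each connected component
#' with `a` ALGs and `c` chromosomes contributes `(a - 1) + (c - 1)` events
#' (the minimum number of fusions plus fissions explaining it). In
#' translocation mode a fully connected 2x2 component counts as a single
#' reciprocal translocation.
#'
#' @param painting a `painting` object (or chromosome -> ALG-set list).
#' @param translocation_mode count complete 2 ALG x 2 chromosome components
#'   as one event.
#' @return list with `total`, `components` (data.frame n_algs, n_chroms,
#'   events, translocation).
#' @export
count_events <- function(painting, translocation_mode = FALSE) {
  sets <- if (inherits(painting, "painting")) painting$assignments else painting
  if (!length(sets)) {
    warning("empty painting; 0 events")
    return(list(total = 0L, components = data.frame()))
  }
  edges <- do.call(rbind, lapply(names(sets), function(ch) {
    if (!length(sets[[ch]])) return(NULL)
    data.frame(chromosome = ch, alg = sets[[ch]], stringsAsFactors = FALSE)
  }))
  nodes <- c(paste0("chr:", unique(edges$chromosome)),
             paste0("alg:", unique(edges$alg)))
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in seq_len(nrow(edges))) {
    a <- find(paste0("chr:", edges$chromosome[e]))
    b <- find(paste0("alg:", edges$alg[e]))
    if (a != b) parent[[a]] <- b
  }
  comp_of <- vapply(nodes, find, character(1))
  comps <- split(nodes, comp_of)
  rows <- lapply(comps, function(members) {
    a <- sum(startsWith(members, "alg:"))
    c <- sum(startsWith(members, "chr:"))
    n_edges <- sum(paste0("chr:", edges$chromosome) %in% members)
    translo <- translocation_mode && a == 2L && c == 2L && n_edges == 4L
    data.frame(n_algs = a, n_chroms = c,
               events = if (translo) 1L else (a - 1L) + (c - 1L),
               translocation = translo)
  })
  components <- do.call(rbind, rows)
  rownames(components) <- NULL
  list(total = sum(components$events), components = components)
}

#' Interchromosomal rearrangement rate
#'
#' @param events nonnegative event count.
#' @param branch_myr branch (divergence) time in Myr; the package default of
#'   500 Myr is the class-pair divergence used for echinoderm comparisons.
#' @return events per Myr, to 3 significant figures.
#' @export
rearrangement_rate <- function(events, branch_myr = 500) {
  if (branch_myr <= 0) stop("branch_myr must be > 0")
  if (events < 0) stop("events must be >= 0")
  signif(events / branch_myr, 3)
}

#' Bundle ortholog links into synteny ribbons
#'
#' Sorts ortholog links along genome 1 and merges consecutive links lying on
#' the same chromosome pair with an ordinal gap of at most `max_gap` on both
#' genomes; bundles with fewer than `min_links` links are dropped.
#'
#' @param orthologs data.frame (gene1, gene2).
#' @param genome1,genome2 data.frames (gene_id, chromosome, position).
#' @param max_gap maximum ordinal gap within a bundle (default 50).
#' @param min_links minimum links per retained bundle (default 3).
#' @return data.frame per bundle: chromosome1, chromosome2, start1, end1,
#'   start2, end2, n_links.
#' @export
synteny_bundles <- function(orthologs, genome1, genome2, max_gap = 50L,
                            min_links = 3L) {
  g1 <- genome1[match(orthologs$gene1, genome1$gene_id), ]
  g2 <- genome2[match(orthologs$gene2, genome2$gene_id), ]
  keep <- !is.na(g1$gene_id) & !is.na(g2$gene_id)
  links <- data.frame(chr1 = g1$chromosome[keep], pos1 = g1$position[keep],
                      chr2 = g2$chromosome[keep], pos2 = g2$position[keep],
                      stringsAsFactors = FALSE)
  if (!nrow(links)) return(data.frame())
  links <- links[order(links$chr1, links$pos1), ]
  bundle_id <- integer(nrow(links))
  current <- 0L
  for (i in seq_len(nrow(links))) {
    new_bundle <- i == 1L ||
      links$chr1[i] != links$chr1[i - 1L] ||
      links$chr2[i] != links$chr2[i - 1L] ||
      links$pos1[i] - links$pos1[i - 1L] > max_gap ||
      abs(links$pos2[i] - links$pos2[i - 1L]) > max_gap
    if (new_bundle) current <- current + 1L
    bundle_id[i] <- current
  }
  out <- do.call(rbind, lapply(split(links, bundle_id), function(b) {
    data.frame(chromosome1 = b$chr1[1L], chromosome2 = b$chr2[1L],
               start1 = min(b$pos1), end1 = max(b$pos1),
               start2 = min(b$pos2), end2 = max(b$pos2),
               n_links = nrow(b), stringsAsFactors = FALSE)
  }))
  out <- out[out$n_links >= min_links, , drop = FALSE]
  rownames(out) <- NULL
  out
}
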