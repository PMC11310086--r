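#' Simulate chromosome evolution along a species tree
#'
#' The ancestor carries `n_algs` chromosomes (ancestral linkage groups) of
#' `genes_per_alg` genes each. Along every branch of the supplied tree,
#' fusions (concatenate two chromosomes), fissions (split one chromosome at a
#' uniform interior point) and terminal-segment translocations are applied;
#' the number of events of each type per branch is Poisson with the
#' configured per-branch expectation. Break points are uniform among the
#' positions leaving at least `min_segment` genes (default 8) on each side,
#' so every derived segment remains detectable by the painting stage. The
#' true per-branch event log is returned alongside the leaf genomes.
#'
#' @param config a [sim_config()]; uses the `karyotype` element.
#' @return list with
#'   \item{genomes}{named list (one per leaf) of data.frames with `gene_id`,
#'     `chromosome`, `position` (0-based ordinal), `anc_gene`, `alg`}
#'   \item{tree}{the `phylo` tree used}
#'   \item{truth}{list: `events` data.frame (branch, type, n applied),
#'     `n_events` per-leaf-lineage totals, `skipped` resampled-event log,
#'     `n_anc` ancestral chromosome count}
#' @export
simulate_karyotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$karyotype
  if (any(c(k$fusion_rate, k$fission_rate, k$translocation_rate) < 0)) {
    stop("event rates must be >= 0")
  }
  tree <- ape::read.tree(text = k$tree)
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 leaves")
  set.seed(derive_seed(config$seed, "karyotype"))

  alg_names <- sprintf("ALG%02d", seq_len(k$n_algs))
  ancestor <- lapply(seq_len(k$n_algs), function(a) {
    sprintf("%s_g%03d", alg_names[a], seq_len(k$genes_per_alg))
  })
  names(ancestor) <- alg_names
  alg_of_gene <- setNames(rep(alg_names, each = k$genes_per_alg),
                          unlist(ancestor))

  n_node <- ape::Nnode(tree) + ape::Ntip(tree)
  root <- ape::Ntip(tree) + 1L
  node_label <- function(i) {
    if (i <= ape::Ntip(tree)) tree$tip.label[i] else paste0("node", i)
  }

  states <- vector("list", n_node)
  states[[root]] <- ancestor
  events <- list()
  skipped <- list()

  # minimum genes left on each side of a break — relative to chromosome ends
  # AND to internal linkage-group junctions — so that every derived segment
  # stays statistically detectable by the painting stage
  min_seg <- if (is.null(k$min_segment)) 8L else as.integer(k$min_segment)
  cut_point <- function(chrom) {
    len <- length(chrom)
    if (len < 2L * min_seg) return(NULL)
    valid <- seq.int(min_seg, len - min_seg)
    alg <- alg_of_gene[chrom]
    junctions <- which(alg[-len] != alg[-1L])
    for (j in junctions) {
      valid <- valid[abs(valid - j) >= min_seg]
    }
    if (!length(valid)) return(NULL)
    if (length(valid) == 1L) valid else sample(valid, 1L)
  }
  apply_event <- function(genome, type) {
    if (type == "fusion") {
      if (length(genome) < 2L) return(NULL)
      idx <- sample.int(length(genome), 2L)
      genome[[idx[1]]] <- c(genome[[idx[1]]], genome[[idx[2]]])
      genome[[idx[2]]] <- NULL
    } else if (type == "fission") {
      ok <- which(lengths(genome) >= 2L * min_seg)
      if (!length(ok)) return(NULL)
      i <- if (length(ok) == 1L) ok else sample(ok, 1L)
      cut <- cut_point(genome[[i]])
      if (is.null(cut)) return(NULL)
      genome <- c(genome, list(genome[[i]][-seq_len(cut)]))
      genome[[i]] <- genome[[i]][seq_len(cut)]
    } else { # translocation: swap terminal segments of two chromosomes
      ok <- which(lengths(genome) >= 2L * min_seg)
      if (length(ok) < 2L) return(NULL)
      idx <- sample(ok, 2L)
      a <- genome[[idx[1]]]; b <- genome[[idx[2]]]
      ca <- cut_point(a)
      cb <- cut_point(b)
      if (is.null(ca) || is.null(cb)) return(NULL)
      genome[[idx[1]]] <- c(a[seq_len(ca)], b[-seq_len(cb)])
      genome[[idx[2]]] <- c(b[seq_len(cb)], a[-seq_len(ca)])
    }
    genome
  }

  # preorder over edges so each child sees its parent's final state
  edge_order <- order(tree$edge[, 1L])
  for (e in edge_order) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    genome <- states[[parent]]
    n_ev <- c(fusion = rpois(1L, k$fusion_rate),
              fission = rpois(1L, k$fission_rate),
              translocation = rpois(1L, k$translocation_rate))
    todo <- sample(rep(names(n_ev), n_ev))
    applied <- character(0)
    for (type in todo) {
      out <- apply_event(genome, type)
      if (is.null(out)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(branch = node_label(child), type = type,
                     stringsAsFactors = FALSE)
      } else {
        genome <- out
        applied <- c(applied, type)
      }
    }
    if (length(applied)) {
      events[[length(events) + 1L]] <-
        data.frame(branch = node_label(child), type = applied,
                   stringsAsFactors = FALSE)
    }
    states[[child]] <- genome
  }

  genomes <- lapply(seq_len(ape::Ntip(tree)), function(i) {
    genome <- states[[i]]
    taxon <- tree$tip.label[i]
    do.call(rbind, lapply(seq_along(genome), function(ci) {
      g <- genome[[ci]]
      data.frame(gene_id = paste(taxon, g, sep = "_"),
                 chromosome = sprintf("%s_chr%02d", taxon, ci),
                 position = seq_along(g) - 1L,
                 anc_gene = g, alg = unname(alg_of_gene[g]),
                 stringsAsFactors = FALSE)
    }))
  })
  names(genomes) <- tree$tip.label

  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(0), type = character(0))
  skipped_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(branch = character(0), type = character(0))

  # per-leaf totals over the root-to-leaf path
  path_events <- vapply(seq_len(ape::Ntip(tree)), function(i) {
    path <- ape::nodepath(tree, from = root, to = i)
    sum(events_df$branch %in% vapply(path[-1L], node_label, character(1)))
  }, numeric(1))
  names(path_events) <- tree$tip.label

  list(genomes = genomes, tree = tree,
       truth = list(events = events_df, skipped = skipped_df,
                    n_events = path_events, n_anc = k$n_algs))
}

#' One-to-one ortholog pairs implied by a simulated karyotype
#'
#' Matches genes of two simulated taxa through their shared ancestral gene.
#'
#' @param karyo result of [simulate_karyotypes()].
#' @param sp1,sp2 taxon names.
#' @return data.frame (gene1, gene2).
#' @export
karyotype_orthologs <- function(karyo, sp1, sp2) {
  g1 <- karyo$genomes[[sp1]]; g2 <- karyo$genomes[[sp2]]
  if (is.null(g1) || is.null(g2)) stop("unknown taxon")
  m <- match(g1$anc_gene, g2$anc_gene)
  keep <- !is.na(m)
  data.frame(gene1 = g1$gene_id[keep], gene2 = g2$gene_id[m[keep]],
             stringsAsFactors = FALSE)
}
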