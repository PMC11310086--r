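#' Default pipeline configuration
#'
#' @param seed global integer seed; every stage derives its own substream.
#' @param n_perm permutations of the conservation test.
#' @param alpha BH-FDR threshold shared by the statistic stages.
#' @param paint_threshold adjusted-p threshold of the macrosynteny painting.
#' @param sim named list of overrides passed to [sim_config()].
#' @return nested list understood by [run_pipeline()]; serializable to YAML.
#' @export
pipeline_config <- function(seed = 1L, n_perm = 1000L, alpha = 0.05,
                            paint_threshold = 1e-5, sim = list()) {
  list(seed = as.integer(seed),
       stages = c("simulate", "cluster", "conserve", "enrich", "paint",
                  "repeats", "explant"),
       n_perm = as.integer(n_perm), alpha = alpha,
       paint_threshold = paint_threshold, sim = sim)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the requested stages in dependency order (simulate -> cluster ->
#' conserve / enrich; paint; repeats; explant), writing every statistic
#' table as TSV under `outdir` together with a provenance record. Reruns
#' with the same config and seed produce byte-identical tables.
#'
#' @param config a [pipeline_config()] list or path to a YAML file with the
#'   same structure.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  results <- list()

  sim_args <- c(list(seed = config$seed,
                     conservation_rate = 0.8, noise_sd = 0.2),
                config$sim)
  sim_args <- sim_args[!duplicated(names(sim_args), fromLast = TRUE)]
  cfg <- do.call(sim_config, sim_args)

  if ("simulate" %in% stages) {
    sim <- simulate_timecourse(cfg)
    results$sim <- sim
    for (sp in names(sim$tpm)) {
      write_expression_tsv(sim$tpm[[sp]],
                           file.path(outdir, paste0("tpm_", sp, ".tsv")))
    }
    write_tsv_table(sim$families, file.path(outdir, "families.tsv"))
    write_tsv_table(sim$truth$gene_clusters,
                    file.path(outdir, "truth_gene_clusters.tsv"))
  }

  if ("cluster" %in% stages) {
    if (is.null(results$sim)) stop("run the `simulate` stage first")
    results$clusterings <- lapply(names(results$sim$counts), function(sp) {
      counts <- results$sim$counts[[sp]]
      z <- transform_standardize(counts, tmm_factors(counts))$z
      fit <- fuzzy_cmeans(z, C = cfg$n_clusters, seed = config$seed)
      write_tsv_table(
        data.frame(gene_id = rownames(z),
                   cluster = paste0("C", fit$cluster),
                   membership_max = apply(fit$membership, 1L, max)),
        file.path(outdir, paste0("clusters_", sp, ".tsv")))
      fit
    })
    names(results$clusterings) <- names(results$sim$counts)
  }

  if ("conserve" %in% stages) {
    if (is.null(results$clusterings)) stop("run the `cluster` stage first")
    sps <- names(results$clusterings)
    hard <- lapply(sps, function(sp) {
      fit <- results$clusterings[[sp]]
      setNames(paste0("C", fit$cluster), rownames(fit$membership))
    })
    fams <- filter_families(results$sim$families, sps[1L], sps[2L])$families
    ov <- count_cluster_overlaps(hard[[1L]], hard[[2L]], fams,
                                 sps[1L], sps[2L])
    test <- permutation_test(ov, n_perm = config$n_perm, seed = config$seed,
                             alpha = config$alpha)
    results$conservation <- test
    pairs <- expand.grid(cluster1 = rownames(test$counts),
                         cluster2 = colnames(test$counts),
                         stringsAsFactors = FALSE)
    pairs$n <- as.vector(test$counts)
    pairs$pvalue <- as.vector(test$pvalue)
    pairs$padj <- as.vector(test$padj)
    pairs$significant <- as.vector(test$significant)
    write_tsv_table(pairs, file.path(outdir, "conservation_pairs.tsv"))
    ribbon <- pairs[pairs$significant, , drop = FALSE]
    ribbon$size1 <- as.integer(table(hard[[1L]])[ribbon$cluster1])
    ribbon$size2 <- as.integer(table(hard[[2L]])[ribbon$cluster2])
    write_tsv_table(ribbon, file.path(outdir, "conservation_ribbons.tsv"))
    if (length(test$conserved_genes)) {
      write_tsv_table(
        data.frame(pair = rep(names(test$conserved_genes),
                              lengths(test$conserved_genes)),
                   gene_id = unlist(test$conserved_genes, use.names = FALSE)),
        file.path(outdir, "conserved_genes.tsv"))
    }
  }

  if ("enrich" %in% stages) {
    if (is.null(results$clusterings)) stop("run the `cluster` stage first")
    sp <- names(results$clusterings)[1L]
    fit <- results$clusterings[[sp]]
    hard <- setNames(paste0("C", fit$cluster), rownames(fit$membership))
    truth_cl <- results$sim$truth$gene_clusters
    ann <- simulate_annotations(truth_cl[truth_cl$species == sp, ], cfg)
    enr <- age_and_list_enrichment(hard, ann$annotations,
                                   alpha = config$alpha)
    results$enrichment <- enr
    write_tsv_table(enr, file.path(outdir, "enrichment.tsv"))
  }

  if ("paint" %in% stages) {
    karyo <- simulate_karyotypes(cfg)
    results$karyotype <- karyo
    taxa <- names(karyo$genomes)
    outgroup <- karyo$tree$tip.label[1L]
    paintings <- lapply(karyo$genomes, function(g) {
      fisher_painting(setNames(g$alg, g$gene_id), g,
                      threshold = config$paint_threshold)
    })
    model <- reconstruct_ancestral(
      paintings, karyo$tree, outgroup,
      sprintf("ALG%02d", seq_len(cfg$karyotype$n_algs)))
    events <- lapply(paintings, count_events)
    rates <- vapply(taxa, function(tx) {
      depth <- max(ape::node.depth.edgelength(karyo$tree))
      rearrangement_rate(events[[tx]]$total, depth)
    }, numeric(1))
    results$painting <- list(paintings = paintings, model = model,
                             events = events, rates = rates)
    write_tsv_table(
      data.frame(taxon = taxa,
                 n_events = vapply(events, `[[`, numeric(1), "total"),
                 rate_per_myr = rates),
      file.path(outdir, "rearrangement_rates.tsv"))
  }

  if ("repeats" %in% stages) {
    rep_sim <- simulate_repeats_and_degs(cfg)
    results$repeats <- rep_sim
    land <- repeat_landscape(rep_sim$repeats, rep_sim$region_length)
    write_tsv_table(land, file.path(outdir, "repeat_landscape.tsv"))
    assoc <- breakpoint_association_test(
      rep_sim$repeats, rep_sim$breakpoints, rep_sim$region_length,
      window = cfg$repeat_region$window_bp, n_perm = config$n_perm,
      seed = config$seed, alpha = config$alpha)
    results$repeat_association <- assoc
    write_tsv_table(assoc, file.path(outdir, "repeat_breakpoint_tests.tsv"))
  }

  if ("explant" %in% stages) {
    if (is.null(results$repeats)) {
      results$repeats <- simulate_repeats_and_degs(cfg)
    }
    sets <- deg_filter(results$repeats$degs)
    cats <- categorize_degs(sets$distal, sets$proximal)
    results$explant <- cats
    write_tsv_table(cats$categories, file.path(outdir, "deg_categories.tsv"))
    write_tsv_table(cats$summary, file.path(outdir, "deg_summary.tsv"))
  }

  provenance <- data.frame(
    key = c("seed", "n_perm", "alpha", "package_version"),
    value = c(config$seed, config$n_perm, config$alpha,
              as.character(utils::packageVersion("ophioregen"))))
  write_tsv_table(provenance, file.path(outdir, "provenance.tsv"))
  invisible(results)
}

#' Human-readable summary of a pipeline run
#'
#' @param outdir directory written by [run_pipeline()].
#' @param path optional file to write the report to (default
#'   `outdir/report.txt`).
#' @return the report lines, invisibly.
#' @export
pipeline_report <- function(outdir, path = file.path(outdir, "report.txt")) {
  lines <- c("ophioregen pipeline report", strrep("=", 26))
  f <- function(...) file.path(outdir, ...)
  if (file.exists(f("clusters_sp1.tsv"))) {
    cl <- read_tsv_table(f("clusters_sp1.tsv"))
    lines <- c(lines, sprintf("species 1: %d genes in %d clusters",
                              nrow(cl), length(unique(cl$cluster))))
  }
  if (file.exists(f("conservation_pairs.tsv"))) {
    pairs <- read_tsv_table(f("conservation_pairs.tsv"))
    n_sig <- sum(pairs$significant)
    lines <- c(lines, if (n_sig == 0) "no conserved clusters" else
      sprintf("%d significant cluster pairs: %s", n_sig,
              paste(pairs$cluster1[pairs$significant],
                    pairs$cluster2[pairs$significant],
                    sep = "~", collapse = ", ")))
    if (file.exists(f("conserved_genes.tsv"))) {
      genes <- read_tsv_table(f("conserved_genes.tsv"))
      lines <- c(lines, sprintf("conserved genes (focal species): %d",
                                length(unique(genes$gene_id))))
    }
  }
  if (file.exists(f("rearrangement_rates.tsv"))) {
    rates <- read_tsv_table(f("rearrangement_rates.tsv"))
    lines <- c(lines, sprintf("%s: %d events, %.3g events/Myr",
                              rates$taxon, rates$n_events,
                              rates$rate_per_myr))
  }
  if (file.exists(f("repeat_breakpoint_tests.tsv"))) {
    assoc <- read_tsv_table(f("repeat_breakpoint_tests.tsv"))
    lines <- c(lines, sprintf("repeat families associated with breakpoints: %d",
                              sum(assoc$significant)))
  }
  if (file.exists(f("deg_summary.tsv"))) {
    s <- read_tsv_table(f("deg_summary.tsv"))
    lines <- c(lines,
               sprintf("proximal DEGs shared with distal: %.0f%%",
                       100 * s$prop_proximal_shared),
               sprintf("distal-specific DEGs: %.0f%%",
                       100 * s$prop_distal_specific))
  }
  writeLines(lines, path)
  invisible(lines)
}
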