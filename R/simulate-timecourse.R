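#' Simulate multi-species regeneration time courses with planted clusters
#'
#' Generates one expression matrix per species plus the homologous gene
#' family table linking them, with a planted truth table. Each gene's TPM
#' profile is a unimodal cluster template (Gaussian bump over the ordered
#' stage index) plus Gaussian noise, scaled by a lognormal gene-level
#' abundance; a Poisson count layer is derived for normalization tests. A
#' fraction `conservation_rate` of families is "conserved": all member genes
#' in all species follow the family's template cluster; genes of the
#' remaining families are assigned to clusters independently at random.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \item{tpm}{named list of gene x sample TPM matrices, one per species}
#'   \item{counts}{matching Poisson count matrices}
#'   \item{samples}{data.frame of sample, stage, regenerating flags}
#'   \item{families}{data.frame (family_id, species, gene_id)}
#'   \item{truth}{list with `gene_clusters` (species, gene_id, cluster) and
#'     `family_conserved` (family_id, conserved, template_cluster)}
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "timecourse"))

  n_stage <- length(config$stages)
  templates <- cluster_templates(config$n_clusters, n_stage,
                                 config$template_width)
  species <- sprintf("sp%d", seq_len(config$n_species))

  conserved <- runif(config$n_families) < config$conservation_rate
  template_cluster <- sample.int(config$n_clusters, config$n_families,
                                 replace = TRUE)
  fam_ids <- sprintf("fam%04d", seq_len(config$n_families))

  # per-species family sizes, uniform on 1..family_size_max
  sizes <- matrix(
    sample.int(config$family_size_max,
               config$n_families * config$n_species, replace = TRUE),
    nrow = config$n_families
  )

  fam_rows <- list()
  truth_rows <- list()
  tpm <- counts <- vector("list", config$n_species)
  names(tpm) <- names(counts) <- species
  # per-sample sequencing depth scalar for the count layer (shared across
  # species for simplicity; TMM only sees within-species columns)
  depth <- runif(n_stage, 5, 20)

  for (s in seq_len(config$n_species)) {
    n_genes_sp <- sum(sizes[, s])
    gene_ids <- sprintf("%s_g%05d", species[s], seq_len(n_genes_sp))
    gene_fam <- rep(seq_len(config$n_families), sizes[, s])
    cl <- ifelse(rep(conserved, sizes[, s]),
                 rep(template_cluster, sizes[, s]),
                 sample.int(config$n_clusters, n_genes_sp, replace = TRUE))
    abundance <- rlnorm(n_genes_sp, meanlog = 3, sdlog = 1)
    noise <- matrix(rnorm(n_genes_sp * n_stage, sd = config$noise_sd),
                    n_genes_sp, n_stage)
    x <- pmax(templates[cl, , drop = FALSE] + noise, 0) * abundance
    dimnames(x) <- list(gene_ids, paste(species[s], config$stages, sep = "."))
    tpm[[s]] <- x
    counts[[s]] <- matrix(rpois(length(x), t(t(x) * depth)),
                          nrow(x), ncol(x), dimnames = dimnames(x))
    fam_rows[[s]] <- data.frame(family_id = fam_ids[gene_fam],
                                species = species[s], gene_id = gene_ids,
                                stringsAsFactors = FALSE)
    truth_rows[[s]] <- data.frame(species = species[s], gene_id = gene_ids,
                                  cluster = cl, stringsAsFactors = FALSE)
  }

  samples <- data.frame(stage = config$stages,
                        regenerating = config$regenerating,
                        stringsAsFactors = FALSE)
  list(
    tpm = tpm, counts = counts, samples = samples,
    families = do.call(rbind, fam_rows),
    truth = list(
      gene_clusters = do.call(rbind, truth_rows),
      family_conserved = data.frame(family_id = fam_ids,
                                    conserved = conserved,
                                    template_cluster = template_cluster,
                                    stringsAsFactors = FALSE)
    )
  )
}
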