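#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' emulate the structure of an arm-regeneration study: an eight-sample time
#' course (one non-regenerating control plus seven regeneration stages),
#' multi-species homologous gene families with small per-species sizes, a
#' small echinoderm-like karyotype history, and a repeat-rich Hox-scale
#' region with planted breakpoint associations.
#'
#' @param seed integer; the single global seed. All stages derive their own
#'   substream from it, so identical config + seed gives identical output.
#' @param n_species number of species sharing the gene families.
#' @param stages character vector of ordered stage labels (sample order is
#'   biological time order).
#' @param regenerating logical flag per stage; the first default sample is the
#'   non-regenerating control.
#' @param n_clusters number of planted temporal co-expression clusters.
#' @param n_families number of homologous gene families.
#' @param conservation_rate fraction rho in `[0, 1]` of families whose member
#'   genes follow the same cluster template in every species; remaining
#'   families have independently random cluster assignments per gene.
#' @param noise_sd Gaussian noise s.d. added to the standardized template
#'   before abundance scaling.
#' @param family_size_max maximum gene count per species per family (sizes are
#'   uniform on `1:family_size_max`).
#' @param template_width s.d. (in stage units) of the Gaussian bump template.
#' @param n_terms number of annotation terms to simulate.
#' @param term_prevalence background probability that a gene carries a term.
#' @param enrichment_odds odds ratio theta of planted (term, cluster) pairs.
#' @param karyotype list with elements `n_algs`, `genes_per_alg`, per-branch
#'   expected event counts `fusion_rate`, `fission_rate`,
#'   `translocation_rate`, a `tree` newick string whose first-listed
#'   basal leaf is treated as the outgroup, and optionally `min_segment`
#'   (minimum genes per derived segment, default 8).
#' @param repeat_region list with `length_bp`, `n_breakpoints`,
#'   `clustering_weight` (fraction pi of an associated family's copies placed
#'   near breakpoints), `copies_per_family`, `n_families`, `window_bp`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 2L,
                       stages = c("control", "48hpa", "72hpa", "stage3",
                                  "stage4", "stage5", "50pD", "50pP"),
                       regenerating = c(FALSE, rep(TRUE, length(stages) - 1L)),
                       n_clusters = 5L,
                       n_families = 300L,
                       conservation_rate = 0.5,
                       noise_sd = 0.1,
                       family_size_max = 4L,
                       template_width = 1.5,
                       n_terms = 20L,
                       term_prevalence = 0.1,
                       enrichment_odds = 1,
                       karyotype = list(n_algs = 24L, genes_per_alg = 40L,
                                        fusion_rate = 1, fission_rate = 0.5,
                                        translocation_rate = 0.25,
                                        tree = "(outgroup:500,(taxonA:250,taxonB:250):250);"),
                       repeat_region = list(length_bp = 500000L,
                                            n_breakpoints = 3L,
                                            clustering_weight = 0,
                                            copies_per_family = 100L,
                                            n_families = 10L,
                                            window_bp = 10000L)) {
  .check_count(seed, "seed", min = 0L)
  .check_count(n_species, "n_species")
  .check_count(n_clusters, "n_clusters", min = 2L)
  .check_count(n_families, "n_families")
  .check_fraction(conservation_rate, "conservation_rate")
  .check_fraction(repeat_region$clustering_weight, "repeat_region$clustering_weight")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (enrichment_odds <= 0) stop("`enrichment_odds` must be positive")
  .check_count(family_size_max, "family_size_max")
  if (length(stages) < 2L) stop("need at least 2 samples per species")
  if (length(stages) < n_clusters) {
    stop("fewer stages (", length(stages), ") than clusters requested (",
         n_clusters, ")")
  }
  if (length(regenerating) != length(stages)) {
    stop("`regenerating` must align with `stages`")
  }
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         stages = stages, regenerating = regenerating,
         n_clusters = as.integer(n_clusters),
         n_families = as.integer(n_families),
         conservation_rate = conservation_rate, noise_sd = noise_sd,
         family_size_max = as.integer(family_size_max),
         template_width = template_width,
         n_terms = as.integer(n_terms), term_prevalence = term_prevalence,
         enrichment_odds = enrichment_odds,
         karyotype = karyotype, repeat_region = repeat_region),
    class = "sim_config"
  )
}

#' Cluster template profiles
#'
#' Unimodal Gaussian-bump templates over the ordered stage index, one per
#' cluster, with peaks evenly spaced across the time course.
#'
#' @param n_clusters number of templates.
#' @param n_stages number of ordered stages.
#' @param width bump s.d. in stage units.
#' @return matrix `n_clusters x n_stages`.
#' @export
cluster_templates <- function(n_clusters, n_stages, width = 1.5) {
  peaks <- seq(1, n_stages, length.out = n_clusters)
  t(vapply(peaks, function(p) {
    exp(-((seq_len(n_stages) - p)^2) / (2 * width^2))
  }, numeric(n_stages)))
}
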