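test_that("identical config and seed give identical outputs", {
  cfg <- sim_config(seed = 11, n_families = 50)
  s1 <- simulate_timecourse(cfg)
  s2 <- simulate_timecourse(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_timecourse(sim_config(seed = 12, n_families = 50))
  expect_false(identical(s1$tpm$sp1, s3$tpm$sp1))

  k1 <- simulate_karyotypes(cfg)
  expect_identical(k1, simulate_karyotypes(cfg))
  r1 <- simulate_repeats_and_degs(cfg)
  expect_identical(r1, simulate_repeats_and_degs(cfg))
})

test_that("noise-free fully conserved families lie on their templates and give a diagonal overlap", {
  cfg <- sim_config(seed = 2, conservation_rate = 1, noise_sd = 0,
                    n_families = 60)
  sim <- simulate_timecourse(cfg)
  templates <- cluster_templates(cfg$n_clusters, length(cfg$stages))
  tr <- sim$truth$gene_clusters
  tr1 <- tr[tr$species == "sp1", ]
  x <- sim$tpm$sp1
  for (i in seq_len(50)) {
    profile <- x[tr1$gene_id[i], ]
    tmpl <- templates[tr1$cluster[i], ]
    expect_equal(profile / max(profile), tmpl / max(tmpl),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  ov <- count_cluster_overlaps(truth_hard(sim, "sp1"), truth_hard(sim, "sp2"),
                               sim$families, "sp1", "sp2")
  off <- ov$counts; diag(off) <- 0L
  expect_true(all(off == 0))
  expect_true(all(diag(ov$counts) > 0))
})

test_that("with no conservation the mean overlap matches the independence expectation", {
  # one gene per family per species, so n_ij counts families and the
  # independence oracle |c_i||c_j|/n applies exactly
  acc <- exp_acc <- matrix(0, 5, 5)
  n_sims <- 200
  for (s in seq_len(n_sims)) {
    cfg <- sim_config(seed = 1000 + s, conservation_rate = 0,
                      n_families = 100, family_size_max = 1)
    sim <- simulate_timecourse(cfg)
    h1 <- truth_hard(sim, "sp1"); h2 <- truth_hard(sim, "sp2")
    ov <- count_cluster_overlaps(h1, h2, sim$families, "sp1", "sp2")
    cn <- matrix(0, 5, 5, dimnames = list(paste0("C", 1:5), paste0("C", 1:5)))
    cn[rownames(ov$counts), colnames(ov$counts)] <- ov$counts
    acc <- acc + cn
    sz1 <- table(factor(h1, levels = paste0("C", 1:5)))
    sz2 <- table(factor(h2, levels = paste0("C", 1:5)))
    exp_acc <- exp_acc + outer(as.numeric(sz1), as.numeric(sz2)) / length(h1)
  }
  expect_lt(max(abs(acc - exp_acc) / n_sims), 0.75)
})

test_that("simulated structure respects the configured bounds", {
  cfg <- sim_config(seed = 4, n_families = 80, family_size_max = 3)
  sim <- simulate_timecourse(cfg)
  sizes <- table(sim$families$family_id, sim$families$species)
  expect_true(all(sizes >= 1 & sizes <= 3))
  # every gene appears exactly once in its truth table
  expect_false(anyDuplicated(sim$truth$gene_clusters$gene_id) > 0)
  expect_setequal(sim$truth$gene_clusters$gene_id, sim$families$gene_id)
  expect_true(all(sim$counts$sp1 == floor(sim$counts$sp1)))
  expect_true(all(sim$tpm$sp1 >= 0))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(conservation_rate = 1.2), "conservation_rate")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_clusters = 9, stages = letters[1:5]), "fewer stages")
  expect_error(sim_config(n_clusters = 1), "n_clusters")
  expect_error(sim_config(enrichment_odds = 0), "enrichment_odds")
})

test_that("karyotype simulation honours zero and single-event histories", {
  base_tree <- "(outgroup:500,(taxonA:250,taxonB:250):250);"
  cfg0 <- sim_config(seed = 5, karyotype = list(
    n_algs = 6, genes_per_alg = 30, fusion_rate = 0, fission_rate = 0,
    translocation_rate = 0, tree = base_tree))
  k0 <- simulate_karyotypes(cfg0)
  expect_equal(nrow(k0$truth$events), 0)
  for (g in k0$genomes) expect_equal(length(unique(g$chromosome)), 6)
  # all taxa identical to the ancestor: every chromosome is one pure ALG
  expect_true(all(table(k0$genomes$taxonA$chromosome,
                        k0$genomes$taxonA$alg) %in% c(0, 30)))

  # a fusion reduces the chromosome count by one
  found <- FALSE
  for (s in 1:50) {
    cfgf <- sim_config(seed = s, karyotype = list(
      n_algs = 6, genes_per_alg = 30, fusion_rate = 0.3, fission_rate = 0,
      translocation_rate = 0, tree = base_tree))
    kf <- simulate_karyotypes(cfgf)
    ev <- kf$truth$events
    one <- names(which(kf$truth$n_events == 1))
    one <- intersect(one, ev$branch[ev$type == "fusion"])
    if (length(one)) {
      tx <- one[1]
      expect_equal(length(unique(kf$genomes[[tx]]$chromosome)), 5)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("per-branch event counts follow the configured Poisson mean", {
  tot <- 0; n_branch <- 0
  for (s in 1:150) {
    cfg <- sim_config(seed = 3000 + s, karyotype = list(
      n_algs = 12, genes_per_alg = 64, fusion_rate = 1.5, fission_rate = 1,
      translocation_rate = 0.5,
      tree = "(outgroup:500,(taxonA:250,taxonB:250):250);"))
    k <- simulate_karyotypes(cfg)
    tot <- tot + nrow(k$truth$events) + nrow(k$truth$skipped)
    n_branch <- n_branch + 4   # edges of the rooted 3-leaf tree
  }
  expect_equal(tot / n_branch, 3, tolerance = 0.25 / 3)
})

test_that("planted DEG categories are realized with the planted signs", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_repeats_and_degs(cfg)
  d <- sim$degs
  wide <- merge(d[d$contrast == "distal", c("gene_id", "log2fc")],
                d[d$contrast == "proximal", c("gene_id", "log2fc")],
                by = "gene_id", suffixes = c("_d", "_p"))
  tr <- sim$truth$deg_category
  opp <- tr$gene_id[tr$category == "opposite"]
  expect_true(all(sign(wide$log2fc_d[match(opp, wide$gene_id)]) ==
                    -sign(wide$log2fc_p[match(opp, wide$gene_id)])))
  shr <- tr$gene_id[tr$category == "shared"]
  expect_true(all(sign(wide$log2fc_d[match(shr, wide$gene_id)]) ==
                    sign(wide$log2fc_p[match(shr, wide$gene_id)])))
})

test_that("repeat placement is uniform when the clustering weight is zero", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_repeats_and_degs(cfg)
  # no family should be flagged associated, and positions should span the region
  expect_false(any(sim$truth$repeat_assoc$associated))
  expect_true(all(sim$repeats$start >= 0))
  expect_true(all(sim$repeats$end <= sim$region_length))
  mid <- sim$region_length / 2
  expect_equal(mean(sim$repeats$start < mid), 0.5, tolerance = 0.05)
})
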