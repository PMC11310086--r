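test_that("overlap counts follow the hand-derived examples", {
  fam <- data.frame(
    family_id = c("f1", "f1", "f2", "f2"),
    species = c("sp1", "sp2", "sp1", "sp2"),
    gene_id = c("a1", "b1", "a2", "b2"))
  clust1 <- c(a1 = "A", a2 = "A")
  clust2 <- c(b1 = "B", b2 = "C")
  ov <- count_cluster_overlaps(clust1, clust2, fam, "sp1", "sp2")
  expect_equal(ov$counts["A", "B"], 1L)
  expect_equal(ov$counts["A", "C"], 1L)

  # two homologues in the same partner cluster count the gene once
  fam2 <- data.frame(
    family_id = c("f1", "f1", "f1"),
    species = c("sp1", "sp2", "sp2"),
    gene_id = c("a1", "b1", "b2"))
  ov2 <- count_cluster_overlaps(c(a1 = "A"), c(b1 = "B", b2 = "B"),
                                fam2, "sp1", "sp2")
  expect_equal(ov2$counts["A", "B"], 1L)

  # no shared families: all-zero counts and full coverage report
  fam3 <- data.frame(family_id = "f9", species = "sp3", gene_id = "x")
  ov3 <- count_cluster_overlaps(clust1, clust2, fam3, "sp1", "sp2")
  expect_true(all(ov3$counts == 0))
  expect_setequal(ov3$coverage$sp1_unmatched, c("a1", "a2"))
})

test_that("the empirical p-value floor is 1/(N+1)", {
  fam <- data.frame(
    family_id = rep(paste0("f", 1:20), 2),
    species = rep(c("sp1", "sp2"), each = 20),
    gene_id = c(paste0("a", 1:20), paste0("b", 1:20)))
  clust1 <- setNames(rep(c("A", "B"), each = 10), paste0("a", 1:20))
  clust2 <- setNames(rep(c("X", "Y"), each = 10), paste0("b", 1:20))
  ov <- count_cluster_overlaps(clust1, clust2, fam, "sp1", "sp2")
  res <- permutation_test(ov, n_perm = 99, seed = 1)
  expect_true(all(res$pvalue >= 1 / 100))
  expect_true(all(res$pvalue <= 1))
  expect_true(all(res$padj >= res$pvalue))
  expect_error(permutation_test(ov, n_perm = 0), "n_perm")
  # determinism
  res2 <- permutation_test(ov, n_perm = 99, seed = 1)
  expect_identical(res$pvalue, res2$pvalue)
})

test_that("sampled null matches exhaustive enumeration over label permutations", {
  # 4 species-2 genes -> 24 permutations enumerable exactly
  fam <- data.frame(
    family_id = c("f1", "f1", "f2", "f2", "f3", "f3", "f3", "f3"),
    species = c("sp1", "sp2", "sp1", "sp2", "sp1", "sp1", "sp2", "sp2"),
    gene_id = c("a1", "b1", "a2", "b2", "a3", "a4", "b3", "b4"))
  clust1 <- c(a1 = "A", a2 = "A", a3 = "B", a4 = "B")
  clust2 <- c(b1 = "X", b2 = "X", b3 = "Y", b4 = "Y")
  ov <- count_cluster_overlaps(clust1, clust2, fam, "sp1", "sp2")
  res <- permutation_test(ov, n_perm = 10000, seed = 2, keep_null = TRUE)

  genes2 <- ov$genes2
  lab2 <- ov$lab2
  perms <- all_perms(seq_along(genes2))
  B <- as.matrix(ov$incidence) > 0
  exact_counts <- vapply(perms, function(p) {
    lab <- lab2[p]
    sapply(c("X", "Y"), function(j) {
      sapply(c("A", "B"), function(i) {
        sum(vapply(which(unname(clust1[ov$genes1]) == i), function(g)
          any(lab[B[g, ]] == j), logical(1)))
      })
    })
  }, matrix(0, 2, 2))

  for (i in 1:2) for (j in 1:2) {
    exact <- table(factor(exact_counts[i, j, ], levels = 0:4)) / length(perms)
    sampled <- table(factor(res$null[, i, j], levels = 0:4)) / res$n_perm
    tv <- 0.5 * sum(abs(exact - sampled))
    expect_lt(tv, 0.02)
  }
})

test_that("a planted diagonal correspondence is recovered and nothing else", {
  cfg <- sim_config(seed = 31, conservation_rate = 1, noise_sd = 0.1,
                    n_families = 100)
  sim <- simulate_timecourse(cfg)
  fams <- filter_families(sim$families, "sp1", "sp2")$families
  ov <- count_cluster_overlaps(truth_hard(sim, "sp1"), truth_hard(sim, "sp2"),
                               fams, "sp1", "sp2")
  res <- permutation_test(ov, n_perm = 500, seed = 1)
  expect_true(all(diag(res$significant)))
  off <- res$significant; diag(off) <- FALSE
  expect_false(any(off))
  # conserved gene lists are subsets of the focal cluster membership
  h1 <- truth_hard(sim, "sp1")
  for (pair in names(res$conserved_genes)) {
    i <- strsplit(pair, "|", fixed = TRUE)[[1]][1]
    expect_true(all(h1[res$conserved_genes[[pair]]] == i))
  }
})

fake_test <- function(sig_pairs, conserved, sp1 = "A", sp2 = "B",
                      clusters1 = c("A1", "A2"), clusters2 = c("B1", "B2")) {
  sig <- matrix(FALSE, length(clusters1), length(clusters2),
                dimnames = list(clusters1, clusters2))
  for (p in sig_pairs) sig[p[1], p[2]] <- TRUE
  structure(list(counts = sig * 1L, significant = sig,
                 conserved_genes = conserved, sp1 = sp1, sp2 = sp2),
            class = "overlap_test")
}

test_that("three-way consistency intersects clusters and gene lists", {
  ab <- fake_test(list(c("A1", "B1")), list("A1|B1" = c("g1", "g2", "g3")))
  ac <- fake_test(list(c("A1", "B2")), list("A1|B2" = c("g1", "g2", "g9")),
                  sp2 = "C")
  out <- threeway_consistency(ab, ac)
  expect_equal(out$clusters, "A1")
  expect_equal(out$genes, c("g1", "g2"))

  none <- fake_test(list(), list())
  empty <- threeway_consistency(ab, none)
  expect_equal(length(empty$clusters), 0)
  expect_equal(length(empty$genes), 0)
  bad <- fake_test(list(), list(), sp1 = "Z")
  expect_error(threeway_consistency(ab, bad), "focal")
})

test_that("homology breakdown partitions conserved genes exhaustively", {
  genes <- paste0("g", 1:10)
  ab <- fake_test(list(c("A1", "B1")), list("A1|B1" = genes))
  # 3 genes also conserved with C, 3 with homologue but divergent, 4 without
  ac <- fake_test(list(c("A1", "B1")), list("A1|B1" = genes[1:3]), sp2 = "C")
  fam_c <- rbind(
    data.frame(family_id = paste0("f", 1:6), species = "sp1",
               gene_id = genes[1:6]),
    data.frame(family_id = paste0("f", 1:6), species = "spC",
               gene_id = paste0("c", 1:6)))
  out <- homology_breakdown(ab, ac, fam_c, "sp1", "spC")
  expect_equal(out$n[out$category == "no_homologue"], 4L)
  expect_equal(out$n[out$category == "divergent_expression"], 3L)
  expect_equal(out$n[out$category == "conserved"], 3L)
  expect_equal(sum(out$fraction), 1)

  # empty third-species table: everything lacks a homologue
  out0 <- homology_breakdown(ab, ac, fam_c[fam_c$species == "sp1", ],
                             "sp1", "spC")
  expect_equal(out0$fraction[out0$category == "no_homologue"], 1)
})

test_that("heterochrony report flags the inverted pair", {
  clusters1 <- paste0("A", 1:5); clusters2 <- paste0("B", 1:5)
  collinear <- fake_test(lapply(1:5, function(i)
    c(paste0("A", i), paste0("B", i))), list(),
    clusters1 = clusters1, clusters2 = clusters2)
  o1 <- setNames(1:5, clusters1); o2 <- setNames(1:5, clusters2)
  out <- heterochrony_report(collinear, o1, o2)
  expect_equal(out$tau, 1)

  # invert one match: A5 pairs with B1
  pairs <- c(lapply(1:4, function(i) c(paste0("A", i), paste0("B", i))),
             list(c("A5", "B1")))
  bent <- fake_test(pairs, list(), clusters1 = clusters1,
                    clusters2 = clusters2)
  out2 <- heterochrony_report(bent, o1, o2)
  expect_lt(out2$tau, 1)
  expect_equal(unname(unlist(out2$outliers[1, c("cluster1", "cluster2")])),
               c("A5", "B1"))
  expect_equal(out2$outliers$tau_gain[1], 1 - out2$tau)

  # two pairs: tau is +-1
  two <- fake_test(list(c("A1", "B2"), c("A2", "B1")), list(),
                   clusters1 = clusters1, clusters2 = clusters2)
  expect_equal(abs(heterochrony_report(two, o1, o2)$tau), 1)
})
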