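test_that("ALG labels propagate through one-to-one orthologs only", {
  ref <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "C")
  pairs <- data.frame(gene1 = c("r1", "r2", "r3", "r9"),
                      gene2 = c("t1", "t2", "t3", "t9"))
  out <- propagate_alg_labels(ref, pairs)
  expect_equal(out, c(t1 = "A", t2 = "A", t3 = "B"))
  # labels never invented beyond the reference vocabulary
  expect_true(all(out %in% ref))
  expect_equal(length(propagate_alg_labels(ref, pairs[0, ])), 0)
  dup <- rbind(pairs, data.frame(gene1 = "r1", gene2 = "t5"))
  expect_error(propagate_alg_labels(ref, dup), "one-to-one")
})

test_that("painting assigns a pure chromosome and both halves of a fusion", {
  set.seed(10)
  n_algs <- 20
  algs <- sprintf("ALG%02d", 1:n_algs)
  # 1000 background genes spread evenly, 50-gene focus chromosome all ALG01
  genome <- data.frame(
    gene_id = sprintf("g%04d", 1:1000),
    chromosome = rep(sprintf("chr%02d", 1:20), each = 50),
    position = rep(0:49, 20))
  labels <- setNames(rep(algs, 50), genome$gene_id)
  labels[genome$chromosome == "chr01"] <- "ALG01"
  p <- fisher_painting(labels, genome)
  expect_true("ALG01" %in% p$assignments[["chr01"]])
  cell <- p$cells[p$cells$chromosome == "chr01" & p$cells$alg == "ALG01", ]
  expect_lt(cell$padj, 1e-5)

  # fused chromosome carrying two planted ALGs in halves
  labels2 <- labels
  labels2[genome$chromosome == "chr02"] <-
    rep(c("ALG05", "ALG06"), each = 25)
  p2 <- fisher_painting(labels2, genome)
  expect_true(all(c("ALG05", "ALG06") %in% p2$assignments[["chr02"]]))
})

test_that("painting p-values equal one-sided Fisher exact tests", {
  set.seed(15)
  genome <- data.frame(gene_id = sprintf("g%03d", 1:200),
                       chromosome = sample(paste0("chr", 1:4), 200, TRUE),
                       position = 1:200)
  labels <- setNames(sample(paste0("ALG", 1:5), 200, TRUE), genome$gene_id)
  p <- fisher_painting(labels, genome)
  for (r in sample(nrow(p$cells), 10)) {
    cell <- p$cells[r, ]
    on_c <- genome$chromosome == cell$chromosome
    is_a <- labels[genome$gene_id] == cell$alg
    tab <- matrix(c(sum(on_c & is_a), sum(on_c & !is_a),
                    sum(!on_c & is_a), sum(!on_c & !is_a)), 2, 2)
    expect_equal(cell$pvalue,
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("random labels essentially never paint at the 1e-5 threshold", {
  false_seeds <- 0
  for (s in 1:20) {
    set.seed(s)
    genome <- data.frame(gene_id = sprintf("g%03d", 1:500),
                         chromosome = sample(sprintf("chr%02d", 1:10), 500,
                                             replace = TRUE),
                         position = 1:500)
    labels <- setNames(sample(sprintf("ALG%02d", 1:20), 500, replace = TRUE),
                       genome$gene_id)
    if (length(fisher_painting(labels, genome)$assignments)) {
      false_seeds <- false_seeds + 1
    }
  }
  expect_lte(false_seeds, 1)
})

test_that("Dollo reconstruction separates ancestral from derived joins", {
  tree <- "(outgroup:500,((inA:200,inB:200):100,inC:300):200);"
  algs <- c("A", "B", "C", "D")
  identity_painting <- function(extra = list()) {
    base <- list(chr1 = "A", chr2 = "B", chr3 = "C", chr4 = "D")
    for (nm in names(extra)) base[[nm]] <- extra[[nm]]
    base
  }
  # join A|B in all ingroups and the outgroup: ancestral, no event
  paintings <- list(
    outgroup = identity_painting(list(chr1 = c("A", "B"), chr2 = NULL)),
    inA = identity_painting(list(chr1 = c("A", "B"), chr2 = NULL)),
    inB = identity_painting(list(chr1 = c("A", "B"), chr2 = NULL)),
    inC = identity_painting(list(chr1 = c("A", "B"), chr2 = NULL)))
  m <- reconstruct_ancestral(paintings, tree, "outgroup", algs)
  expect_equal(m$n_ancestral, 3)
  expect_equal(nrow(m$events), 0)
  expect_true("A + B" %in% names(m$ancestral_units))

  # join C|D in a single ingroup leaf: derived fusion on its branch
  paintings2 <- list(
    outgroup = identity_painting(),
    inA = identity_painting(list(chr3 = c("C", "D"), chr4 = NULL)),
    inB = identity_painting(),
    inC = identity_painting())
  m2 <- reconstruct_ancestral(paintings2, tree, "outgroup", algs)
  expect_equal(m2$n_ancestral, 4)
  expect_equal(m2$events$branch, "inA")
  expect_equal(m2$events$type, "fusion")

  # join shared by the two sister ingroups only: event on their stem branch
  paintings3 <- list(
    outgroup = identity_painting(),
    inA = identity_painting(list(chr1 = c("A", "B"), chr2 = NULL)),
    inB = identity_painting(list(chr1 = c("A", "B"), chr2 = NULL)),
    inC = identity_painting())
  m3 <- reconstruct_ancestral(paintings3, tree, "outgroup", algs)
  expect_equal(m3$n_ancestral, 4)
  expect_equal(nrow(m3$events), 1)
})

test_that("event counting follows the bipartite component formula", {
  # identity: no event
  identity <- as.list(setNames(LETTERS[1:5], paste0("chr", 1:5)))
  expect_equal(count_events(identity)$total, 0)
  # one fusion
  expect_equal(count_events(list(chr1 = c("A", "B"), chr2 = "C"))$total, 1)
  # one fission
  expect_equal(count_events(list(chr1 = "A", chr2 = "A"))$total, 1)
  # fully connected 2x2: 2 by default, 1 in translocation mode
  sq <- list(chr1 = c("A", "B"), chr2 = c("A", "B"))
  expect_equal(count_events(sq)$total, 2)
  expect_equal(count_events(sq, translocation_mode = TRUE)$total, 1)
  expect_warning(out <- count_events(list()), "empty")
  expect_equal(out$total, 0)
})

test_that("rearrangement rates reproduce the published worked examples", {
  expect_equal(rearrangement_rate(26, 500), 0.052)
  expect_equal(rearrangement_rate(5, 500), 0.01)
  expect_equal(rearrangement_rate(1, 500), 0.002)
  expect_equal(rearrangement_rate(0, 500), 0)
  expect_error(rearrangement_rate(3, 0), "branch_myr")
})

test_that("simulated histories are recovered exactly by painting plus counting", {
  checked <- 0
  for (s in 1:6) {
    cfg <- sim_config(seed = s, karyotype = list(
      n_algs = 20, genes_per_alg = 60, min_segment = 25,
      fusion_rate = 1, fission_rate = 0.75, translocation_rate = 0,
      tree = "(outgroup:500,(taxonA:250,taxonB:250):250);"))
    k <- simulate_karyotypes(cfg)
    for (tx in c("taxonA", "taxonB")) {
      g <- k$genomes[[tx]]
      truth_pairs <- unique(g[, c("chromosome", "alg")])
      tp <- lapply(split(truth_pairs$alg, truth_pairs$chromosome), sort)
      if (count_events(tp)$total != unname(k$truth$n_events[tx])) next
      checked <- checked + 1
      p <- fisher_painting(setNames(g$alg, g$gene_id), g)
      expect_equal(count_events(p)$total, unname(k$truth$n_events[tx]))
      expect_identical(lapply(p$assignments, sort)[sort(names(tp))],
                       tp[sort(names(tp))])
    }
  }
  expect_gte(checked, 8)
})

test_that("fusion arithmetic links chromosome counts to event counts", {
  for (s in 1:5) {
    cfg <- sim_config(seed = 40 + s, karyotype = list(
      n_algs = 15, genes_per_alg = 40, min_segment = 10,
      fusion_rate = 1, fission_rate = 1, translocation_rate = 0,
      tree = "(outgroup:500,(taxonA:250,taxonB:250):250);"))
    k <- simulate_karyotypes(cfg)
    tree <- k$tree
    root <- ape::Ntip(tree) + 1
    for (i in seq_len(ape::Ntip(tree))) {
      tx <- tree$tip.label[i]
      path <- ape::nodepath(tree, from = root, to = i)[-1]
      labs <- vapply(path, function(n) {
        if (n <= ape::Ntip(tree)) tree$tip.label[n] else paste0("node", n)
      }, character(1))
      ev <- k$truth$events[k$truth$events$branch %in% labs, ]
      expected <- 15 - sum(ev$type == "fusion") + sum(ev$type == "fission")
      expect_equal(length(unique(k$genomes[[tx]]$chromosome)), expected)
    }
  }
})

test_that("synteny bundling honours the gap and minimum-link rules", {
  g1 <- data.frame(gene_id = paste0("a", 1:300), chromosome = "c1",
                   position = 1:300)
  g2 <- data.frame(gene_id = paste0("b", 1:300), chromosome = "k1",
                   position = 1:300)
  # 5 consecutive collinear links -> one bundle of 5
  ort <- data.frame(gene1 = paste0("a", 1:5), gene2 = paste0("b", 1:5))
  out <- synteny_bundles(ort, g1, g2)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_links, 5)
  # two groups separated by more than the gap -> two bundles
  ort2 <- data.frame(gene1 = paste0("a", c(1:3, 200:202)),
                     gene2 = paste0("b", c(1:3, 200:202)))
  out2 <- synteny_bundles(ort2, g1, g2)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$n_links, c(3, 3))
  # a 2-link bundle is dropped under the default minimum
  ort3 <- data.frame(gene1 = paste0("a", 1:2), gene2 = paste0("b", 1:2))
  expect_equal(nrow(synteny_bundles(ort3, g1, g2)), 0)
  # the gap rule also applies on the second genome
  ort4 <- data.frame(gene1 = paste0("a", 1:6),
                     gene2 = paste0("b", c(1:3, 150:152)))
  out4 <- synteny_bundles(ort4, g1, g2)
  expect_equal(nrow(out4), 2)
})
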