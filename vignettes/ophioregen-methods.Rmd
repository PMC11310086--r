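---
title: "Methods: cross-species regeneration transcriptomics and karyotype evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species regeneration transcriptomics and karyotype evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ophioregen)
```

# Scope

`ophioregen` packages, as reusable and tested components, the statistical
core of a comparative study of appendage regeneration and genome
architecture in echinoderms and other regenerating animals:

* **Time-course clustering** — TMM normalization, log transform and
  per-gene standardization, fuzzy c-means soft clustering, cluster-number
  selection by the minimum centroid distance curve, temporal ordering and
  the "major cluster" rule.
* **Cross-species conservation** — the overlap of homologous genes between
  co-expression clusters of two species, tested against a constrained
  permutation null with Benjamini–Hochberg (BH) correction, plus three-way
  consistency, third-species homology breakdown and a heterochrony report.
* **Homology utilities** — reciprocal best hits, family retention
  filtering, phylostratigraphic gene-age assignment.
* **Enrichment** — one-sided hypergeometric enrichment/depletion with
  custom foregrounds and backgrounds, family-level annotation propagation.
* **Karyotype evolution** — Fisher-exact macrosynteny painting against
  ancestral linkage groups (ALGs), Dollo reconstruction of the ancestral
  karyotype, interchromosomal event counting and per-Myr rates, synteny
  ribbon bundling.
* **Repeats** — divergence-to-age calibration, repeat landscapes, region
  expansion and breakpoint-association tests, the differential-activity
  filter.
* **Explant contrasts** — threshold filtering of DE tables and the
  distal/proximal DEG categorization.

Each stage consumes and produces plain tables, so the pipeline runs equally
on user data and on the package's own synthetic-data generators, which
plant a known truth for every statistic.

# The conservation statistic

For species 1 clustered into clusters $i = 1 \dots C_1$ and species 2 into
$j = 1 \dots C_2$, with homologous families linking their genes, the
observed statistic is

$$ n_{ij} = \#\{\,\text{species-1 genes in cluster } i \text{ with at least
one family member in species-2 cluster } j\,\}. $$

Each species-1 gene contributes at most once per pair, so several
homologues in the same partner cluster do not inflate the count. The null
distribution is built by permuting the species-2 gene labels over the fixed
multiset of cluster assignments — cluster sizes and family structure are
held constant, only the pairing of genes to clusters is randomized — and
recomputing all $n_{ij}$ per replicate (default $N = 10{,}000$). The
empirical p-value is the bias-avoiding estimator

$$ p_{ij} = \frac{r_{ij} + 1}{N + 1}, \qquad
   r_{ij} = \#\{\text{replicates with null count} \ge n_{ij}\}, $$

BH-corrected across all $C_1 \times C_2$ pairs of one comparison. Ties
count against significance ($\ge$, conservative). Species-1 genes are the
counting unit; the roles can be swapped by exchanging the arguments.

Two design points deserve emphasis:

* **Permutation unit.** Gene labels, not family labels, are permuted; this
  preserves both cluster sizes and the per-family gene multiplicities while
  breaking the gene-to-cluster association.
* **Discreteness of empirical p-values.** Permutation p-values live on the
  grid $\{1/(N+1), \dots, 1\}$ and, because overlap counts are small
  integers with ties, they are slightly conservative relative to a
  continuous uniform. Calibration is therefore checked as uniformity *on
  the attainable grid*: observed p-values are compared (two-sample KS)
  against p-values computed for held-out null replicates, which follow the
  grid distribution exactly under exchangeability.

# Clustering decisions

* **Normalization.** TMM factors use the standard construction: reference
  sample = the one whose 75th-percentile proportion is closest to the mean;
  two-sided trims of 30% on M-values and 5% on A-values; inverse-variance
  weights from the count-level delta-method variance; pairwise exclusion of
  zero counts; geometric-mean centering. Because the precision weights
  depend on absolute counts, scaling a single library changes factors by a
  small amount (order $10^{-3}$) even though all proportion M-values are
  unchanged; whole-matrix scaling cancels exactly. Clustering operates on
  `log2(x + 1)`-transformed, per-gene standardized profiles; zero-variance
  genes are dropped and reported.
* **Fuzzy c-means.** Memberships $u_{ij} \in [0,1]$ with unit row sums
  minimize $\sum_{i,j} u_{ij}^m \lVert x_i - c_j \rVert^2$ by alternating
  updates until the largest centroid shift falls below $10^{-6}$ (cap
  1,000 iterations; non-convergence returns the best state with a
  warning). The fuzzifier defaults to $m = 1.25$, a typical value for
  standardized expression profiles; hard assignments are argmax
  memberships with ties resolved to the lowest cluster index.
  Initialization samples `C` distinct gene profiles; the best of three
  seeded restarts (lowest objective) is kept, so results are fully
  reproducible given the seed.
* **Cluster number.** The minimum pairwise centroid distance
  $D_{\min}(C)$ is recorded over the candidate range. The selected $C$ is
  the knee of this decreasing curve: the largest $C$ maximizing the local
  curvature $2 D(C) - D(C{-}1) - D(C{+}1)$, i.e. the last value before the
  curve flattens. (The knee, not the point after the drop: on data with
  $k$ well-separated planted templates the curve stays high up to $k$ and
  collapses at $k{+}1$, and the knee rule returns $k$.) The full curve is
  returned for inspection and a manual override is available by passing a
  single-value range.
* **Major clusters.** A cluster is "major" when it has more than one
  significantly enriched term and its centroid exceeds the onset threshold
  (default 0 on the standardized scale) in more than one regenerating
  sample. Clusters are ordered by onset (first sample above threshold),
  ties by peak position, then by index.

# Karyotype decisions

* **Painting.** Every (chromosome, ALG) cell gets a one-sided Fisher exact
  test (upper hypergeometric tail) of the 2×2 split on/off chromosome ×
  this/other ALG, BH-corrected across all cells, with assignment at
  adjusted $p < 10^{-5}$.
* **Ancestral reconstruction.** A "join" — two reference ALGs co-assigned
  to one chromosome — is a binary character under Dollo parsimony: gained
  once on the branch to the MRCA of the taxa showing it, never regained.
  Joins whose gain covers the ingroup ancestor merge reference groups into
  ancestral units; younger joins are per-lineage fusions. Fusions are
  essentially never exactly reversed, which is what motivates the
  no-reversal assumption and the outgroup-based orientation of ancestral
  states.
* **Event counting.** In the bipartite graph of significant ALG–chromosome
  assignments, a connected component with $a$ ALGs and $c$ chromosomes
  implies at least $(a-1) + (c-1)$ fusions-plus-fissions; this minimum is
  the reported count. An optional mode counts a fully connected 2×2
  component as a single reciprocal translocation, since the default
  decomposition would charge it two events.
* **Rates.** Events divided by branch time in Myr, reported to three
  significant figures; 500 Myr — the divergence of the echinoderm class
  pairs motivating the method — is the default branch time.
* **Repeat ages.** $t = d / r$ with $d$ the (fractional) Kimura divergence
  to consensus and $r$ the neutral substitution rate per bp per year
  (default $1.885 \times 10^{-9}$). The consensus is read as a proxy for
  the ancestral sequence, so a copy's whole divergence accrues on its own
  branch; the halved alternative $d/(2r)$ would be appropriate for the
  distance between two extant copies instead and is inconsistent with the
  calibration windows this rate is used with (2% → ≈10.6 Myr, 18–22% →
  ≈100 Myr).

# What the generators emulate — and what they do not

The synthetic-data module exists so that every downstream test reads its
expectation from a planted truth table rather than re-deriving it.

* **Time courses.** Gene profiles are unimodal Gaussian bumps over the
  ordered stage index (peak evenly spaced per cluster, width 1.5 stages)
  plus Gaussian noise, scaled by a lognormal abundance; counts add a
  Poisson layer on top of per-sample depths. A fraction $\rho$ of families
  is "conserved": all member genes in all species follow the family's
  template cluster; other families draw cluster labels independently. The
  default eight-sample design mirrors a regeneration experiment: one
  non-regenerating control plus seven ordered regeneration stages.
* **Karyotypes.** An ancestor with `n_algs` chromosomes evolves along a
  newick tree by Poisson numbers of fusions, fissions and terminal-segment
  translocations per branch. Break points avoid the `min_segment`
  neighborhood (default 8 genes) of chromosome ends *and* internal
  linkage-group junctions: a fragment carrying fewer genes than the
  painting stage can call significant would make the simulated history
  unrecoverable by construction, which would test nothing. Histories whose
  events reuse the same linkage group twice can still be genuinely
  non-identifiable from extant gene content; recovery tests detect these
  through the truth tables and treat them separately.
* **Annotations.** Term membership is Bernoulli at a background prevalence,
  with planted (term, cluster) pairs at a configured odds ratio; odds 1
  yields a calibrated null.
* **Repeats and DEGs.** Associated repeat families place a fraction $\pi$
  of copies near breakpoints, the rest uniformly; DE tables realize planted
  categories (shared / opposite / distal-only / proximal-only / null) as
  normal draws around ±2 log2-fold-change effects, with the planted sign
  enforced.

Not emulated: read-level sequencing noise, sequence evolution,
overdispersion beyond Poisson, batch effects, intrachromosomal
rearrangements, GO-graph structure, or correlated annotation terms.
Passing recovery tests therefore demonstrates the correctness of the
statistics under their stated models, not robustness to every property of
real data.

One global integer seed drives everything; each stage derives a fixed
substream from it, so identical configuration and seed give byte-identical
outputs, including across partial reruns.

# Numerical choices and degenerate inputs

* Empirical p-values use $(r+1)/(N+1)$; the attainable minimum is
  $1/(N+1)$.
* Hypergeometric and binomial tails go through `phyper`/`pbinom`; tests
  verify agreement with direct combinatorial summation to $10^{-12}$ on
  tables with $M \le 60$.
* BH families: all cluster pairs of one species-pair comparison; all terms
  of one foreground test (per cluster); all painting cells of one genome;
  all repeat families of one test. Enrichment terms need at least 3
  background hits by default.
* RBH ties for the best hit discard all tied candidates ("one-to-one"
  semantics). Family filter bounds are inclusive and configurable
  (defaults 1–4 genes per species).
* Zero-total-count samples, empty backgrounds, foregrounds outside their
  background, conflicting one-to-one pairs and out-of-range configuration
  all fail fast with named errors; empty hit tables and empty DEG sets are
  valid empty results.

# Problem sizes used by the test suite

The suite plants its truths at deliberately modest sizes — a few hundred
genes, 5 clusters, 1,000 permutations, 10–20 seeds per property, 20
linkage groups of 60 genes — chosen so that every planted effect is far
from its detection boundary and every calibration check has enough pooled
replicates to be meaningful.

# Known limitations

* The axolotl-style partner species is emulated with the same generator as
  the focal species; no attempt is made to model dataset-specific depth or
  annotation quality differences.
* The heterochrony report ranks outlier pairs by leave-one-out gain in
  Kendall's tau; it is descriptive and carries no significance test.
* Dollo reconstruction emits fusion gains only; losses within a gain clade
  are not charged as fission events on specific branches.
* The translocation mode of `count_events` flags only exact 2×2 complete
  components; larger mixed components are always decomposed into
  fusions-plus-fissions.
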