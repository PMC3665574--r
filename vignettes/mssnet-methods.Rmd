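---
title: "Methods: mutation-seeded subnetworks and coevolution consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-seeded subnetworks and coevolution consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mssnet)
```

## The problem and the model

Selection experiments and association studies frequently yield a short list
of mutated genes together with a genome-wide expression contrast, at sample
sizes far too small for purely statistical causal inference.  `mssnet`
implements a knowledge-driven alternative: if a set of driver mutations
collectively re-regulates a core pathway, the mutated genes should sit
unusually *close*, in the protein–protein interaction (PPI) network, to the
differentially expressed (DE) genes that read out that re-regulation, and
the same pathway categories should recur across the mutated genes'
subnetworks.

The pipeline has four network-scale stages and one molecular-scale stage:

1. **DE calling.** Two-channel intensities can be LOWESS-normalized per
   array (`M' = M − lowess(A)`); missing values are imputed by gene-space
   k-nearest neighbours; each gene is tested with a two-sided Welch t-test;
   p-values are Holm-adjusted; a gene is called up if adjusted `p < α` and
   linear fold change `> 1.5`, down if `< 0.67`.
2. **Mutation-seeded subnetworks (MSSN).** For each mutated gene (seed) and
   DE direction, single-source Dijkstra shortest paths connect the seed to
   every reachable DE target; the union of one retained path per target is
   the MSSN, and the per-target distances form its distance sample.
3. **Path statistics.** The MSSN sample (sample 2) is compared with pooled
   distances from random background draws (sample 1; each replicate draws
   one random source and a matched number of random distinct destinations)
   through the Welch statistic
   `t = (x̄₁ − x̄₂) / √(s₁²/n₁ + s₂²/n₂)` with unbiased variances, so a
   *positive t means shorter-than-random paths*.  Two complementary
   quantities come from the per-replicate background means: an empirical p
   (fraction of replicate means at or below the observed MSSN mean) and a
   z-score `z = (x̄₁ − x̄₂)/sd(replicate means)`.  Both t and z are always
   reported because the field's tables conventionally print either; the
   ranking uses t, significance gating uses the empirical p.
4. **Core pathways and ranking.** Each MSSN is tested for category
   overrepresentation with the hypergeometric upper tail
   (`P(X ≥ k)` for k annotated members among n subnetwork genes, K of N in
   the universe), BH-corrected within that MSSN's term family.  Terms are
   profiled by the fraction of MSSNs in which they are significant; the
   most frequent are designated core pathways (top-k, frequency threshold,
   or an explicit externally validated list).  Seeds are then tiered:
   tier 1 passes both evidence channels (enrichment for a core pathway
   *and* path significance in at least one direction), tier 2 exactly one,
   tier 3 neither; within a tier the best-direction t decides the order.
5. **Coevolution consensus (molecular scale).** For one mutated alignment
   column against all others, five covariation scores are computed — SCA
   (perturbation log-ratios), ELSC (subset-composition likelihood), OMES
   (observed-minus-expected squared), mutual information (nats), and a
   conservation sum — and a partner column is called co-evolving when at
   least two methods place the pair at or above their own 95th score
   percentile.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `score_threshold` | 400 | STRING combined-score cutoff (0–1000); 400 is the usual "medium confidence" |
| `weight_scheme` | `unit` | `unit`: distance = hop count; `string_confidence`: weight `1000/score` |
| `alpha` | 0.05 | significance level for DE calls, enrichment and path gating |
| `fc_up`, `fc_down` | 1.5, 0.67 | linear fold-change gates |
| `adjust` | `holm` | DE p-value adjustment (`holm` or `bh`) |
| `knn_k` | 10 | imputation neighbours |
| `lowess_span` | 0.4 | LOWESS smoother span (fraction of spots) |
| `n_replicates` | 1000 | background replicates per seed and direction |
| `identity_threshold` | 0.90 | redundancy removal before coevolution |
| `flag_quantile` | 0.95 | per-method coevolution flagging quantile |
| `max_gap_fraction` | 0.5 | alignment columns with more gaps are masked |

Background destination-set sizes are always matched to the observed
in-network target count, and backgrounds are redrawn per seed from a
substream derived from the pipeline seed, so adding or removing a seed
never changes another seed's numbers.

## Numerical and design choices

* **Holm, as named.** The DE stage follows the microarray convention of
  calling Bonferroni–Holm an "FDR procedure"; Holm in fact controls the
  family-wise error rate, which is what the suite verifies.  BH is
  available via `adjust = "bh"` when genuine FDR control is wanted.
* **Welch everywhere.** The per-gene DE test and the path statistic use the
  same unequal-variance t form; variances use the n−1 estimator.
* **Fold-change scale.** Fold changes are ratios of linear-scale group
  means; matrices whose 99th percentile is below 30 are treated as log2
  (overridable), since log2 microarray intensities rarely exceed that.
* **Tie-breaking.** Among equal-cost shortest paths the lexicographically
  smallest node-id sequence is retained; ranking ties break on gene id;
  subalignment majority-residue ties break alphabetically.  All outputs are
  byte-identical across reruns with the same config and seed (provenance
  headers carry version, config hash and seed, never timestamps).
* **Degenerate inputs.** Zero-variance genes with equal means get `t = 0,
  p = 1`; unequal means get `p = 0` with a `degenerate` flag.  Unreachable
  targets are excluded from distance samples but counted.  MSSNs with
  fewer than two reachable targets are flagged rather than scored and fall
  to tier 3 of the ranking.
* **Hypergeometric tail.** Evaluated through the distribution function's
  log-space path to avoid underflow in deep tails; exactness against
  subset enumeration is part of the suite.
* **SCA regularization.** The perturbation log-ratio uses a unit
  pseudocount added to the residue *frequencies* (not counts), which keeps
  terms finite and — being sample-size free — makes the score exactly zero
  whenever the subalignment and full-alignment compositions coincide.
  The statistical-energy constant is kT\* = 1.
* **ELSC rounding.** The unbiased reference composition `m_y` uses
  largest-remainder apportionment of the proportional allocation, capped
  at the full-column counts.
* **Perturbation methods and symmetry.** SCA and ELSC are directional; the
  stored matrix entry is the mean of the two directed scores (or the one
  defined direction), preserving the symmetric-matrix contract shared by
  all five methods.
* **MI units and corrections.** Natural log; no average-product correction
  by default (the consensus design predates it), and conservation scores
  participate in the consensus exactly like the four covariation scores.
* **Ontology handling.** The annotation map is taken as given (no
  true-path propagation); GAF input honours `NOT` qualifiers; the
  enrichment universe defaults to all annotated genes and can be supplied
  explicitly.

## The synthetic benchmark and what it shows

`make_toy_study()` builds a complete miniature study with planted truth:
a 500-node preferential-attachment network (m = 2); two 20-gene pathway
modules; five driver seeds each wired by direct edges to about half of its
module's members; a 6 + 6 sample log2 expression matrix in which module 1
is planted 2-fold up and module 2 2-fold down (σ = 0.15, 2% missing); an
annotation map where each module is one category among background
categories; and a 60 × 40 alignment with three covarying pairs (coupling
0.9) planted at the mutated column of the first seed.

Two generator design choices matter for the statistics:

* **DE genes live inside the planted modules.**  This encodes the method's
  central hypothesis — drivers collectively re-regulate a pathway whose
  members respond transcriptionally — as the simulation's generative
  assumption, so planted drivers genuinely sit close to their targets.
* **Centrality-neutral planting.**  Module members and seeds are drawn
  from peripheral, minimum-degree backbone nodes, and module density and
  seed wiring are modest (internal edge probability 0.05; per-member
  attach probability 0.5).  Pathway genes are rarely network hubs, and,
  just as importantly, the background model draws *random* destinations:
  it is only a valid null for the observed target sets when targets are
  about as reachable as random genes.  Planting the modules on
  well-connected nodes would make every gene's paths to the targets
  "significantly short" and the benchmark would measure target hubness,
  not driver wiring.  With the neutral design, non-planted control genes
  show path significance at about the nominal 5% rate per direction
  (the per-seed rate over both directions is correspondingly
  ~`1 − 0.95²`), which is what the acceptance suite checks.

What passing the benchmark does *not* show about real data: STRING-scale
networks have heavier tails and score-dependent edge reliability; real
microarray noise is heteroskedastic and spatially structured; real protein
families are phylogenetically correlated rather than star-shaped, which
inflates background coevolution scores; and real pathway annotations
overlap hierarchically.  The benchmark validates the machinery and its
calibration under its stated assumptions, not biological discovery
performance.

Problem sizes used by the checks (chosen to exercise every stage at full
statistical resolution): 50 toy-study replicates with 200 background
replicates per MSSN for driver/control recovery; 200 global-null
1000-gene studies for the family-wise error check; 20 alignments of
200 × 50 for covariation recovery; 100 random graphs (≤ 50 nodes) for the
shortest-path oracle.  The consensus chance-level check compares against
the independent-flags expectation within three single-replicate binomial
standard errors — a deliberately wide band, because the five methods are
positively correlated (MI and OMES especially) and their joint flag rate
sits above the independence value.

## Known limitations

* The MSSN inclusion rule is operationalized at the subnetwork level (the
  Welch t and empirical p over the whole distance sample); per-target
  pruning against the background median is available but not default.
* Directionality of regulation is not modeled on the network: paths may
  traverse any gene, and signed or directed interactions are out of scope.
* The per-seed evaluation treats the two DE directions as separate tests
  and qualifies a seed on either; users wanting strict per-direction
  claims should read `empirical_p_up` / `empirical_p_down` directly.
* Coevolution assumes a reasonably deep alignment after 90%-identity
  deduplication; below a few dozen effective sequences the 95th-percentile
  flags become noisy.

## A worked miniature run

```{r toy, eval = FALSE}
study <- make_toy_study(rng_seed = 1)
dir <- tempfile()
write_toy_study(study, dir)
cfg <- pipeline_config(
  network     = file.path(dir, "network.tsv"),
  mutations   = file.path(dir, "mutations.tsv"),
  annotations = file.path(dir, "annotation.tsv"),
  expression  = file.path(dir, "expression.tsv"),
  design      = file.path(dir, "design.tsv"),
  msa         = file.path(dir, "msa.fasta"),
  output_dir  = file.path(dir, "out"),
  n_replicates = 200, rng_seed = 1)
res <- run_pipeline(cfg)
res$ranking
```
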