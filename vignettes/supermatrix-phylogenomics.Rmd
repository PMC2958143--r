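---
title: "Supermatrix phylogenomics with parsimony, likelihood and Bayesian support diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supermatrix phylogenomics with parsimony, likelihood and Bayesian support diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopipe)
library(ape)
```

## The analysis this package implements

`phylopipe` implements a complete multi-locus ("supermatrix")
phylogenomic workflow of the kind used to resolve shallow, rapid
radiations — for example an endemic freshwater-fish clade sampled for on
the order of a hundred single-copy nuclear loci across a dozen or so
species plus a distant outgroup. The workflow runs from marker discovery
to dated trees:

1. **Marker mining.** Candidate single-copy genes are found by an
   all-vs-all self-comparison of a proteome: a gene is kept only if
   every non-self local-alignment hit has both similarity *S* and query
   coverage *C* below a threshold (30% by default), and a candidate's
   orthology is confirmed by requiring exactly one significant hit in a
   reference database. Exon lengths are binned to pick PCR-amenable
   candidates.
2. **Supermatrix assembly.** Per-gene alignments with exon/intron
   annotation are concatenated; missing taxa become all-`?` rows. Five
   partitioning schemes are materialised (by gene, exon+intron, codon
   positions+intron, seven equal blocks, single partition) together with
   descriptive statistics: variable and parsimony-informative site
   counts, base composition with a chi-square homogeneity test, pooled
   Ti/Tv, and Kimura two-parameter distances with pairwise deletion.
3. **Maximum parsimony.** Equal-weights Fitch scoring with exact
   (exhaustive or branch-and-bound) search for small taxon sets and
   random-addition + TBR branch swapping above that; nonparametric
   bootstrap; a *variable-length bootstrap* that resamples
   pseudo-matrices of increasing length to chart how node support grows
   with data quantity; and Bremer support with its per-partition
   decomposition (PBS), whose per-split sum equals the decay index by
   construction.
4. **Maximum likelihood.** Felsenstein-pruning likelihood under
   JC/K80/HKY/GTR with optional invariant sites and discrete-gamma rate
   heterogeneity; AIC model selection; NNI hill-climbing tree search;
   a global-clock likelihood-ratio test; RELL-based KH, SH and WSH
   topology tests; and a simplified strict-clock dating step that
   scales an ultrametric tree so one fossil-calibrated node sits at its
   minimum age (1.81 MY by default).
5. **Bayesian inference.** Partitioned Metropolis-Hastings MCMC with
   parameters unlinked across partitions, 50% majority-rule consensus
   with split posterior probabilities, harmonic-mean marginal
   likelihoods, and Bayes-factor comparison of partitioning strategies
   and models on the Kass-Raftery scale (2lnBF > 10 decisive).
6. **Ancestral states.** Marginal reconstruction of discrete traits
   (e.g. keel presence, egg type, vertebra-count class, gill-raker
   class) under the symmetric Mk model on a fixed tree, by exact
   pruning with an ML or MCMC-integrated rate.

Every stage is also exercisable end-to-end on synthetic data with
recorded truth via `run_pipeline()`.

## Models and their assumptions

**Substitution models.** The GTR family with stationary frequencies
$\pi$, exchangeabilities $r_{ij}$ (GT fixed to 1), rate matrix scaled to
one expected substitution per site per unit branch length. JC, K80 and
HKY are the usual special cases. Rate heterogeneity uses the
discrete-gamma approximation with four equal-probability categories
represented by their category means; with invariant sites the gamma
rates are rescaled by $1/(1-p_{inv})$ so the mixture keeps mean rate 1.
The likelihood assumes site independence, stationarity, reversibility
and homogeneity along the tree — the usual idealisations, violated to
some degree by real data (e.g. compositional drift, heterotachy).

**Parsimony.** Fitch's algorithm on unordered states with gaps, `?` and
`N` treated as wildcards: a missing cell never forces a change. This
matches the practice of excluding indels from character scoring.

**Mk traits.** A k-state symmetric Markov chain with total leave-rate
$r$; transition probabilities have the closed form
$P(\text{same}) = 1/k + (1-1/k)\,e^{-rkt/(k-1)}$. Root state prior is
uniform.

**Harmonic-mean marginal likelihoods.** The marginal likelihood of a
partitioning strategy or model is approximated by the harmonic mean of
the sampled likelihoods, computed in log space with log-sum-exp so a
71 kb matrix (lnL near $-2\times10^5$) cannot overflow. The estimator
is retained because it is the method this workflow standardises on, but
it is known to be unstable (its variance can be infinite); the
`dominance` diagnostic reports the largest single-sample weight so a
run dominated by one sample is visible. Stepping-stone or path sampling
would be superior and is deliberately out of scope.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `s_max`, `c_max` | 30, 30 | similarity / coverage ceilings (%) for the single-copy filter; retention requires *every* non-self hit below both |
| `significance_cutoff` | 150 | raw local-alignment score threshold; unrelated random proteins of a few hundred residues score below ~100, homologues at 40%+ identity score in the hundreds |
| `n_reps` (bootstrap) | 100 (function), 1000 reachable | pseudo-replicates |
| VLB `sizes` | user-set | resample lengths; with-replacement resampling allows sizes beyond the matrix length |
| `n_gens`, `sample_every` | 20000, 100 | MCMC length; the real-data scale of 2,000,000 generations with one tree kept per 1000 is reachable by configuration |
| burn-in | 1000 sampled trees (real-data scale); fractions at desk scale | discarded prefix per run |
| `min_age` | 1.81 | fossil minimum age (MY) used as a point calibration |
| `intron_rate_mult` | 2 | simulator: introns evolve faster than exons |
| `missing_fraction` | 0.1 | simulator: probability a (taxon, locus) cell is entirely absent |

The strict reading of the mining filter (a hit with S = 20, C = 35
disqualifies) is the default because the filter's sentence conditions
*retention* on both quantities being small; the alternative reading
(disqualify only when both exceed) is available as `rule = "either"`.
Similarity is percent identity over aligned columns and coverage is
relative to the query; both conventions are configurable because
neither is fixed by common usage.

## What the synthetic generator emulates — and what it does not

`preset_config()` produces the study-shaped conditions: 13 taxa (a
shallow ingroup of 12 plus a distant outgroup), ~100 loci of
300–1500 bp, ~70% exon content, intron sites at twice the exon rate,
log-normal per-gene rate multipliers (sd 0.3 on the log scale — the
per-gene dispersion is a free parameter, not calibrated to any real
per-locus table), and whole-locus missingness at rate 0.1 per (taxon,
gene) cell. The generating tree is fixed with ingroup pairwise path
lengths of roughly 0.02–0.05 expected substitutions/site and ~0.11 to
the outgroup, matching the K2P divergence profile of a low-divergence
multi-gene fish dataset. Missingness is modelled as whole-locus absence
because amplification failure removes whole loci; real partial
sequences (a locus present but truncated in one taxon) are not
emulated. Indels, codon structure beyond position labels, heterotachy
and alignment error are also not simulated — so passing recovery tests
demonstrates correctness of the inference machinery under the model, not
robustness to real-data pathologies.

Trait simulation rescales the tree to unit root-to-tip depth so the Mk
rate reads as expected changes per root-to-tip path.

## Numerical choices

* Pruning partials are rescaled per column at every edge; zero partial
  columns (legitimate under the invariant-sites rate class at variable
  columns) propagate as $-\infty$ for that category and are resolved by
  the mixture, never treated as numerical failure.
* Branch lengths are optimised coordinate-wise by Brent's method with
  sweeps repeated until the likelihood gain falls below a relative
  $10^{-6}$; model parameters by Nelder-Mead (Brent in one dimension)
  with a BFGS polish, and a parameter move is only accepted when it
  improves the likelihood, which enforces the nested-model ordering up
  to small optimiser slack.
* The clock fit parameterises node heights as a root height and one
  fraction per internal node, keeping every proposal ultrametric; the
  LRT uses df = n − 2 (2n − 3 free branch lengths against n − 1 node
  heights). A clock fit that lands within 0.05 lnL above the free fit
  is clamped; anything larger raises an optimiser-failure error rather
  than producing a negative statistic.
* Bremer anti-constraint searches are exact (stepwise addition with
  pruning) up to 9 taxa and constrained TBR above; among co-optimal
  anti-constraint trees the per-partition lengths are averaged by
  default (`tie_break = "first"` switches to the first tree found).
  Either way the per-split PBS sum equals the decay index exactly,
  because all co-optimal trees share the same total length.
* Splits are keyed by the lexicographically smaller side (the one
  containing the alphabetically first taxon), so support tables from
  MP, ML and BI merge on the key.
* NNI proposals in the MCMC swap a child of an internal edge's lower
  node with a child of its upper node; the move is symmetric and the
  two alternative resolutions of every internal edge are reachable, so
  the chain is irreducible over unrooted topologies.
* Ties among equally good greedy insertions during stepwise addition
  are broken uniformly at random (under the run's seed), which is what
  makes repeated random-addition replicates informative.

## Design choices that were genuinely open

* **Variable-site percentages** are reported with the total column
  count as denominator. Published per-matrix percentages do not always
  follow one convention; the convention here is stated rather than
  reverse-engineered, and `site_percent()` makes the arithmetic
  explicit.
* **Priors** (none are dictated by the workflow's sources): uniform on
  topologies, Exponential(10) on branch lengths, flat Dirichlet on
  frequencies and exchangeabilities, Uniform(0,1) on the invariant
  proportion, Exponential(1) on the gamma shape, and a flat Dirichlet
  on the length-weighted partition-rate simplex (mean rate constrained
  to 1). All are defaults, not recommendations.
* **Dating** replaces a rate-autocorrelated Bayesian relaxed clock with
  strict-clock scaling against a single minimum-age calibration treated
  as a point age. This keeps the stage testable end-to-end; absolute
  ages from it inherit every caveat of a strict clock and a minimum age
  used as a point estimate, and should be read as illustrative.
* **Topology tests** implement KH, SH and WSH via RELL; the AU test's
  multiscale bootstrap is out of scope.
* **Coverage denominator** in mining is the query length; with
  duplicated-then-diverged fixtures the choice is immaterial, with real
  multi-domain proteins it is not.

## Problem sizes used in the shipped tests

The test-suite and acceptance script run at desk scale, chosen so the
whole suite completes in minutes on one core: oracle equivalence on
hundreds to a thousand random 4–6-taxon instances; recovery on 13 taxa
with 100 loci at 36–180 bp per locus (~11 kb total); MCMC runs of a few
thousand generations; bootstraps of tens of replicates. The real-data
scale (71 kb, 1000 bootstrap replicates, 2,000,000 generations) is
reachable through the same interfaces by changing the configuration.

## A worked run

```{r pipeline, eval = FALSE}
bundle <- run_pipeline(list(
  seed = 3,
  synthetic = list(n_genes = 20, length_scale = 0.25),
  mp = list(bootstrap_reps = 30),
  bayes = list(n_gens = 3000)))

# do all three methods agree with the generating tree?
same_topology(bundle$mp$search$trees[[1]], bundle$truth$tree)
same_topology(bundle$ml$search$tree, bundle$truth$tree)
same_topology(bundle$bayes$consensus$tree, bundle$truth$tree)
bundle$agreement
```

## Known limitations

* The heuristic MP search is hill-climbing; on data with weak or
  conflicting signal it can return a local optimum (mitigated by
  addition-sequence replicates, but not eliminated).
* The harmonic-mean estimator's instability is inherited by design;
  treat Bayes factors computed from short runs as qualitative.
* The MCMC updates one block per generation with fixed proposal
  scales; there is no adaptive tuning, so very large matrices may mix
  slowly.
* `ancestral_states()` conditions on a fixed tree; uncertainty in the
  topology is not propagated into the trait posteriors.
* The clock LRT assumes the chi-square asymptotics of nested models;
  at very short alignments the test is conservative.
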