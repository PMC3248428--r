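---
title: "Scoring prey-prey interactions from aggregated IP-MS pull-downs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring prey-prey interactions from aggregated IP-MS pull-downs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preynet)
```

## The model and its assumptions

Immunoprecipitation followed by mass spectrometry (IP-MS) reports, per
experiment, a list of identified proteins with spectral counts (SPC) — a
semi-quantitative abundance proxy. Antibody-based purifications carry two
structural problems: primary antibodies cross-react with secondary
antigens, so the nominal bait is an unreliable anchor; and abundant
"sticky" proteins (heat-shock machinery, ribosomal proteins, hnRNPs)
appear in most pull-downs regardless of bait.

`preynet` therefore scores **prey-prey** pairs: if two proteins reappear
together near the top of many different pull-down lists, they are likely
in physical contact, no matter which antibody brought them down. The
operating assumptions are

* counts are comparable within an experiment and, after dividing by the
  molecular weight of the largest isoform (`q = SPC/MW`, an NSAF-style
  normalisation that is *not* rescaled per experiment), roughly
  comparable across proteins;
* non-specific identifications are removable with a curated sticky list
  (applied before all scoring — the package follows the
  filter-then-analyse order throughout, configurable);
* molecular weights use one consistent unit across all proteins (the
  object records the unit); mixing units would distort every
  cross-protein comparison.

## The four pair scores

For proteins A, B with presence sets `M_A`, `M_B` (experiments with
SPC > 0) and full-length profiles over all `m` experiments:

* **Sorensen** `sor = 2|M_A ∩ M_B| / (|M_A| + |M_B|)` — pure
  co-occurrence, in [0, 1].
* **Pearson** `pr` — correlation of the two `q` profiles, zeros included,
  over *all* experiments (whether to restrict to experiments containing
  at least one of the pair is a genuinely open choice; all-experiments is
  the default because it preserves the penalty for solitary appearances).
* **Rank-proximity** (`e3`) — per experiment `j` containing both:
  `(SPC_A,j + SPC_B,j) / (|rank_A,j − rank_B,j| + 1)`, ranks by
  descending SPC among proteins identified in `j` (competition ranking,
  ties share the smallest rank). The final score averages over **all** m
  experiments by default, so pairs that rarely co-occur are penalised;
  `denominator = "cooccurring"` averages only over shared experiments.
* **Count-product** (`ab`)
  `= mean_j(SPC_A,j · SPC_B,j) / (mean_j SPC_A + mean_j SPC_B)` — zero
  exactly when the pair never co-occurs.

The symbolic forms of `e3` and `ab` are **reconstructions from prose
descriptions**, not transcriptions of published formulas. Two choices
deserve emphasis: the `+ 1` in the `e3` denominator exists because tied
counts give a rank gap of zero; and `ab` is computed on raw SPC while
`pr` is computed on `q`, because that is the quantity each description
names (`ab_use_abundance = TRUE` switches `ab` onto `q`).

Undefined scores — a zero-variance profile under `pr`, an all-zero pair
under `ab` — become `NA` sentinels and are excluded from that method's
ranking rather than imputed. All rankings break ties by score descending,
then lexicographic pair identifier, so every ranking is reproducible.

### Combination

The combined score is the plain product `base × sor` (`pr` is affinely
mapped to [0, 1] first so the product stays monotone in both factors).
The product is the simplest monotone combiner with the right annihilator
behaviour: a pair that never shares an experiment (`sor = 0`) cannot be
rescued by a high count-based score.

## Networks and complexes

The global interaction map keeps pairs ranked in the top 10 % by
*every* combined method (per-method top `ceiling(f·N)` over that method's
defined scores, then intersection). The complex map tightens the cut to
the top 1 %, retains only edges participating in at least one triangle
(three-node clique — the minimal unit of dense support), and reports
connected components of the result as predicted complexes. Components
are the minimal faithful formalisation of "tightly connected groups";
every component then has ≥ 3 members and every edge has triangle
support. Edges are classified against a reference interactome as
`recalled` (known), `indirect` (two-step path in the reference), or
`novel`.

## Domain-domain propagation

A scored pair (A, B) with domain-occurrence multisets `D_A`, `D_B`
(Pfam accessions; a domain may occur several times in one protein)
spreads its score uniformly: each unordered accession pair with one side
from each protein receives `s · mult_a · mult_b / (|D_A|·|D_B|)`. The
uniform split conserves the pair's score mass exactly — summed over its
domain pairs the contribution equals `s` — which keeps proteins with
many domains from dominating the domain ranking (`normalize = FALSE`
assigns the raw score instead). Homodomain pairs are retained: reference
DDI sets contain them. Separately, the λ index counts the supporting
protein pairs per domain pair, once per pair regardless of multiplicity;
`combine_ddi_rankings(use_lambda = TRUE)` multiplies scores by λ before
ranking so single-support domain pairs sink.

## Evaluation machinery

* **ROC/AUC** by the trapezoidal rule over the full ranking; tied scores
  are grouped, which makes the AUC equal to the Mann-Whitney statistic
  with averaged tie ranks (asserted against that closed form in tests).
* **Running sum**: walking down the ranking, +√((u−t)/t) on a known
  interaction and −√(t/(u−t)) otherwise (u predictions, t known among
  them). The steps are chosen so the walk ends at exactly zero; the peak
  deviation and its rank summarise how early the known signal
  concentrates. The reference set is restricted to pairs present in the
  ranking before computing t — the only defensible recall denominator.
* **Sliding recall**: fraction of known interactions in a trailing
  window (default 2,000 ranks, truncated at the list start). Trailing
  rather than centred, preserving the "performance up to rank r" reading.
* **Shuffled null**: the same walk on rank-shuffled lists; the pointwise
  mean of many shuffles should hover near zero. One mandatory seed
  controls all shuffles.

## The synthetic study

`generate_ipms()` emulates the data model the method is built for, with
every parameter surfaced in `generator_config()`. Defaults describe a
mid-sized aggregation study and are fixed once:

* 40 planted complexes of 3–25 members; 200 experiments with target
  list sizes 30–200 (2 % of experiments are "promiscuous" draws padded
  with one-off background up to 3× the nominal maximum, emulating the
  heavy tail of oversized lists);
* 1,600 proteins total — roughly two background proteins for every
  complex member, reflecting that most detected proteins are outside the
  surveyed complexes;
* each antibody targets one complex (every complex gets at least one
  antibody) and carries a fixed off-target complex set that comes down
  in 25 % of its experiments — cross-reactivity is an antibody property,
  its expression varies by experiment;
* complex members are captured with probability 0.8; counts are negative
  binomial (dispersion 0.5) around a lognormal per-protein abundance
  (median ≈ 6 spectra); 100 sticky proteins appear in 80 % of all
  experiments at elevated counts — a deliberately large non-specific
  set, matching how many recurrent contaminants real nuclear-extract
  lists carry and making replicate experiments overlap enough for the
  similarity graph to be informative; background proteins appear at
  rate 0.08 with counts near 1;
* domains: each complex carries one compatible domain pair on
  alternating members (the ground-truth DDIs), plus decoy domains, some
  duplicated within a protein to exercise multiset handling.

What the generator does **not** emulate: peptide-level identification
and FDR, protein inference ambiguity, shared subunits between complexes,
condition-dependent remodelling, and correlated contamination. Passing
tests on this generator therefore demonstrate that the statistics
recover planted co-occurrence structure under realistic count noise —
not that they would achieve the same figures on any particular real
dataset.

With the default configuration (seed 42) all four methods exceed 0.8
AUC against the planted interactions, combination with `sor` never
lowers a method's AUC, and the top-1 % + triangle + component pipeline
recovers the planted complexes at a mean best-match Jaccard above 0.5.
Roughly six complexes in ten are recovered at Jaccard ≥ 0.5
individually: the strict top-1 % cut (~3,000 edges against ~3,600
planted pairs) can only partially tile sparsely sampled complexes, so
rarely pulled complexes surface with partial membership. These are the
figures `scripts/acceptance.R` recomputes from scratch.

## Numerical choices and degenerate inputs

* Pair universes contain only co-occurring pairs (`min_cooccurrence ≥ 1`);
  never-co-occurring pairs carry no evidence under any method.
* Jaccard-graph rule: an edge is kept when JD < 0.7 (the operational
  statement; the threshold is a parameter), and isolated experiments are
  dropped.
* The spectral-count reader accepts integers only; fractional counts
  (shared-peptide apportioning) are out of scope and rejected loudly.
* Degenerate evaluations fail fast: running sums need 0 < t < u, ROC
  needs both classes, Jaccard needs a non-empty union.
* Problem sizes in the test suite: oracle comparisons run on matrices up
  to 20 × 15 where brute force is exact and fast; the end-to-end study
  runs once at the full default configuration.

## Known limitations

* Complexes sharing subunits merge into one component by construction;
  the k-clique-percolation refinement was considered and left out in
  favour of the minimal component reading.
* Scores are co-complex evidence, not binding affinities; indirect
  within-complex pairs score as well as direct contacts.
* Repeated near-identical experiments inflate co-occurrence support;
  the similarity graph exposes such clusters but no down-weighting is
  applied.
* λ helps only when domain vocabularies are diverse; with few, widely
  shared domains it can demote genuinely supported pairs.
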