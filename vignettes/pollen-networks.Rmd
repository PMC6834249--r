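---
title: "Methods: pollen metabarcoding foraging networks"
author: "pollinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen metabarcoding foraging networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

## The problem this package addresses

Pollen pellets carried by individual bumblebees can be identified to plant
taxa by DNA metabarcoding (here: ITS2 amplicons clustered into OTUs). Two
downstream problems then dominate the analysis of such surveys:

1. **False-positive OTUs.** Tag switching, cross-talk and low-level
   contamination leave many OTUs with a handful of reads in samples they do
   not belong to. Leaving them in inflates diet breadth and network
   connectance; removing them with a fixed global read cutoff ignores the
   large differences in sequencing depth between samples.
2. **Quantifying foraging structure.** Once each pellet is reduced to a set
   of plant taxa with read counts, the colony's foraging can be described as
   a bipartite network (individual bumblebees × plant taxa) and summarised
   with node- and network-level indices, compared between experimental
   phases, and checked for sampling completeness.

`pollinet` implements this pipeline end to end for a paired design:
colonies (nests) sampled in a *before* and an *after* phase, with half the
nests receiving a treatment. All stages run on plain CSV tables and every
stochastic step is seeded.

## Per-sample ROC/Youden filtering of false positives

For each sample independently, every OTU is labelled *positive* (reads
> 0) or *negative* (0 reads). A quasipoisson GLM of reads on this binary
label is the model behind the threshold; because a two-group model with a
binary predictor is saturated, its fitted values are exactly the arithmetic
group means, $\mu_+$ and $\mu_- = 0$. We therefore compute the closed form
directly rather than iterating a log-link fit whose zero-group coefficient
diverges to $-\infty$; the quasipoisson Pearson $\chi^2/\mathrm{df}$
dispersion is still reported as a diagnostic.

A ROC curve is built with the fitted values as scores and the labels as
truth, and the operating threshold is placed at the Youden optimum
(maximising sensitivity + specificity − 1) using the midpoint convention
between consecutive distinct scores, with ties broken toward the smaller
cut. With two fitted values this yields

$$\mathrm{cut} = \frac{\mu_+ + \mu_-}{2} = \frac{\mu_+}{2},$$

and OTUs with reads **strictly below** the cut are zeroed out and recorded
as removed. Samples in which one label group is empty (no zero-read OTUs,
or no reads at all) carry no information for a two-group fit; they are
flagged unfilterable and passed through untouched.

Two properties of this construction are worth spelling out:

* **The score must be the fitted value, not the raw count.** Raw counts
  score every positive OTU above every (zero-read) negative, so any
  threshold between 0 and the smallest positive count is Youden-optimal and
  the filter degenerates to a no-op. The regression-based score is what
  makes the method a filter at all.
* **Thresholds are estimated once, on the raw data.** Filtering removes
  low-read OTUs, which raises the positive-group mean; re-estimating the
  threshold on already-filtered data can therefore cut genuine survivors
  (e.g. reads {1000, 260, 3}: the first pass cuts at 210.5 and removes only
  the 3; a re-fit on {1000, 260} would cut at 315 and remove the 260). The
  invariant the pipeline guarantees — and tests — is that re-applying the
  *recorded* per-sample cut is a no-op: every surviving count sits at or
  above its sample's threshold.

## Foraging networks and their indices

`build_networks()` assembles one weight matrix $W$ per (nest, phase): one
row per pellet (individual bumblebee), one column per plant taxon with a
nonzero total in that nest and phase, cells $b_{ij}$ equal to read counts.
Read counts are used as a quantitative proxy for pollen amounts; binary
versions ($W > 0$) are derived lazily by the indices that need them, and
marginal totals $b_{i\cdot}, b_{\cdot j}, b_{\cdot\cdot}$ are always
recomputed from the cells.

### Node level

* **degree** — taxa per pellet (binary).
* **resource range** $RR = (r-1)/(R-1)$ — used fraction of the $R$
  available plants; 0 for a one-plant specialist.
* **proportional generality** $PG = e^{H_p}/e^{H_q}$ — the bee's effective
  plant diversity over the effective diversity of the plant marginals
  (natural-log entropies).
* **PDI** — paired difference index with interactions scaled by their
  maximum before applying $1-\sum_{i\ge2}(P_{\max}-P_i)/(R-1)$; without
  that scaling the printed expression leaves $[0,1]$ (a single resource of
  weight 10 would give −9), contradicting its role as a bounded measure.
  Here 1 means uniform use of all $R$ resources and 0 a single resource.
* **d′** — Kullback–Leibler divergence of the bee's use shares from the
  availability shares $q_j = b_{\cdot j}/b_{\cdot\cdot}$, normalised by the
  achievable extremes given the bee's total and the plant marginals
  ($d' = (d - d_{\min})/(d_{\max} - d_{\min})$).
* **closeness centrality** for plants, on the plant-mode projection (two
  plants adjacent iff they share a bee), $CC = (R-1)/\sum_i d(v,i)$ with
  Wasserman–Faust scaling $(\mathrm{reachable}-1)/(R-1)$ on disconnected
  projections and 0 for isolated plants — bounded and monotone under added
  links. The projection choice is a design decision; a bipartite-graph
  variant is available via `mode = "bipartite"` but we make no claim about
  which variant other software used.

$R$ ("available resources") defaults to the plants realized in the focal
network; the full flowering-checklist size can be passed instead — both
conventions are defensible and the choice is exposed rather than hidden.

### Network level

* **Link density, generality, vulnerability** (Bersier's quantitative
  versions): $G$ and $V$ are marginal-weighted means of effective partner
  numbers $2^{H}$, with $H$ the base-2 entropy of a node's partner shares;
  $LD = (G+V)/2$ holds as an exact identity and is tested as one.
* **Connectance** $C = L/(I\,J)$ on the binarized matrix.
* **NODF / WNODF** (0–100): paired overlap under strictly decreasing fill;
  ties in the fill condition contribute zero. The weighted variant keeps
  the binary-fill condition and counts cells of the lower-fill row/column
  that are positive yet strictly smaller than the matching cell — the
  convention of the reference implementations (`vegan::nestednodf`, which
  the ecological-network packages defer to); our implementation is checked
  against `vegan` cell by cell.
* **Barber bipartite modularity**
  $Q = \frac{1}{m}\sum_{ij}\left(A_{ij} - \frac{k_i d_j}{m}\right)
  \delta(g_i, h_j)$, with a label-propagation optimizer in the
  DIRTLPAwb+ family: every node starts in its own module, nodes adopt the
  neighbour label with the best modularity gain (traversal order drawn
  from the seeded generator, ties to the lowest label), then whole modules
  are merged while $Q$ increases, and the best of `restarts` runs is kept.
  Only the $Q$ *evaluator* is contract-exact; the optimizer is a stochastic
  search whose reported $Q$ can never exceed the true optimum, and it
  attains the exhaustive-search optimum on ≥95% of small networks in the
  test suite.
* **H2′** — two-dimensional interaction diversity
  $H_2 = -\sum (b_{ij}/b_{\cdot\cdot})\ln(b_{ij}/b_{\cdot\cdot})$
  standardised as $(H_{2\max}-H_2)/(H_{2\max}-H_{2\min})$ so that 1 is
  perfect specialisation. $H_{2\min}$ comes from greedy
  largest-row-by-largest-column packing at the matrix's own integer
  resolution. For $H_{2\max}$ we use the entropy of the
  marginal-proportional fill, $H(\text{row shares}) + H(\text{col
  shares})$: it upper-bounds every matrix with those marginals
  (subadditivity), so the index cannot go negative. An integer-corrected
  maximum was considered and rejected — when marginal totals tie (e.g. a
  permutation matrix) every feasible integer matrix is an extreme one,
  $H_{2\max}$ collapses onto $H_{2\min}$, and the index loses its
  diagonal-equals-1 endpoint. Because the minimum is heuristic, the final
  value is clamped to $[0,1]$.

Entropy bases are intentionally mixed and follow each index's printed
formula: base 2 inside $LD/G/V$ (effective numbers as $2^H$), natural log
for $PG$, $d'$ and $H_2$.

### d′ extremes

$d_{\max}$ is exact: the divergence is convex in the use vector, so its
maximum over allocations of the bee's total sits on a vertex — all reads
on the plant with the smallest availability, giving
$d_{\max} = \ln(1/\min_j q_j)$. $d_{\min}$ is found on the integer grid at
the matrix's own resolution by a floor-of-proportional start, greedy
placement of the remaining units, and single-unit exchange passes; for a
separable convex objective over the integer simplex a point with no
improving single-unit move is globally optimal, so this is exact, and it is
verified against brute-force enumeration on small allocations. Working at
the matrix's integer resolution (units of the smallest positive cell) also
makes the normalised $d'$ — like $H_2'$ — exactly invariant to rescaling
the whole matrix.

## Comparing paired networks: the swap test

To test whether an index changed between the *before* and *after* network
of a nest, recorded interactions are randomly reassigned between the two
networks and the index difference recomputed each time; the two-sided
p-value is $(1 + \#\{|\Delta^{null}| \ge |\Delta^{obs}|\})/(n_{swaps}+1)$
(the add-one convention avoids $p = 0$).

The default swap unit is a **whole bee row**. The cells of one pellet are
not independent interactions — they were packed by one forager on one trip
— and the two networks have disjoint individual sets, so cell-level
swapping between differently shaped matrices is ill-defined. Row
reassignment preserves each network's row count and treats the pellet as
the exchangeable unit. A `unit = "cell"` mode (swap aligned plant-column
cells between randomly paired rows) is provided for sensitivity analysis,
not as the default inference. Indices are recomputed on each permuted
network after dropping plant columns that became empty, matching how the
per-phase matrices are built in the first place. The pooled rows are put
into a canonical order before permuting, which makes the p-value exactly
invariant to relabeling which network is "before".

Under the null (both networks drawn from one generative law) the p-values
of this test are approximately uniform; the test suite checks this by
simulation (200 replicate pairs, Kolmogorov–Smirnov test at α = 0.01).

## PERMANOVA and sampling coverage

Composition changes across the design are tested with PERMANOVA on the
samples × plants presence/absence matrix: Bray–Curtis distances (equal to
Sørensen on presence/absence), Gower-centred inner products, sequential
(Type-I) sums of squares in the fixed order *phase*, *treatment*, *nest*,
*phase × treatment*, and free permutation of sample rows. This is
delegated to `vegan::adonis2` — the standard implementation of exactly
this computation — behind `pollen_permanova()`; with four nests nested in
two treatment groups the nest term carries 2 df, and the $R^2$ of all
terms plus residual sums to 1 by construction. Jaccard distances are
available by flag.

Sampling completeness per nest uses the bias-corrected incidence form of
Chao2 from uniques $Q_1$ and duplicates $Q_2$ over $m$ sampling units:

$$\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1^2}{2 Q_2}\quad (Q_2>0),
\qquad
\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1(Q_1-1)}{2}\quad (Q_2=0),$$

with coverage $S_{obs}/\hat S$. The three-line estimator is implemented
directly and cross-checked against `vegan::specpool` in the tests.

## The synthetic-data generator

Every stage above is testable offline because `simulate_read_counts()`
generates read-count tables with known ground truth at the design scale of
the motivating field campaign: 4 nests (half treated), 18 pellets per nest
and phase, a 112-species flowering checklist.

Per pellet: the number of true taxa is zero-truncated Poisson clipped to
[1, 10]; taxa are drawn from a lognormal community-abundance profile;
total reads are lognormal; within-pellet read shares are
Dirichlet(1)-multinomial (uninformative, since no within-pellet share law
is available to emulate); and a configurable fraction of reads is carried
by false-positive OTUs — non-member taxa drawn proportional to global
abundance, each receiving a small geometric read count capped strictly
below the sample's smallest true count. Reads always sum to the drawn
total. The before/after composition change is implanted
phenomenologically, by log-space mixing of two abundance profiles with a
tunable `phase_shift` (larger shifts produce larger phase $R^2$ in
PERMANOVA, which is tested as a monotonicity property); no mechanistic
phenology is modelled.

The defaults were fixed once by solving the model's own identities rather
than by trial: the zero-truncated Poisson rate 1.9202 gives a mean of 2.25
taxa per pellet; the read-depth lognormal `sdlog = 0.4339` makes the
expected Youden threshold fraction, $E[1/(2 n_+)]$ under the resulting
distribution of positive-OTU counts $n_+$, equal the configured 2.28%
false-positive read fraction (a self-consistency of the noise model, and a
read-depth CV of ≈45%, typical of amplicon libraries); and the
community-abundance `sdlog = 4` makes roughly 34 of the 112 pool species
appear across a 144-pellet campaign. With `false_positive_rate = 0` every
nonzero OTU is a true taxon, which pins down the filter's ground truth.

`simulate_network_pair()` draws paired 18-row networks over a shared
12-plant pool (a typical realized per-nest richness for this kind of
survey); `structural_delta = "none"` is the null case for calibrating the
swap test, and the other deltas (`vulnerability_shift`,
`link_density_shift`, `module_merge`) implant directional changes of known
sign. `simulate_incidence()` produces presence/absence pools with a Beta
rare-species tail and known richness for validating Chao2.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: taxonomic mis-assignment, index hopping
between samples (false positives are drawn independently per sample),
chimeras, phenological turnover within a phase, repeat visits by the same
individual, or any correlation between a plant's abundance and its pollen
production rank. Trait ranks are drawn independently of abundance.

## Numerical conventions and degenerate inputs

* Seeds: every stochastic routine takes an explicit integer seed;
  identical seeds give byte-identical outputs, including the full
  permutation null distributions and the label-propagation trajectories.
* Ties: Youden ties break toward the smaller threshold; label-propagation
  ties toward the lowest module label; NODF fill ties contribute zero.
* Degenerate inputs: empty matrices, single-row/column networks,
  single-group samples, constant design factors and header-only files all
  raise early, specific errors (or documented warnings with pass-through
  behaviour) rather than propagating NaNs.
* Scale invariance: all quantitative indices are invariant to multiplying
  the matrix by a positive constant; for the two normalised indices this
  required fixing the discretization grid at the matrix's own integer
  resolution.

## Problem sizes used by the test suite

The suite exercises the index oracle equivalences exhaustively on all 512
binary 3×3 matrices plus 200 random weighted 6×6 matrices; the modularity
optimizer against exhaustive partition search on 100 random networks of up
to 7 nodes (20 restarts each); swap-test calibration on 200 replicate
null pairs of 18-row networks (199 swaps each); PERMANOVA type-I error on
500 null simulations of ~40 samples (199 permutations each); and filter
recovery on a 400-pellet synthetic campaign. These sizes give the Monte
Carlo resolution the corresponding tolerances need while keeping the whole
suite desk-scale.

## Known limitations

* The ROC reconstruction (fitted-value scores, midpoint convention) is one
  defensible reading of a procedure whose published description is
  ambiguous about the score variable and threshold convention; variant
  choices would shift per-sample cuts and are deliberately not presented
  as settled.
* The H2′ minimum and the modularity optimum are heuristic searches;
  both are bounded on the correct side and tested against exhaustive
  oracles at small sizes, but neither carries a global guarantee at field
  scale.
* The swap test conditions on the realized row counts and treats pellets
  as exchangeable units; it does not model within-colony dependence
  between pellets of the same trip or day.
* PERMANOVA terms are sequential, so the reported $R^2$ of later terms
  depends on the fixed term order; this mirrors the analysis convention
  the pipeline targets rather than a causal decomposition.
* Chao2 is a lower-bound-type estimator: with strongly heterogeneous
  detection probabilities its coverage estimates are conservative.
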