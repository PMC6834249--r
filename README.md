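# pollinet

Downstream analysis of pollen DNA-metabarcoding surveys of social
pollinators. Starting from per-sample OTU read-count tables (one pollen
pellet per individual bumblebee), `pollinet`:

1. **filters false-positive OTUs** per sample with a ROC/Youden threshold
   on a two-group overdispersed-Poisson fit — OTUs are labelled positive
   (reads > 0) or negative (0 reads), the fitted group means `μ₊, μ₋` serve
   as ROC scores, and the Youden-optimal midpoint `cut = (μ₊ + μ₋)/2`
   removes OTUs with reads strictly below it;
2. **builds bipartite foraging networks** (individual bumblebees × plant
   taxa, weights = read counts) per nest and experimental phase;
3. **computes the standard index suites** — node level: degree, resource
   range `RR = (r−1)/(R−1)`, proportional generality `e^{H_p}/e^{H_q}`,
   paired difference index, complementary specialization `d′` (normalised
   KL divergence from availability), plant closeness centrality; network
   level: quantitative link density `LD = (G+V)/2`, connectance
   `C = L/(I·J)`, nestedness NODF/WNODF (0–100), Barber bipartite
   modularity `Q = (1/m)Σ(A_ij − k_i d_j/m)δ(g_i,h_j)` with a seeded
   DIRTLPAwb+-style label-propagation optimizer, complementary
   specialization `H2′`, generality and vulnerability;
4. **compares paired before/after networks** with a permutation swap test
   (whole pellets reassigned between the two networks; add-one two-sided
   p-value);
5. runs **PERMANOVA** on pollen presence/absence composition (Bray–Curtis,
   sequential SS: phase, treatment, nest, phase×treatment; via
   `vegan::adonis2`) and estimates **Chao2 sampling coverage** per nest;
6. ships a **seeded synthetic-data generator** that emulates the paired
   colony design (4 nests, 18 pellets per nest and phase, 112-species
   plant pool, ~2.25 taxa per pellet, 2.28% cross-talk reads), so the
   entire pipeline is testable with known ground truth and no sequence
   data.

Intended users: pollination ecologists and metabarcoding bioinformaticians
who have already clustered and assigned their reads and need a principled,
reproducible route from read-count tables to filtered diets, network
indices and design-level inference.

## Worked example

```r
library(pollinet)

sim <- simulate_read_counts(synth_config(seed = 42))  # 144 pellets, ground truth known
fd  <- filter_dataset(sim$table)                      # per-sample ROC/Youden filter
diet <- summarize_diet(fd$filtered)
nets <- build_networks(fd$filtered)                   # 8 networks: 4 nests x 2 phases

network_indices(nets[["NT1_B"]], restarts = 20, seed = 42)
network_swap_test(nets[["NT1_B"]], nets[["NT1_A"]], index = "LD",
                  n_swaps = 10000, seed = 42)
pollen_permanova(fd$filtered, n_perm = 999, seed = 42)
```

which prints (seed 42):

```
removed 136591 reads; mean threshold = 2.19% of a sample reads
39 plant taxa; 2.12 taxa/pellet (sd 1.10, range 1-6); 49 monofloral pellets
    index  value
1      LD  3.665
2       C  0.158
3    NODF 32.796
4   WNODF 12.691
5       Q  0.510
6      Qw  0.577
7 H2prime  0.781
8       G  1.784
9       V  5.546
permutation swap test (LD, unit = row): before = 3.665, after = 2.263,
  diff = -1.401, p = 0.0007999 (10000 swaps)
   term df SumOfSqs   R2    F     p
1 phase  1     9.35 0.16 26.9 0.001
```

Reading this: the filter's per-sample thresholds averaged 2.19% of each
sample's reads; the treated nest's *before* network had a quantitative
link density of 3.67 (each pellet/plant had ~1.8/5.5 effective partners),
moderate nestedness and fairly high complementary specialization; the
link-density drop after the workforce manipulation is larger than almost
all row-swap permutations (p ≈ 0.0008); and the experimental phase
explains 16% of the variation in pollen composition. On real data, start
from `read_read_counts()` (sample × OTU CSV) or — for already-filtered
individual × plant interaction tables with nest/treatment/phase columns —
`read_interactions()`, and run the same calls, or everything at once with
`run_pipeline()`. A thin command-line wrapper with the same subcommands
lives in `inst/cli/pollinet.R`.

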