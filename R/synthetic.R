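#' Configuration for the synthetic pollen-metabarcoding generator
#'
#' Defaults emulate the study design the pipeline targets: 4 nests (half
#' treated), 18 pellets per nest and phase, a 112-species flowering-plant
#' checklist, a zero-truncated Poisson number of true taxa per pellet with
#' mean 2.25 (clipped to 1..10), lognormal sequencing depth with mean
#' 3.9e4 reads, and 2.28% of each sample's reads redistributed as low-count
#' cross-talk false positives averaging 36 reads each.
#'
#' The non-printed parameters were fixed once by solving the model's own
#' identities: `taxa_lambda = 1.9202` gives a zero-truncated-Poisson mean of
#' 2.25; `reads_sdlog = 0.4339` makes the expected per-sample Youden
#' threshold fraction equal the 2.28% false-positive read fraction;
#' `abundance_sdlog = 4` makes roughly 34 of the 112 pool species appear
#' across a 144-sample campaign (counting both phase profiles).
#'
#' @param n_nests number of nests; the first half are treated.
#' @param n_samples_per_nest_phase pellets sampled per nest per phase.
#' @param plant_pool_size size of the flowering checklist pool.
#' @param taxa_mean mean true taxa per pellet (zero-truncated Poisson mean).
#' @param taxa_max upper clip for true taxa per pellet.
#' @param reads_mean mean total reads per sample (lognormal).
#' @param reads_sdlog lognormal sd (log scale) of total reads.
#' @param false_positive_rate expected fraction of a sample's reads carried
#'   by false-positive OTUs; in `[0, 1]`.
#' @param fp_mean_reads mean reads per false-positive OTU (geometric law).
#' @param abundance_sdlog lognormal sd of the plant-pool abundance profile.
#' @param dirichlet_concentration concentration of within-pellet read shares.
#' @param trait_probs probabilities over pollen-quantity ranks P0..P5.
#' @param phase_shift size in `[0, 1]` of the before/after community
#'   composition change (0 = none).
#' @param treat_shift selectivity shift of treated colonies after removal
#'   (>= 0; scales down their per-pellet taxon count).
#' @param network_plants shared plant-pool size used by
#'   [simulate_network_pair()].
#' @param seed integer seed; identical seeds give identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_nests = 4L,
                         n_samples_per_nest_phase = 18L,
                         plant_pool_size = 112L,
                         taxa_mean = 2.25,
                         taxa_max = 10L,
                         reads_mean = 3.9e4,
                         reads_sdlog = 0.4339,
                         false_positive_rate = 0.0228,
                         fp_mean_reads = 36,
                         abundance_sdlog = 4,
                         dirichlet_concentration = 1,
                         trait_probs = c(P0 = 0.05, P1 = 0.2, P2 = 0.25,
                                         P3 = 0.25, P4 = 0.15, P5 = 0.1),
                         phase_shift = 0.5,
                         treat_shift = 0,
                         network_plants = 12L,
                         seed = 1L) {
  if (false_positive_rate < 0 || false_positive_rate > 1)
    stop("synth_config: false_positive_rate must lie in [0, 1]")
  if (phase_shift < 0 || phase_shift > 1)
    stop("synth_config: phase_shift must lie in [0, 1]")
  if (taxa_max < 1) stop("synth_config: taxa_max must be >= 1")
  if (plant_pool_size < taxa_max)
    stop("synth_config: plant pool smaller than the maximum per-pellet taxon count")
  cfg <- list(n_nests = as.integer(n_nests),
              n_samples_per_nest_phase = as.integer(n_samples_per_nest_phase),
              plant_pool_size = as.integer(plant_pool_size),
              taxa_mean = taxa_mean,
              taxa_lambda = ztp_lambda(taxa_mean),
              taxa_max = as.integer(taxa_max),
              reads_mean = reads_mean,
              reads_sdlog = reads_sdlog,
              false_positive_rate = false_positive_rate,
              fp_mean_reads = fp_mean_reads,
              abundance_sdlog = abundance_sdlog,
              dirichlet_concentration = dirichlet_concentration,
              trait_probs = trait_probs / sum(trait_probs),
              phase_shift = phase_shift,
              treat_shift = treat_shift,
              network_plants = as.integer(network_plants),
              seed = as.integer(seed))
  structure(cfg, class = "synth_config")
}

# lambda of a zero-truncated Poisson with the requested mean
ztp_lambda <- function(mean_taxa) {
  if (mean_taxa <= 1) stop("ztp_lambda: truncated mean must exceed 1")
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean_taxa,
                 c(1e-8, 100), tol = 1e-10)$root
}

# one zero-truncated Poisson draw, clipped to [1, kmax]
rztpois <- function(n, lambda, kmax) {
  k <- stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
  pmin(pmax(k, 1L), kmax)
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (all(g == 0)) g <- rep(1, k)
  g / sum(g)
}

# community abundance profiles: a base lognormal profile and a phase-shifted
# one obtained by log-space mixing with an independent profile
community_weights <- function(cfg) {
  base <- stats::rlnorm(cfg$plant_pool_size, 0, cfg$abundance_sdlog)
  alt <- stats::rlnorm(cfg$plant_pool_size, 0, cfg$abundance_sdlog)
  after <- exp((1 - cfg$phase_shift) * log(base) + cfg$phase_shift * log(alt))
  list(before = base / sum(base), after = after / sum(after))
}

#' Simulate per-sample OTU read-count tables with known ground truth
#'
#' Each pellet receives a zero-truncated-Poisson number of true plant taxa
#' drawn from the (phase-specific) community abundance profile; its reads are
#' split over those taxa by Dirichlet-multinomial shares. A configurable
#' fraction of reads is then carried by false-positive OTUs: taxa the pellet
#' does not contain, drawn proportionally to their global abundance, each
#' receiving a small geometric read count capped below the sample's smallest
#' true-taxon count. Reads always sum to the sample's drawn total.
#'
#' @param config a [synth_config()].
#' @return list with `table` (a [read_count_table()] over the full pool),
#'   `truth` (named list: sample id -> character vector of true taxa),
#'   `weights` (the community profiles) and `config`.
#' @export
simulate_read_counts <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  pool <- sprintf("sp%03d", seq_len(cfg$plant_pool_size))
  w <- community_weights(cfg)

  treated <- seq_len(cfg$n_nests) <= cfg$n_nests / 2
  design <- expand.grid(nest = seq_len(cfg$n_nests), phase = c("before", "after"),
                        rep = seq_len(cfg$n_samples_per_nest_phase),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(design$nest, design$phase, design$rep), ]
  n <- nrow(design)

  counts <- matrix(0L, n, cfg$plant_pool_size, dimnames = list(NULL, pool))
  truth <- vector("list", n)
  sample_id <- character(n)

  for (s in seq_len(n)) {
    nest <- design$nest[s]; phase <- design$phase[s]
    weights <- if (phase == "before") w$before else w$after
    lam <- cfg$taxa_lambda
    # treated colonies after removal can be made more selective
    if (treated[nest] && phase == "after" && cfg$treat_shift > 0)
      lam <- lam * exp(-cfg$treat_shift)
    k <- rztpois(1, lam, cfg$taxa_max)
    taxa <- sample.int(cfg$plant_pool_size, k, prob = weights)
    total <- max(50L, as.integer(round(stats::rlnorm(
      1, log(cfg$reads_mean) - cfg$reads_sdlog^2 / 2, cfg$reads_sdlog))))

    # false positives: number from the Poisson budget, counts geometric
    n_fp <- if (cfg$false_positive_rate > 0)
      stats::rpois(1, cfg$false_positive_rate * total / cfg$fp_mean_reads) else 0L
    n_fp <- min(n_fp, cfg$plant_pool_size - k)
    fp_taxa <- if (n_fp > 0) {
      pw <- weights[-taxa]
      setdiff(seq_len(cfg$plant_pool_size), taxa)[
        sample.int(cfg$plant_pool_size - k, n_fp, prob = pw)]
    } else integer(0)
    fp_reads <- if (n_fp > 0) 1L + stats::rgeom(n_fp, 1 / cfg$fp_mean_reads) else integer(0)

    true_total <- total - sum(fp_reads)
    if (true_total < k) { # pathological tiny sample: drop false positives
      fp_taxa <- integer(0); fp_reads <- integer(0); true_total <- total
    }
    shares <- rdirichlet1(k, cfg$dirichlet_concentration)
    true_reads <- as.integer(1L + stats::rmultinom(1, true_total - k, prob = shares))

    # cap false positives strictly below the smallest true count; returned
    # budget goes to the dominant true taxon so reads still sum to the total
    if (length(fp_reads)) {
      cap <- min(true_reads) - 1L
      if (cap < 1L) {
        fp_taxa <- integer(0); fp_reads <- integer(0)
        true_reads[which.max(true_reads)] <- true_reads[which.max(true_reads)] +
          total - sum(true_reads)
      } else {
        over <- fp_reads > cap
        spare <- sum(fp_reads[over] - cap)
        fp_reads[over] <- cap
        true_reads[which.max(true_reads)] <- true_reads[which.max(true_reads)] + spare
      }
    }
    counts[s, taxa] <- true_reads
    if (length(fp_taxa)) counts[s, fp_taxa] <- fp_reads
    sample_id[s] <- sprintf("%s%d_%s_BB%d",
                            if (treated[nest]) "NT" else "NC", nest,
                            if (phase == "before") "B" else "A", design$rep[s])
    truth[[s]] <- pool[sort(taxa)]
  }
  names(truth) <- sample_id
  meta <- data.frame(sample_id = sample_id,
                     nest_id = design$nest,
                     treatment = ifelse(treated[design$nest], "treated", "control"),
                     phase = design$phase,
                     stringsAsFactors = FALSE)
  list(table = read_count_table(counts, meta), truth = truth,
       weights = w, config = cfg)
}

#' Simulate a pair of foraging networks with a known structural difference
#'
#' Draws two individual-by-plant networks over a shared plant pool. With
#' `structural_delta = "none"` both come from the same generative law (the
#' null case for permutation-test calibration); the other deltas implant a
#' known directional change in the second network.
#'
#' @param config a [synth_config()]; `network_plants` rows the shared pool.
#' @param structural_delta one of `"none"`, `"vulnerability_shift"`
#'   (second network concentrates onto fewer plants), `"link_density_shift"`
#'   (second network halves its per-pellet taxon count) or `"module_merge"`
#'   (first network is two-block modular, second mixes the blocks, so its
#'   weighted modularity is lower by construction).
#' @param n_bees rows per network.
#' @return list of two [interaction_matrix()] objects (`before`, `after`).
#' @export
simulate_network_pair <- function(config = synth_config(),
                                  structural_delta = c("none", "vulnerability_shift",
                                                       "link_density_shift", "module_merge"),
                                  n_bees = 18L) {
  cfg <- config
  structural_delta <- match.arg(structural_delta)
  J <- cfg$network_plants
  if (J < 4L) stop("simulate_network_pair: need >= 4 plants in the shared pool")
  if (structural_delta == "module_merge" && J < 6L)
    stop("simulate_network_pair: module_merge needs >= 6 plants")
  set.seed(cfg$seed)
  plants <- sprintf("sp%03d", seq_len(J))
  wpool <- stats::rlnorm(J, 0, 1)

  draw_net <- function(weights, lambda, kmax, phase, block = NULL) {
    W <- matrix(0, n_bees, J, dimnames = list(paste0("BB", seq_len(n_bees)), plants))
    for (i in seq_len(n_bees)) {
      wgt <- weights
      if (!is.null(block)) { # two-module structure: bees use only their block
        mine <- if (i <= n_bees / 2) seq_len(floor(J / 2)) else (floor(J / 2) + 1):J
        wgt <- replace(rep(1e-12, J), mine, weights[mine])
      }
      k <- rztpois(1, lambda, min(kmax, J))
      taxa <- sample.int(J, k, prob = wgt)
      total <- max(50L, as.integer(round(stats::rlnorm(
        1, log(cfg$reads_mean) - cfg$reads_sdlog^2 / 2, cfg$reads_sdlog))))
      W[i, taxa] <- as.integer(1L + stats::rmultinom(
        1, total - k, prob = rdirichlet1(k, cfg$dirichlet_concentration)))
    }
    interaction_matrix(W[, colSums(W) > 0, drop = FALSE],
                       nest_id = 1L, phase = phase, treatment = "treated")
  }

  lam <- cfg$taxa_lambda
  before <- switch(structural_delta,
                   module_merge = draw_net(wpool, lam, cfg$taxa_max, "before", block = TRUE),
                   draw_net(wpool, lam, cfg$taxa_max, "before"))
  after <- switch(structural_delta,
                  none = draw_net(wpool, lam, cfg$taxa_max, "after"),
                  vulnerability_shift = draw_net(wpool^4 / sum(wpool^4), lam,
                                                 cfg$taxa_max, "after"),
                  link_density_shift = draw_net(wpool, lam / 2, cfg$taxa_max, "after"),
                  module_merge = draw_net(wpool, lam, cfg$taxa_max, "after"))
  list(before = before, after = after)
}

#' Simulate a sampling-unit-by-species incidence matrix
#'
#' Presence/absence data with a known true richness, for validating
#' incidence-based richness estimators. Per-species detection probabilities
#' follow a Beta law whose default shape produces a rare-species tail.
#'
#' @param config a [synth_config()] (supplies the seed).
#' @param n_units number of sampling units (>= 2).
#' @param richness true species richness of the pool.
#' @param detect_shape1,detect_shape2 Beta parameters of detection
#'   probabilities.
#' @return 0/1 matrix (`n_units` x `richness`) with attribute
#'   `true_richness`.
#' @export
simulate_incidence <- function(config = synth_config(), n_units = 20L,
                               richness = 34L, detect_shape1 = 0.5,
                               detect_shape2 = 1.5) {
  if (n_units < 2L) stop("simulate_incidence: need >= 2 sampling units")
  set.seed(config$seed)
  p <- stats::rbeta(richness, detect_shape1, detect_shape2)
  m <- matrix(stats::rbinom(n_units * richness, 1, rep(p, each = n_units)),
              n_units, richness,
              dimnames = list(sprintf("unit%02d", seq_len(n_units)),
                              sprintf("sp%03d", seq_len(richness))))
  attr(m, "true_richness") <- as.integer(richness)
  m
}
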