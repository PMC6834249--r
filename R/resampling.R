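#' Permutation swap test comparing two foraging networks
#'
#' Tests whether a network index differs between the "before" and "after"
#' networks of a nest by randomly reassigning recorded interactions between
#' the two networks. The default swap unit is a whole bee row (one
#' individual's pellet): the pooled rows are redistributed between the two
#' networks preserving each network's row count, because the cells of one
#' pellet are not independent interactions and the two networks have
#' disjoint individual sets. `unit = "cell"` instead swaps aligned
#' plant-column cells between randomly paired rows, as a sensitivity
#' analysis. After each swap the index difference is recomputed on networks
#' restricted to their own realized plant sets, and a two-sided p-value is
#' obtained with the add-one convention.
#'
#' @param net_before,net_after [interaction_matrix()] objects (aligned on
#'   the union plant set internally).
#' @param index index name as in [network_indices()]: one of `"LD"`, `"C"`,
#'   `"NODF"`, `"WNODF"`, `"Q"`, `"Qw"`, `"H2prime"`, `"G"`, `"V"`.
#' @param n_swaps number of permutations (a warning is raised below 100).
#' @param seed integer seed; identical seeds reproduce the null
#'   distribution exactly.
#' @param unit `"row"` (default) or `"cell"`.
#' @param restarts modularity restarts per evaluation when `index` is
#'   `"Q"`/`"Qw"` (kept small inside the permutation loop).
#' @return list of class `permutation_result`: `index`, `observed_before`,
#'   `observed_after`, `observed_diff` (after - before), `null_diffs`,
#'   `p_value`, `n_swaps`, `seed`, `unit`.
#' @export
network_swap_test <- function(net_before, net_after, index = "LD",
                              n_swaps = 10000L, seed = 1L,
                              unit = c("row", "cell"), restarts = 4L) {
  unit <- match.arg(unit)
  if (n_swaps < 100) warning("network_swap_test: n_swaps < 100 gives a coarse p-value")
  f <- index_function(index, restarts = restarts, seed = seed)
  al <- align_networks(net_before, net_after)
  W1 <- al$W1; W2 <- al$W2
  obs_b <- f(drop_empty_cols(W1))
  obs_a <- f(drop_empty_cols(W2))
  obs <- obs_a - obs_b
  r1 <- nrow(W1); r2 <- nrow(W2)
  pool <- rbind(W1, W2)
  # canonical pooled-row order, so the null distribution (and hence p) is
  # exactly invariant to relabeling which network is "before"
  ord <- order(apply(pool, 1, paste, collapse = "\r"))
  pool <- pool[ord, , drop = FALSE]
  n <- nrow(pool)
  set.seed(seed)
  null_diffs <- vapply(seq_len(n_swaps), function(b) {
    if (unit == "row") {
      pick <- sample.int(n, min(r1, r2))
      if (r1 <= r2) {
        A <- pool[pick, , drop = FALSE]
        B <- pool[-pick, , drop = FALSE]
      } else {
        B <- pool[pick, , drop = FALSE]
        A <- pool[-pick, , drop = FALSE]
      }
    } else {
      A <- W1; B <- W2
      np <- min(nrow(W1), nrow(W2))
      p1 <- sample.int(nrow(W1), np); p2 <- sample.int(nrow(W2), np)
      swap <- matrix(stats::runif(np * ncol(W1)) < 0.5, np, ncol(W1))
      Ai <- A[p1, , drop = FALSE]; Bi <- B[p2, , drop = FALSE]
      tmp <- Ai
      Ai[swap] <- Bi[swap]; Bi[swap] <- tmp[swap]
      A[p1, ] <- Ai; B[p2, ] <- Bi
    }
    A <- A[rowSums(A) > 0, , drop = FALSE]
    B <- B[rowSums(B) > 0, , drop = FALSE]
    f(drop_empty_cols(B)) - f(drop_empty_cols(A))
  }, numeric(1))
  p <- (1 + sum(abs(null_diffs) >= abs(obs) - 1e-12)) / (n_swaps + 1)
  structure(list(index = index, observed_before = obs_b, observed_after = obs_a,
                 observed_diff = obs, null_diffs = null_diffs, p_value = p,
                 n_swaps = as.integer(n_swaps), seed = as.integer(seed),
                 unit = unit),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation swap test (%s, unit = %s): before = %.4g, after = %.4g, diff = %.4g, p = %.4g (%d swaps)\n",
              x$index, x$unit, x$observed_before, x$observed_after,
              x$observed_diff, x$p_value, x$n_swaps))
  invisible(x)
}

# resolve an index name to a function of a weight matrix
index_function <- function(index, restarts = 4L, seed = 1L) {
  switch(index,
         LD = link_density,
         C = connectance,
         NODF = function(W) nodf(W, weighted = FALSE),
         WNODF = function(W) nodf(W, weighted = TRUE),
         Q = function(W) modularity_lpa(W, weighted = FALSE,
                                        restarts = restarts, seed = seed)$Q,
         Qw = function(W) modularity_lpa(W, weighted = TRUE,
                                         restarts = restarts, seed = seed)$Q,
         H2prime = h2prime,
         G = function(W) generality_vulnerability(W)$G,
         V = function(W) generality_vulnerability(W)$V,
         stop("unknown index: ", index))
}

# pad two networks onto their union plant set
align_networks <- function(net1, net2) {
  W1 <- as_weight_matrix(net1); W2 <- as_weight_matrix(net2)
  plants <- sort(unique(c(colnames(W1), colnames(W2))))
  pad <- function(W) {
    M <- matrix(0, nrow(W), length(plants), dimnames = list(rownames(W), plants))
    M[, colnames(W)] <- W
    M
  }
  list(W1 = pad(W1), W2 = pad(W2), plants = plants)
}

drop_empty_cols <- function(W) W[, colSums(W) > 0, drop = FALSE]

#' PERMANOVA on pollen presence/absence composition
#'
#' Permutational multivariate analysis of variance of the samples-by-plants
#' presence/absence matrix against the experimental design, with pairwise
#' Bray-Curtis distances (equal to Sorensen on presence/absence) and
#' sequential (Type-I) sums of squares in the order experimental phase,
#' treated/control, nest identity, phase x treatment; p-values come from
#' free permutation of sample rows. Fitted with `vegan::adonis2`.
#'
#' @param comm samples-by-plants matrix (binarized internally) or a
#'   [read_count_table()] (its metadata then supplies `meta`).
#' @param meta data.frame with `phase`, `treatment`, `nest_id` per sample;
#'   ignored when `comm` is a [read_count_table()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param method distance index for `vegan::vegdist` (default Bray-Curtis;
#'   `"jaccard"` available).
#' @return data.frame with `term`, `df`, `SumOfSqs`, `R2`, `F`, `p`;
#'   `R2` over all terms plus residual sums to 1.
#' @export
pollen_permanova <- function(comm, meta = NULL, n_perm = 999L, seed = 1L,
                             method = "bray") {
  if (inherits(comm, "read_count_table")) {
    meta <- comm$meta
    comm <- comm$counts
  }
  if (is.null(meta)) stop("pollen_permanova: metadata required")
  keep <- rowSums(comm) > 0
  comm <- comm[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  pa <- (comm > 0) * 1
  meta <- data.frame(phase = factor(meta$phase),
                     treatment = factor(meta$treatment),
                     nest_id = factor(meta$nest_id))
  for (v in names(meta)) {
    if (nlevels(droplevels(meta[[v]])) < 2)
      stop("pollen_permanova: factor '", v, "' is constant")
    if (min(table(meta[[v]])) < 2)
      stop("pollen_permanova: need >= 2 samples per level of '", v, "'")
  }
  d <- vegan::vegdist(pa, method = method)
  set.seed(seed)
  fit <- vegan::adonis2(d ~ phase + treatment + nest_id + phase:treatment,
                        data = meta, permutations = n_perm, by = "terms")
  data.frame(term = rownames(fit), df = fit$Df, SumOfSqs = fit$SumOfSqs,
             R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chao2 richness estimate and sampling coverage
#'
#' Bias-corrected incidence-based Chao2 estimator of asymptotic species
#' richness from uniques (species in exactly one sampling unit, `Q1`) and
#' duplicates (`Q2`):
#' `chao2 = S_obs + ((m-1)/m) * Q1^2 / (2*Q2)` when `Q2 > 0`, else
#' `S_obs + ((m-1)/m) * Q1*(Q1-1)/2`. Coverage is `S_obs / chao2`.
#'
#' @param incidence sampling-units-by-species matrix; any positive entry
#'   counts as a detection.
#' @return list of class `incidence_summary`: `S_obs`, `Q1`, `Q2`, `m`,
#'   `chao2`, `coverage`.
#' @export
chao2_coverage <- function(incidence) {
  x <- as.matrix(incidence)
  if (!nrow(x) || !ncol(x) || sum(x) == 0) stop("chao2_coverage: empty matrix")
  if (nrow(x) < 2) stop("chao2_coverage: need >= 2 sampling units")
  inc <- colSums(x > 0)
  S_obs <- sum(inc > 0)
  Q1 <- sum(inc == 1)
  Q2 <- sum(inc == 2)
  m <- nrow(x)
  chao2 <- if (Q2 > 0) S_obs + ((m - 1) / m) * Q1^2 / (2 * Q2)
           else S_obs + ((m - 1) / m) * Q1 * (Q1 - 1) / 2
  structure(list(S_obs = S_obs, Q1 = Q1, Q2 = Q2, m = m,
                 chao2 = chao2, coverage = S_obs / chao2),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("Chao2: S_obs = %d, Q1 = %d, Q2 = %d over m = %d units -> %.2f species (coverage %.1f%%)\n",
              x$S_obs, x$Q1, x$Q2, x$m, x$chao2, 100 * x$coverage))
  invisible(x)
}
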