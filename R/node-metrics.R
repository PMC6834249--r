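#' Degree of a bumblebee
#'
#' Number of plant taxa found in the bee's pollen pellet (nonzero cells of
#' its row; binary information only).
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param bee row name or index.
#' @return integer degree.
#' @export
node_degree <- function(net, bee) {
  W <- as_weight_matrix(net)
  row <- bee_row(W, bee)
  sum(row > 0)
}

bee_row <- function(W, bee) {
  if (is.character(bee) && !bee %in% rownames(W))
    stop("unknown bumblebee: ", bee)
  W[bee, ]
}

#' Resource range of a bumblebee
#'
#' Fraction of the available plant resources the bee actually used:
#' `RR = 1 - (R - r)/(R - 1) = (r - 1)/(R - 1)`, where `R` is the number of
#' available plants and `r` the bee's degree. 0 for an extreme specialist
#' (one plant), 1 when every available plant is used.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param bee row name or index.
#' @param R available-resource count; defaults to the plants present in the
#'   network, but the full flowering-checklist size can be passed instead.
#' @return numeric in `[0, 1]`.
#' @export
resource_range <- function(net, bee, R = ncol(as_weight_matrix(net))) {
  if (R < 2) stop("resource_range: need R >= 2 available resources")
  r <- node_degree(net, bee)
  if (r > R) stop("resource_range: degree exceeds available resources")
  (r - 1) / (R - 1)
}

#' Proportional generality of a bumblebee
#'
#' Quantitative diversity of the bee's plant use relative to the potential
#' resources: `exp(H_p) / exp(H_q)`, where `H_p` is the (natural-log)
#' Shannon entropy of the bee's partner shares and `H_q` that of the plant
#' marginal shares `b_.j / b..`.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param bee row name or index.
#' @return positive numeric (1 when the bee's use mirrors availability).
#' @export
proportional_generality <- function(net, bee) {
  W <- as_weight_matrix(net)
  row <- bee_row(W, bee)
  if (sum(row) <= 0) stop("proportional_generality: zero row")
  exp(shannon(row)) / exp(shannon(colSums(W)))
}

#' Paired Difference Index of a bumblebee
#'
#' Compares the strongest quantitative interaction with all remaining ones:
#' with interactions scaled so the largest equals 1 and sorted decreasingly,
#' `PDI = 1 - sum_{i=2..R} (1 - P_i) / (R - 1)`. 1 means uniform use of all
#' `R` available resources, 0 a single resource. (Without the `P_max`
#' scaling the expression would leave `[0, 1]`.)
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param bee row name or index.
#' @param R available-resource count (defaults to plants in the network).
#' @return numeric in `[0, 1]`.
#' @export
pdi <- function(net, bee, R = ncol(as_weight_matrix(net))) {
  if (R < 2) stop("pdi: need R >= 2 available resources")
  W <- as_weight_matrix(net)
  row <- bee_row(W, bee)
  if (sum(row) <= 0) stop("pdi: zero row")
  P <- sort(row, decreasing = TRUE) / max(row)
  P <- c(P, rep(0, max(0, R - length(P))))[seq_len(R)]
  1 - sum(1 - P[-1]) / (R - 1)
}

#' Complementary specialization d' of a bumblebee
#'
#' Kullback-Leibler divergence of the bee's partner-use shares `p'_ij` from
#' the plant availability shares `q_j = b_.j / b..`, normalised to `[0, 1]`
#' by the achievable extremes given the bee's integer read total and the
#' plant marginals: `d' = (d - d_min) / (d_max - d_min)`. `d_max` is attained
#' by concentrating the whole total on the rarest plant (the divergence is
#' convex in the use vector, so its maximum sits on a vertex); `d_min` is the
#' discrete allocation closest to proportionality, found by a floor-of-
#' proportional start plus greedy remainder and single-unit exchange passes
#' (exact for this separable convex objective).
#'
#' @param net an [interaction_matrix()] or matrix (integer read counts).
#' @param bee row name or index.
#' @param raw if `TRUE` return the unnormalised divergence.
#' @return numeric in `[0, 1]` (or the raw divergence).
#' @export
d_prime <- function(net, bee, raw = FALSE) {
  W <- as_weight_matrix(net)
  row <- bee_row(W, bee)
  t <- sum(row)
  if (t <= 0) stop("d_prime: zero row")
  q <- colSums(W) / sum(W)
  d_obs <- kl_use(row, q)
  if (raw) return(d_obs)
  # the d_min allocation grid sits at the matrix's own integer resolution,
  # which keeps the normalized index invariant to rescaling the matrix
  t_int <- max(1, round(t / min(W[W > 0])))
  d_max <- log(1 / min(q[q > 0]))
  d_min <- kl_use(min_kl_allocation(t_int, q), q)
  if (d_max - d_min < 1e-12) return(0)
  min(1, max(0, (d_obs - d_min) / (d_max - d_min)))
}

kl_use <- function(a, q) {
  p <- a / sum(a)
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

# integer allocation of t units over plants minimizing KL(p' || q);
# exact: floor of proportional start, greedy remainder, then single-unit
# exchange passes (sufficient for separable convex objectives on the simplex)
min_kl_allocation <- function(t, q) {
  J <- length(q)
  f <- function(a, j) if (a == 0) 0 else a * log(a / (t * q[j])) # t * contribution
  a <- floor(t * q)
  # objective is +Inf whenever a_j > 0 with q_j = 0; never allocate there
  usable <- which(q > 0)
  while (sum(a) < t) {
    gain <- vapply(usable, function(j) f(a[j] + 1, j) - f(a[j], j), numeric(1))
    j <- usable[which.min(gain)]
    a[j] <- a[j] + 1
  }
  repeat {
    improved <- FALSE
    from <- which(a > 0)
    dec <- vapply(from, function(j) f(a[j] - 1, j) - f(a[j], j), numeric(1))
    inc <- vapply(usable, function(j) f(a[j] + 1, j) - f(a[j], j), numeric(1))
    jf <- from[which.min(dec)]
    jt <- usable[which.min(inc)]
    if (jf != jt && min(dec) + min(inc) < -1e-12) {
      a[jf] <- a[jf] - 1; a[jt] <- a[jt] + 1
      improved <- TRUE
    }
    if (!improved) break
  }
  a
}

#' Closeness centrality of plants
#'
#' How near a plant sits to the core of the interactions, based on geodesic
#' path lengths: `CC(v) = (R - 1) / sum_{i != v} d(v, i)`. By default
#' distances are measured on the plant-mode projection (plants adjacent iff
#' they share at least one bumblebee); `mode = "bipartite"` uses the full
#' two-mode graph instead. On disconnected graphs the Wasserman-Faust
#' correction is applied: the index is computed within the reachable set and
#' scaled by `(reachable - 1)/(R - 1)`; isolated plants get 0.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param plant optional plant name/index; default all plants.
#' @param mode `"projection"` (default) or `"bipartite"`.
#' @return named numeric vector of closeness values in `[0, 1]`.
#' @export
closeness_plants <- function(net, plant = NULL, mode = c("projection", "bipartite")) {
  mode <- match.arg(mode)
  B <- binarize(net)
  R <- ncol(B)
  if (R < 2) stop("closeness_plants: need >= 2 plants")
  if (mode == "projection") {
    A <- (crossprod(B) > 0) * 1 # plants sharing >= 1 bee
    diag(A) <- 0
    dimnames(A) <- NULL
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    D <- igraph::distances(g)
  } else {
    n <- nrow(B)
    A <- rbind(cbind(matrix(0, n, n), unname(B)),
               cbind(t(unname(B)), matrix(0, R, R)))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    D <- igraph::distances(g)[n + seq_len(R), n + seq_len(R), drop = FALSE]
  }
  cc <- vapply(seq_len(R), function(v) {
    d <- D[v, -v]
    reach <- sum(is.finite(d))
    if (reach == 0) return(0)
    ((reach / sum(d[is.finite(d)])) * reach) / (R - 1)
  }, numeric(1))
  names(cc) <- colnames(B)
  if (!is.null(plant)) cc[plant] else cc
}

#' All node-level indices of a network
#'
#' Long-format table of degree, resource range, proportional generality,
#' PDI and d' for every bumblebee, plus closeness centrality for every
#' plant.
#'
#' @param net an [interaction_matrix()].
#' @param R available-resource count for RR and PDI (default: plants present
#'   in the network; pass the checklist size for the checklist convention).
#' @param closeness_mode passed to [closeness_plants()].
#' @return data.frame `network`, `index`, `scope`, `node`, `value`.
#' @export
node_indices <- function(net, R = ncol(as_weight_matrix(net)),
                         closeness_mode = "projection") {
  W <- as_weight_matrix(net)
  id <- if (inherits(net, "interaction_matrix")) network_id(net) else "network"
  bees <- rownames(W)
  bee_tab <- do.call(rbind, lapply(bees, function(b) {
    data.frame(network = id,
               index = c("degree", "RR", "PG", "PDI", "d_prime"),
               scope = "bumblebee", node = b,
               value = c(node_degree(W, b),
                         resource_range(W, b, R),
                         proportional_generality(W, b),
                         pdi(W, b, R),
                         d_prime(W, b)),
               stringsAsFactors = FALSE)
  }))
  cc <- closeness_plants(W, mode = closeness_mode)
  plant_tab <- data.frame(network = id, index = "closeness", scope = "plant",
                          node = names(cc), value = unname(cc),
                          stringsAsFactors = FALSE)
  rbind(bee_tab, plant_tab)
}
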