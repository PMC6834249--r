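#' Connectance
#'
#' Proportion of realized links in the binarized network: `C = L / (I * J)`.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @return numeric in `(0, 1]` for non-empty networks.
#' @export
connectance <- function(net) {
  B <- binarize(net)
  sum(B) / (nrow(B) * ncol(B))
}

# marginal-weighted effective partner numbers; entropies in base 2 by the
# quantitative link-density convention
effective_partners <- function(W, margin) {
  tot <- sum(W)
  if (tot <= 0) stop("effective partners: empty matrix")
  H <- apply(W, margin, shannon, base = 2)
  b <- if (margin == 1) rowSums(W) else colSums(W)
  sum((b / tot) * 2^H)
}

#' Generality and vulnerability
#'
#' Mean effective numbers of partners weighted by the marginal totals:
#' generality `G` is the effective number of plants per bumblebee, and
#' vulnerability `V` the effective number of bumblebees per plant. Effective
#' numbers are `2^H` with `H` the base-2 Shannon entropy of the node's
#' partner shares.
#'
#' @param net an [interaction_matrix()] or matrix (bees in rows).
#' @return list with `G` and `V`, both >= 1 for non-empty networks.
#' @export
generality_vulnerability <- function(net) {
  W <- as_weight_matrix(net)
  list(G = effective_partners(W, 1), V = effective_partners(W, 2))
}

#' Quantitative link density
#'
#' Bersier's weighted link density, the marginal-weighted mean of the
#' effective partner numbers of the two modes:
#' `LD = (G + V) / 2` with `G`/`V` as in [generality_vulnerability()].
#'
#' @param net an [interaction_matrix()] or matrix.
#' @return positive numeric.
#' @export
link_density <- function(net) {
  gv <- generality_vulnerability(net)
  (gv$G + gv$V) / 2
}

#' Nestedness based on Overlap and Decreasing Fill (NODF / WNODF)
#'
#' For every ordered pair of rows (and of columns) whose marginal fill
#' decreases strictly, the paired overlap percentage is accumulated and the
#' sum is scaled by the number of pairs, giving a 0-100 score (100 = fully
#' nested). Binary NODF uses presence fills and shared presences; the
#' weighted variant uses the same strict decreasing-fill condition and counts
#' cells of the lower-fill row/column that are positive yet strictly smaller
#' than the matching cell of the higher-fill one. Ties in the fill condition
#' contribute zero.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param weighted compute WNODF instead of binary NODF.
#' @return numeric in `[0, 100]`.
#' @export
nodf <- function(net, weighted = FALSE) {
  W <- as_weight_matrix(net)
  if (nrow(W) < 2 || ncol(W) < 2) stop("nodf: need >= 2 rows and >= 2 columns")
  total_pairs <- nrow(W) * (nrow(W) - 1) / 2 + ncol(W) * (ncol(W) - 1) / 2
  as.numeric(nodf_margin(W, weighted) + nodf_margin(t(W), weighted)) / total_pairs
}

# sum of paired-overlap percentages over row pairs of M; the decreasing-fill
# condition is on binary fill (strict; ties contribute 0) for both variants,
# matching the reference NODF/WNODF implementations
nodf_margin <- function(M, weighted) {
  B <- (M > 0) * 1
  fill <- rowSums(B)
  n <- nrow(M)
  acc <- 0
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (fill[u] == fill[v] || fill[u] == 0 || fill[v] == 0) next
      up <- if (fill[u] > fill[v]) u else v
      down <- u + v - up
      k <- if (weighted) sum(M[down, ] > 0 & M[down, ] < M[up, ])
           else sum(B[down, ] == 1 & B[up, ] == 1)
      acc <- acc + 100 * k / fill[down]
    }
  }
  acc
}

#' Barber bipartite modularity of a given partition
#'
#' Evaluates `Q = (1/m) * sum_ij (A_ij - k_i d_j / m) * delta(g_i, h_j)`
#' where `m` is the total link weight, `k`/`d` the row/column strengths and
#' `delta` is 1 when row `i` and column `j` carry the same module label.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param labels_row,labels_col module labels per row / column node.
#' @param weighted use cell weights (default) or the binarized matrix.
#' @return numeric modularity `Q`.
#' @export
barber_modularity <- function(net, labels_row, labels_col, weighted = TRUE) {
  W <- if (weighted) as_weight_matrix(net) else binarize(net)
  m <- sum(W)
  if (m <= 0) stop("barber_modularity: empty matrix")
  k <- rowSums(W); d <- colSums(W)
  Bmod <- W - outer(k, d) / m
  same <- outer(as.character(labels_row), as.character(labels_col), "==")
  sum(Bmod[same]) / m
}

#' Maximise Barber modularity by label propagation (DIRTLPAwb+-style)
#'
#' Seed-deterministic reimplementation of the two-stage label-propagation
#' scheme: every node starts in its own module, nodes repeatedly adopt the
#' neighbouring module label that maximises the modularity gain (traversal
#' order shuffled by the seeded generator, ties broken toward the lowest
#' label), and an agglomerative stage merges whole modules while the gain is
#' positive. The best partition over `restarts` seeded runs is returned.
#' Only the `Q` evaluator is contract-exact; the optimizer is a stochastic
#' search.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @param weighted optimise the weighted (default) or binary modularity.
#' @param restarts number of independent seeded runs (>= 1).
#' @param seed integer seed.
#' @return list with `Q`, `labels_row`, `labels_col`, and `meta` (per-restart
#'   best-of record and the seed).
#' @export
modularity_lpa <- function(net, weighted = TRUE, restarts = 20L, seed = 1L) {
  if (restarts < 1) stop("modularity_lpa: restarts must be >= 1")
  W <- if (weighted) as_weight_matrix(net) else binarize(net)
  m <- sum(W)
  if (m <= 0) stop("modularity_lpa: empty matrix")
  r <- nrow(W); c <- ncol(W)
  k <- rowSums(W); d <- colSums(W)
  Bmod <- W - outer(k, d) / m # modularity matrix (rows x cols)

  run_once <- function() {
    lr <- seq_len(r)
    lc <- rep(NA_integer_, c)
    # initial column labels: best row label by modularity gain
    for (j in seq_len(c)) {
      sc <- vapply(seq_len(r), function(L) sum(Bmod[lr == L, j]), numeric(1))
      lc[j] <- if (max(sc) > 0) which.max(sc) else r + j
    }
    next_label <- r + c + 1L
    repeat {
      changed <- FALSE
      for (i in sample.int(r)) {
        labs <- sort(unique(lc[W[i, ] > 0]))
        if (!length(labs)) next
        sc <- vapply(labs, function(L) sum(Bmod[i, lc == L]), numeric(1))
        best <- labs[which.max(sc)] # ties: lowest label (labs sorted)
        if (max(sc) <= 0) { # prefers a singleton module
          if (sum(lr == lr[i]) > 1 || any(lc == lr[i])) {
            lr[i] <- next_label; next_label <- next_label + 1L; changed <- TRUE
          }
        } else if (best != lr[i]) {
          lr[i] <- best; changed <- TRUE
        }
      }
      for (j in sample.int(c)) {
        labs <- sort(unique(lr[W[, j] > 0]))
        if (!length(labs)) next
        sc <- vapply(labs, function(L) sum(Bmod[lr == L, j]), numeric(1))
        best <- labs[which.max(sc)]
        if (max(sc) <= 0) {
          if (sum(lc == lc[j]) > 1 || any(lr == lc[j])) {
            lc[j] <- next_label; next_label <- next_label + 1L; changed <- TRUE
          }
        } else if (best != lc[j]) {
          lc[j] <- best; changed <- TRUE
        }
      }
      if (!changed) break
    }
    # agglomerative stage: merge module pairs while Q increases
    repeat {
      labs <- sort(unique(c(lr, lc)))
      nl <- length(labs)
      if (nl < 2) break
      S <- matrix(0, nl, nl) # S[a, b] = sum Bmod over rows in a x cols in b
      for (a in seq_len(nl)) {
        ra <- lr == labs[a]
        if (any(ra)) for (b in seq_len(nl)) {
          cb <- lc == labs[b]
          if (any(cb)) S[a, b] <- sum(Bmod[ra, cb, drop = FALSE])
        }
      }
      gain <- -Inf; pick <- NULL
      for (a in seq_len(nl - 1)) for (b in (a + 1):nl) {
        g <- S[a, b] + S[b, a]
        if (g > gain + 1e-15) { gain <- g; pick <- c(a, b) }
      }
      if (is.null(pick) || gain <= 1e-15) break
      keep <- labs[pick[1]]; drop <- labs[pick[2]]
      lr[lr == drop] <- keep
      lc[lc == drop] <- keep
    }
    list(Q = barber_modularity(W, lr, lc, weighted = TRUE), lr = lr, lc = lc)
  }

  set.seed(seed)
  best <- NULL
  record <- numeric(restarts)
  for (t in seq_len(restarts)) {
    res <- run_once()
    record[t] <- res$Q
    if (is.null(best) || res$Q > best$Q + 1e-15) best <- res
  }
  relab <- function(x) as.integer(factor(x, levels = unique(c(best$lr, best$lc))))
  nm <- dimnames(W)
  list(Q = best$Q,
       labels_row = stats::setNames(relab(best$lr)[seq_len(r)], nm[[1]]),
       labels_col = stats::setNames(relab(c(best$lr, best$lc))[r + seq_len(c)], nm[[2]]),
       meta = list(restarts = restarts, seed = seed, record = record))
}

#' Raw two-dimensional interaction diversity
#'
#' `H2 = -sum_ij (b_ij / b..) * ln(b_ij / b..)` over nonzero cells.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @return non-negative numeric.
#' @export
h2_diversity <- function(net) {
  W <- as_weight_matrix(net)
  if (sum(W) <= 0) stop("h2_diversity: empty matrix")
  shannon(as.vector(W))
}

#' Network-level complementary specialization H2'
#'
#' Standardises the two-dimensional Shannon diversity of the interaction
#' matrix by its achievable extremes given the marginal totals:
#' `H2' = (H2max - H2) / (H2max - H2min)`, so 1 is perfect specialisation
#' and 0 a marginal-proportional (maximally overlapping) matrix. `H2min`
#' comes from greedy largest-row-by-largest-column packing at the matrix's
#' own integer resolution; `H2max` is the entropy of the marginal-
#' proportional fill (`H` of the row shares plus `H` of the column shares),
#' the exact continuous maximum. Because the minimum is a heuristic bound,
#' the index is clamped to `[0, 1]`.
#'
#' @param net an [interaction_matrix()] or matrix.
#' @return numeric in `[0, 1]`.
#' @export
h2prime <- function(net) {
  W <- as_weight_matrix(net)
  tot <- sum(W)
  if (tot <= 0) stop("h2prime: empty matrix")
  V <- resolution_units(W) # extremes at the matrix's own integer resolution
  H2 <- h2_diversity(V)
  ex <- h2_extremes(rowSums(V), colSums(V))
  if (ex$max - ex$min < 1e-12) return(0)
  min(1, max(0, (ex$max - H2) / (ex$max - ex$min)))
}

# express a weight matrix in units of its smallest positive cell, so that
# discretized extremes are invariant to rescaling the whole matrix
resolution_units <- function(W) {
  s <- min(W[W > 0])
  V <- W / s
  if (all(abs(V - round(V)) < 1e-9)) round(V) else V
}

# heuristic extremes of H2 for fixed marginal totals
h2_extremes <- function(rt, ct) {
  tot <- sum(rt)
  # H2min: greedy packing, largest remaining row total x largest column total
  r <- rt; c <- ct
  vals <- numeric(0)
  while (sum(r) > 1e-9) {
    i <- which.max(r); j <- which.max(c)
    a <- min(r[i], c[j])
    vals <- c(vals, a)
    r[i] <- r[i] - a; c[j] <- c[j] - a
  }
  h2min <- shannon(vals)
  # H2max: entropy of the marginal-proportional fill, H(row shares) +
  # H(col shares); this upper-bounds the H2 of every matrix with these
  # marginals (subadditivity), so the normalized index can never go negative
  h2max <- shannon(rt) + shannon(ct)
  list(min = h2min, max = max(h2max, h2min))
}

#' All network-level indices
#'
#' Computes the nine-index suite on one network: quantitative link density
#' (LD), connectance (C), binary and weighted nestedness (NODF, WNODF),
#' binary and weighted Barber modularity (Q, Qw), complementary
#' specialization (H2'), generality (G) and vulnerability (V).
#'
#' @param net an [interaction_matrix()].
#' @param restarts,seed passed to [modularity_lpa()].
#' @return data.frame `network`, `index`, `scope`, `node`, `value`, with the
#'   modularity partitions attached as attribute `"partitions"`.
#' @export
network_indices <- function(net, restarts = 20L, seed = 1L) {
  W <- as_weight_matrix(net)
  id <- if (inherits(net, "interaction_matrix")) network_id(net) else "network"
  gv <- generality_vulnerability(W)
  qb <- modularity_lpa(W, weighted = FALSE, restarts = restarts, seed = seed)
  qw <- modularity_lpa(W, weighted = TRUE, restarts = restarts, seed = seed)
  vals <- c(LD = link_density(W),
            C = connectance(W),
            NODF = nodf(W, weighted = FALSE),
            WNODF = nodf(W, weighted = TRUE),
            Q = qb$Q, Qw = qw$Q,
            H2prime = h2prime(W),
            G = gv$G, V = gv$V)
  out <- data.frame(network = id, index = names(vals), scope = "network",
                    node = NA_character_, value = unname(vals),
                    stringsAsFactors = FALSE)
  attr(out, "partitions") <- list(binary = qb, weighted = qw)
  out
}
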