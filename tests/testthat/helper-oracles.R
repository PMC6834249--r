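# Naive, definition-level oracle implementations, kept deliberately
# independent of the package code paths they check.

oracle_connectance <- function(W) {
  links <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (W[i, j] > 0) links <- links + 1
  links / (nrow(W) * ncol(W))
}

oracle_entropy2 <- function(w) { # base-2 Shannon entropy by the definition
  if (sum(w) == 0) return(0) # zero-margin nodes carry zero weight anyway
  p <- w / sum(w)
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log2(x)
  h
}

oracle_gv <- function(W) {
  tot <- sum(W)
  G <- 0
  for (i in seq_len(nrow(W)))
    G <- G + (sum(W[i, ]) / tot) * 2^oracle_entropy2(W[i, ])
  V <- 0
  for (j in seq_len(ncol(W)))
    V <- V + (sum(W[, j]) / tot) * 2^oracle_entropy2(W[, j])
  c(G = G, V = V)
}

oracle_ld <- function(W) {
  gv <- oracle_gv(W)
  (gv["G"] + gv["V"]) / 2
}

oracle_h2 <- function(W) {
  tot <- sum(W)
  h <- 0
  for (x in as.vector(W)) if (x > 0) h <- h - (x / tot) * log(x / tot)
  h
}

# binary/weighted NODF by the double loop over all ordered pairs
oracle_nodf <- function(W, weighted = FALSE) {
  pair_sum <- function(M) {
    B <- (M > 0) * 1
    acc <- 0
    n <- nrow(M)
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (u == v) next
      if (weighted) {
        if (!(sum(B[u, ]) > sum(B[v, ]))) next # strictly decreasing fill
        fv <- sum(B[v, ])
        if (fv == 0) next
        k <- sum(M[v, ] > 0 & M[v, ] < M[u, ])
        acc <- acc + 100 * k / fv
      } else {
        if (!(sum(B[u, ]) > sum(B[v, ]))) next
        fv <- sum(B[v, ])
        if (fv == 0) next
        acc <- acc + 100 * sum(B[u, ] * B[v, ]) / fv
      }
    }
    acc
  }
  np <- nrow(W) * (nrow(W) - 1) / 2 + ncol(W) * (ncol(W) - 1) / 2
  (pair_sum(W) + pair_sum(t(W))) / np
}

# Barber bipartite modularity of a given partition, cell by cell
oracle_barber_q <- function(W, lr, lc) {
  m <- sum(W)
  k <- rowSums(W); d <- colSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (lr[i] == lc[j]) q <- q + W[i, j] - k[i] * d[j] / m
  as.numeric(q / m)
}

# all set partitions of n elements via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) { out[[length(out) + 1]] <<- rgs; return(invisible()) }
    for (lab in seq_len(mx + 1)) rec(c(rgs, lab), max(mx, lab))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive-search optimum of Barber modularity over joint row+col partitions
oracle_best_q <- function(W) {
  n <- nrow(W) + ncol(W)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- oracle_barber_q(W, p[seq_len(nrow(W))], p[nrow(W) + seq_len(ncol(W))])
    if (q > best) best <- q
  }
  best
}

# brute-force KL extremes over all integer allocations of t units on J plants
oracle_kl_extremes <- function(t, q) {
  best_min <- Inf; best_max <- -Inf
  rec <- function(left, j, alloc) {
    if (j == length(q)) {
      a <- c(alloc, left)
      p <- a / t
      i <- p > 0
      if (any(i & q == 0)) return(invisible())
      d <- sum(p[i] * log(p[i] / q[i]))
      best_min <<- min(best_min, d); best_max <<- max(best_max, d)
      return(invisible())
    }
    for (a in 0:left) rec(left - a, j + 1, c(alloc, a))
  }
  rec(t, 1, integer(0))
  c(min = best_min, max = best_max)
}

# all compositions of `total` into `parts` non-negative integers
compositions <- function(total, parts) {
  if (parts == 1) return(matrix(total, 1, 1))
  out <- NULL
  for (a in 0:total) out <- rbind(out, cbind(a, compositions(total - a, parts - 1)))
  unname(out)
}

# exhaustive H2 extremes over all non-negative integer matrices with the
# given marginal totals (tiny cases only)
oracle_h2_extremes <- function(rt, ct) {
  rows <- lapply(rt, compositions, parts = length(ct))
  best_min <- Inf; best_max <- -Inf
  rec <- function(i, acc) {
    if (i > length(rt)) {
      W <- do.call(rbind, acc)
      if (all(colSums(W) == ct)) {
        h <- oracle_h2(W)
        best_min <<- min(best_min, h); best_max <<- max(best_max, h)
      }
      return(invisible())
    }
    for (r in seq_len(nrow(rows[[i]]))) rec(i + 1, c(acc, list(rows[[i]][r, ])))
  }
  rec(1, list())
  c(min = best_min, max = best_max)
}

random_weighted_matrix <- function(nr, nc, max_count = 50) {
  repeat {
    W <- matrix(rpois(nr * nc, 2) * rbinom(nr * nc, 1, 0.6), nr, nc)
    W <- W * sample(seq_len(max_count %/% 2), nr * nc, replace = TRUE)
    if (all(rowSums(W) > 0) && all(colSums(W) > 0)) return(W)
  }
}
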