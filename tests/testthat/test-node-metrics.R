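toy_net <- function() {
  W <- rbind(BB1 = c(3, 0, 7, 0),
             BB2 = c(0, 5, 0, 0),
             BB3 = c(2, 2, 2, 2))
  colnames(W) <- paste0("p", 1:4)
  interaction_matrix(W, nest_id = 1, phase = "before", treatment = "treated")
}

test_that("degree counts the plant taxa in a pellet", {
  net <- toy_net()
  expect_equal(node_degree(net, "BB1"), 2)
  expect_equal(node_degree(net, "BB2"), 1) # monofloral pellet
  expect_equal(node_degree(net, "BB3"), 4) # all plants
  expect_error(node_degree(net, "BB9"), "unknown bumblebee")
})

test_that("resource range is the used fraction of available plants", {
  net <- toy_net()
  expect_equal(resource_range(net, "BB2", R = 4), 0) # extreme specialist
  expect_equal(resource_range(net, "BB3", R = 4), 1) # uses everything
  expect_equal(resource_range(net, "BB1", R = 4), 1 / 3)
  expect_error(resource_range(net, "BB1", R = 1), "R >= 2")
})

test_that("proportional generality is the ratio of effective diversities", {
  # bee uses 2 plants equally; plant marginals equal over 4 plants -> 1/2
  W <- rbind(BB1 = c(10, 10, 0, 0), BB2 = c(0, 0, 10, 10))
  colnames(W) <- paste0("p", 1:4)
  expect_equal(proportional_generality(W, "BB1"), 2 / 4)
  # a bee whose shares equal the marginal shares scores 1
  W2 <- rbind(BB1 = c(8, 4, 2), BB2 = c(8, 4, 2))
  colnames(W2) <- paste0("p", 1:3)
  expect_equal(proportional_generality(W2, "BB1"), 1)
  # single-plant bee against k > 1 effective plants: 1/k, directly from entropies
  W3 <- rbind(BB1 = c(12, 0, 0), BB2 = c(0, 9, 3))
  colnames(W3) <- paste0("p", 1:3)
  k_eff <- exp(-sum(c(12, 9, 3) / 24 * log(c(12, 9, 3) / 24)))
  expect_equal(proportional_generality(W3, "BB1"), 1 / k_eff)
  expect_lt(proportional_generality(W3, "BB1"), 1)
})

test_that("PDI follows the max-scaled paired-difference formula", {
  W <- rbind(BB1 = c(4, 4, 4), BB2 = c(9, 0, 0), BB3 = c(10, 5, 0))
  colnames(W) <- paste0("p", 1:3)
  expect_equal(pdi(W, "BB1", R = 3), 1) # uniform use
  expect_equal(pdi(W, "BB2", R = 3), 0) # single resource
  expect_equal(pdi(W, "BB3", R = 3), 0.25) # scaled P = (1, 0.5, 0)
  expect_error(pdi(W, "BB1", R = 1), "R >= 2")
})

test_that("d' matches the KL definition and its brute-force extremes", {
  # bee with shares equal to availability: raw d = 0, normalized 0
  W <- rbind(BB1 = c(6, 3), BB2 = c(6, 3))
  colnames(W) <- c("p1", "p2")
  expect_equal(d_prime(W, "BB1", raw = TRUE), 0)
  expect_equal(d_prime(W, "BB1"), 0)

  # 3-plant toy network: extremes against exhaustive allocation search
  W2 <- rbind(BB1 = c(2, 3, 1), BB2 = c(8, 1, 0), BB3 = c(5, 0, 1))
  colnames(W2) <- paste0("p", 1:3)
  q <- colSums(W2) / sum(W2)
  for (b in rownames(W2)) {
    t <- sum(W2[b, ])
    ex <- oracle_kl_extremes(t, q)
    d_raw <- d_prime(W2, b, raw = TRUE)
    expect_gte(d_raw, ex["min"] - 1e-12)
    expect_lte(d_raw, ex["max"] + 1e-12)
    # the normalisation uses exactly those extremes
    expect_equal(d_prime(W2, b), (d_raw - ex["min"]) / (ex["max"] - ex["min"]),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }

  # concentrating everything on the rarest plant maxes out the index
  W3 <- rbind(BB1 = c(0, 0, 9), BB2 = c(50, 30, 1))
  colnames(W3) <- paste0("p", 1:3)
  expect_gt(d_prime(W3, "BB1"), 0.95)
})

test_that("d' stays within [0, 1] over many random networks", {
  set.seed(99)
  for (r in 1:1000) {
    W <- random_weighted_matrix(sample(2:5, 1), sample(2:5, 1), max_count = 30)
    rownames(W) <- paste0("BB", seq_len(nrow(W)))
    b <- sample(rownames(W), 1)
    d <- d_prime(W, b)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("plant closeness follows geodesics on the plant projection", {
  # 3 plants all sharing one bee: complete projection, CC = 1 each
  W <- rbind(BB1 = c(1, 1, 1))
  colnames(W) <- paste0("p", 1:3)
  expect_equal(unname(closeness_plants(W)), rep(1, 3))

  # path graph p1 - p2 - p3: middle 1, ends 2/3
  W2 <- rbind(BB1 = c(1, 1, 0), BB2 = c(0, 1, 1))
  colnames(W2) <- paste0("p", 1:3)
  expect_equal(unname(closeness_plants(W2)), c(2 / 3, 1, 2 / 3))

  # plant in a separate component gets Wasserman-Faust-scaled closeness
  W3 <- rbind(BB1 = c(1, 1, 0, 0), BB2 = c(0, 0, 1, 0), BB3 = c(0, 0, 0, 1))
  colnames(W3) <- paste0("p", 1:4)
  cc <- closeness_plants(W3)
  expect_equal(unname(cc[3:4]), c(0, 0)) # isolated plants
  expect_equal(unname(cc[1]), (1 / 1) * 1 / 3) # reaches 1 of 3 others at distance 1
  expect_error(closeness_plants(W3[, 1, drop = FALSE]), ">= 2 plants")

  # bipartite-mode distances are twice the projection distances here
  cc_bip <- closeness_plants(W2, mode = "bipartite")
  expect_equal(which.max(cc_bip), c(p2 = 2))
})

test_that("binary indices ignore weights; quantitative indices ignore scale", {
  set.seed(7)
  W <- random_weighted_matrix(4, 5)
  rownames(W) <- paste0("BB", 1:4); colnames(W) <- paste0("p", 1:5)
  for (b in rownames(W)) {
    expect_equal(node_degree(W * 3.7, b), node_degree(W > 0, b))
    expect_equal(resource_range(W * 3.7, b), resource_range(W, b))
    expect_equal(proportional_generality(W * 3.7, b), proportional_generality(W, b))
    expect_equal(pdi(W * 3.7, b), pdi(W, b))
    expect_equal(d_prime(W * 3.7, b), d_prime(W, b))
  }
  # degree = 1 <=> RR = 0 <=> PDI = 0
  for (b in rownames(W)) {
    deg1 <- node_degree(W, b) == 1
    expect_equal(resource_range(W, b) == 0, deg1)
    expect_equal(pdi(W, b) == 0, deg1)
  }
})

test_that("node_indices assembles the long-format per-node table", {
  net <- toy_net()
  tab <- node_indices(net)
  expect_equal(sum(tab$scope == "bumblebee"), 3 * 5)
  expect_equal(sum(tab$scope == "plant"), 4)
  expect_true(all(tab$value[tab$index == "RR"] >= 0 &
                  tab$value[tab$index == "RR"] <= 1))
})
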