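test_that("OTUs are labelled positive iff they received reads", {
  reads <- c(A = 1000, B = 3, C = 0)
  expect_equal(label_otus(reads),
               c(A = "positive", B = "positive", C = "negative"))
  expect_true(all(label_otus(c(a = 0, b = 0)) == "negative"))
  expect_true(all(label_otus(c(a = 2, b = 9)) == "positive"))
  expect_error(label_otus(numeric(0)), "no OTU")
})

test_that("two-group quasipoisson fit returns the closed-form group means", {
  reads <- c(a = 1000, b = 800, c = 3, d = 0, e = 0)
  fit <- fit_group_means(reads)
  expect_equal(fit$mu_pos, 601)
  expect_equal(fit$mu_neg, 0)
  expect_true(fit$filterable)
  expect_gt(fit$dispersion, 1) # heavily overdispersed counts

  # all positives equal c: mu_pos = c
  expect_equal(fit_group_means(c(x = 7, y = 7, z = 0))$mu_pos, 7)

  # single-group samples are unfilterable
  expect_false(fit_group_means(c(a = 10, b = 5))$filterable)
  expect_false(fit_group_means(c(a = 0, b = 0))$filterable)
})

test_that("Youden threshold is the midpoint between the fitted group means", {
  labels <- c("positive", "positive", "positive", "negative", "negative")
  scores <- c(601, 601, 601, 0, 0)
  roc <- roc_threshold(scores, labels)
  expect_equal(roc$cut, 300.5)
  expect_equal(roc$J, 1)
  # no separation: cut = the common score, J = 0, warn
  expect_warning(flat <- roc_threshold(rep(5, 4),
                                       c("positive", "positive", "negative", "negative")),
                 "no separation")
  expect_equal(flat$cut, 5)
  expect_equal(flat$J, 0)
  # degenerate one-class ROC
  expect_true(is.na(roc_threshold(1:3, rep("positive", 3))$cut))
})

test_that("the returned cut maximises sensitivity + specificity over candidates", {
  set.seed(8)
  for (r in 1:20) {
    scores <- c(rpois(6, 40), rpois(6, 5))
    labels <- rep(c("positive", "negative"), each = 6)
    roc <- roc_threshold(scores, labels)
    u <- sort(unique(scores))
    cands <- c(u - 0.5, u + 0.5)
    J <- function(cut) mean(scores[labels == "positive"] >= cut) +
      mean(scores[labels == "negative"] < cut) - 1
    expect_gte(roc$J + 1e-12, max(vapply(cands, J, numeric(1))))
  }
})

test_that("Youden midpoint agrees with the pROC reference on two-level scores", {
  skip_if_not_installed("pROC")
  labels <- c(rep("positive", 4), rep("negative", 7))
  scores <- c(rep(520, 4), rep(0, 7))
  ours <- roc_threshold(scores, labels)
  ref <- pROC::coords(pROC::roc(response = labels, predictor = scores,
                                levels = c("negative", "positive"), quiet = TRUE),
                      "best", best.method = "youden")
  expect_equal(ours$cut, ref$threshold)
})

test_that("filtering a sample removes reads strictly below the cut", {
  reads <- c(a = 1000, b = 800, c = 3)
  res <- filter_sample(reads, 300.5)
  expect_equal(unname(res$reads), c(1000, 800, 0))
  expect_equal(res$removed_otus, "c")
  expect_equal(res$removed_reads, 3)
  # cut = 0 removes nothing
  expect_equal(filter_sample(reads, 0)$removed_reads, 0)
  # a sample losing everything is emitted empty with a warning
  expect_warning(res2 <- filter_sample(c(a = 2, b = 1), 10), "lost all OTUs")
  expect_true(all(res2$reads == 0))
  expect_error(filter_sample(reads, -1), "non-negative")
})

test_that("dataset filtering is per-sample, order-invariant, and summarised", {
  rct <- toy_read_counts()
  fd <- filter_dataset(rct)
  # sample s1: mu_pos = 601, cut 300.5 -> otu3 (3 reads) removed
  expect_equal(fd$thresholds$cut[1], 300.5)
  expect_equal(fd$filtered$counts["s1", "otu3"], 0)
  expect_equal(fd$thresholds$removed_reads[1], 3)
  expect_equal(fd$thresholds$cut_fraction[1], 300.5 / 1803)
  # sample s4 has a single positive OTU and no other information is lost
  expect_equal(fd$filtered$counts["s4", "otu1"], 700)
  # summary aggregates
  expect_equal(fd$summary$total_removed_reads, sum(fd$thresholds$removed_reads))

  # order invariance: permuting samples permutes the per-sample results
  perm <- c(3, 1, 4, 2)
  rct2 <- read_count_table(rct$counts[perm, ], rct$meta[perm, ])
  fd2 <- filter_dataset(rct2)
  expect_equal(fd2$thresholds[match(fd$thresholds$sample_id,
                                    fd2$thresholds$sample_id), -1],
               fd$thresholds[, -1], ignore_attr = TRUE)
  expect_error(filter_dataset(read_count_table(
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b"))),
    data.frame(sample_id = character(0), nest_id = integer(0),
               treatment = character(0), phase = character(0)))),
    "empty")
})

test_that("unfilterable samples pass through untouched", {
  counts <- rbind(c(10, 20, 30)) # no zero group
  colnames(counts) <- paste0("otu", 1:3)
  rct <- read_count_table(counts, data.frame(
    sample_id = "s1", nest_id = 1L, treatment = "treated", phase = "before"))
  fd <- filter_dataset(rct)
  expect_false(fd$thresholds$filterable[1])
  expect_equal(fd$filtered$counts, rct$counts)
  expect_equal(fd$summary$n_unfilterable, 1)
})

test_that("re-applying the recorded threshold is a no-op", {
  sim <- simulate_read_counts(synth_config(seed = 17, n_samples_per_nest_phase = 6))
  fd <- filter_dataset(sim$table)
  for (s in seq_len(nrow(fd$filtered$counts))) {
    cut <- fd$thresholds$cut[s]
    if (is.na(cut)) next
    row <- fd$filtered$counts[s, ]
    expect_true(all(row[row > 0] >= cut))
    again <- filter_sample(row, cut)
    expect_equal(again$reads, row)
    expect_equal(again$removed_reads, 0)
  }
})

test_that("an OTU drop-list removes columns before filtering", {
  rct <- toy_read_counts()
  fd <- filter_dataset(rct, drop_otus = "otu5")
  expect_false("otu5" %in% colnames(fd$filtered$counts))
})
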