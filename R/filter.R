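#' Label the OTUs of one sample as positive or negative
#'
#' The per-sample classification underlying the ROC threshold: an OTU is
#' `"positive"` if it received any reads in the sample and `"negative"` if it
#' received zero.
#'
#' @param reads named non-negative integer vector (one sample's row).
#' @return character vector of `"positive"`/`"negative"` labels.
#' @export
label_otus <- function(reads) {
  if (!length(reads)) stop("label_otus: sample has no OTU columns")
  ifelse(reads > 0, "positive", "negative")
}

#' Fit the two-group overdispersed-Poisson means of a sample
#'
#' Models read counts on the positive/negative label with a quasipoisson
#' log-link GLM. With a single binary predictor the model is saturated, so
#' the fitted group means are exactly the arithmetic group means (and the
#' negative group, zero reads by definition, has mean 0); they are computed
#' in closed form, with the quasipoisson Pearson chi-squared / df dispersion
#' retained as a diagnostic.
#'
#' @param reads named non-negative integer vector.
#' @param labels labels from [label_otus()]; recomputed if `NULL`.
#' @return list with `mu_pos`, `mu_neg`, `dispersion`, `n_pos`, `n_neg` and
#'   `filterable` (FALSE when one of the groups is empty, in which case the
#'   sample must be passed through untouched).
#' @export
fit_group_means <- function(reads, labels = NULL) {
  if (is.null(labels)) labels <- label_otus(reads)
  pos <- reads[labels == "positive"]
  neg <- reads[labels == "negative"]
  if (!length(pos) || !length(neg)) {
    return(list(mu_pos = if (length(pos)) mean(pos) else NA_real_,
                mu_neg = if (length(neg)) mean(neg) else NA_real_,
                dispersion = NA_real_, n_pos = length(pos), n_neg = length(neg),
                filterable = FALSE))
  }
  mu_pos <- mean(pos)
  mu_neg <- mean(neg) # identically 0 under the labelling rule
  # Pearson dispersion; cells with fitted mean 0 have zero residual
  df <- length(reads) - 2L
  pearson <- sum((pos - mu_pos)^2 / mu_pos)
  list(mu_pos = mu_pos, mu_neg = mu_neg,
       dispersion = if (df > 0) pearson / df else NA_real_,
       n_pos = length(pos), n_neg = length(neg), filterable = TRUE)
}

#' Youden-optimal ROC threshold
#'
#' Builds the ROC of `scores` against `labels` and returns the operating
#' threshold at the Youden optimum (maximising sensitivity + specificity -
#' 1), using the midpoint convention: candidate thresholds are the midpoints
#' between consecutive distinct score values (plus open ends), and ties in J
#' are broken toward the smaller threshold. With the fitted values of
#' [fit_group_means()] as scores this reduces to `(mu_pos + mu_neg) / 2`.
#'
#' @param scores numeric score per OTU (higher = more likely positive).
#' @param labels `"positive"`/`"negative"` per OTU.
#' @return list with `cut`, `J` (Youden index at the cut), `sensitivity`,
#'   `specificity`. If only one class is present, `cut` is `NA` (degenerate
#'   ROC). When the two classes are not separated at all (`J = 0`), a
#'   warning is raised.
#' @export
roc_threshold <- function(scores, labels) {
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) {
    return(list(cut = NA_real_, J = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_))
  }
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
  stats <- vapply(cand, function(cut) {
    sens <- mean(scores[pos] >= cut)
    spec <- mean(scores[!pos] < cut)
    c(sens = sens, spec = spec, J = sens + spec - 1)
  }, numeric(3))
  best <- which(stats["J", ] == max(stats["J", ]))[1] # ties: smaller cut
  out <- list(cut = unname(cand[best]), J = unname(stats["J", best]),
              sensitivity = unname(stats["sens", best]),
              specificity = unname(stats["spec", best]))
  if (out$J <= 0) warning("roc_threshold: no separation between groups (J = 0)")
  out
}

#' Apply a read-count threshold to one sample
#'
#' OTUs whose read count is strictly below `cut` are set to zero and recorded
#' as removed; everything else (including metadata) is untouched. A sample
#' losing all its OTUs is emitted empty with a warning.
#'
#' @param reads named non-negative integer vector.
#' @param cut threshold (reads `< cut` are removed); must be >= 0.
#' @return list with `reads` (filtered vector), `removed_otus` (names),
#'   `removed_reads` (total reads removed).
#' @export
filter_sample <- function(reads, cut) {
  if (is.na(cut) || cut < 0) stop("filter_sample: cut must be a non-negative number")
  drop <- reads > 0 & reads < cut
  out <- reads
  out[drop] <- 0L
  if (all(out == 0) && any(reads > 0))
    warning("filter_sample: sample lost all OTUs at cut = ", cut)
  list(reads = out, removed_otus = names(reads)[drop],
       removed_reads = sum(reads[drop]))
}

#' ROC/Youden false-positive filtering of a read-count dataset
#'
#' Applies the per-sample pipeline independently to every sample: label OTUs
#' positive/negative by presence, fit the two-group quasipoisson means, take
#' the Youden-optimal midpoint threshold on the fitted values, and zero out
#' OTUs below it. Samples where one label group is empty (no zeros, or no
#' reads at all) are unfilterable and passed through untouched.
#'
#' @param x a [read_count_table()].
#' @param drop_otus optional character vector of OTU columns to drop before
#'   filtering (e.g. OTUs annotated as non-plant upstream).
#' @return list with:
#'   * `filtered`: the filtered [read_count_table()];
#'   * `thresholds`: data.frame per sample (`sample_id`, `mu_pos`, `mu_neg`,
#'     `dispersion`, `cut`, `cut_fraction`, `n_removed`, `removed_reads`,
#'     `filterable`);
#'   * `summary`: list (`total_removed_reads`, `mean_removed_per_sample`,
#'     `mean_cut_fraction`, `n_unfilterable`, `surviving_taxa`).
#' @export
filter_dataset <- function(x, drop_otus = NULL) {
  stopifnot(inherits(x, "read_count_table"))
  if (!nrow(x$counts)) stop("filter_dataset: empty dataset")
  counts <- x$counts
  if (!is.null(drop_otus))
    counts <- counts[, setdiff(colnames(counts), drop_otus), drop = FALSE]
  n <- nrow(counts)
  thr <- data.frame(sample_id = x$meta$sample_id,
                    mu_pos = NA_real_, mu_neg = NA_real_, dispersion = NA_real_,
                    cut = NA_real_, cut_fraction = NA_real_,
                    n_removed = 0L, removed_reads = 0L, filterable = FALSE,
                    stringsAsFactors = FALSE)
  out <- counts
  for (s in seq_len(n)) {
    reads <- counts[s, ]
    labels <- label_otus(reads)
    fit <- fit_group_means(reads, labels)
    thr$mu_pos[s] <- fit$mu_pos; thr$mu_neg[s] <- fit$mu_neg
    thr$dispersion[s] <- fit$dispersion
    thr$filterable[s] <- fit$filterable
    if (!fit$filterable) next
    roc <- roc_threshold(ifelse(labels == "positive", fit$mu_pos, fit$mu_neg),
                         labels)
    res <- filter_sample(reads, roc$cut)
    out[s, ] <- res$reads
    thr$cut[s] <- roc$cut
    thr$cut_fraction[s] <- roc$cut / sum(reads)
    thr$n_removed[s] <- length(res$removed_otus)
    thr$removed_reads[s] <- res$removed_reads
  }
  filtered <- read_count_table(out, x$meta)
  surviving <- colnames(out)[colSums(out) > 0]
  list(filtered = filtered, thresholds = thr,
       summary = list(total_removed_reads = sum(thr$removed_reads),
                      mean_removed_per_sample = mean(thr$removed_reads),
                      mean_cut_fraction = mean(thr$cut_fraction, na.rm = TRUE),
                      n_unfilterable = sum(!thr$filterable),
                      surviving_taxa = surviving))
}
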