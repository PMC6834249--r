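#' Build per-(nest, phase) foraging networks from a read-count table
#'
#' Splits the samples by nest and experimental phase and assembles one
#' individual-by-plant [interaction_matrix()] per combination: one row per
#' sample (pellet), one column per plant taxon with a nonzero total in that
#' nest and phase, weights equal to read counts. All-zero samples (e.g.
#' emptied by filtering) are excluded with a message; a nest-phase with
#' fewer than two usable samples is skipped with a warning.
#'
#' @param x a [read_count_table()] (normally the filtered one).
#' @return named list of [interaction_matrix()] objects (names like
#'   `"NT1_B"`).
#' @export
build_networks <- function(x) {
  stopifnot(inherits(x, "read_count_table"))
  nonzero <- rowSums(x$counts) > 0
  if (any(!nonzero))
    message("build_networks: excluding ", sum(!nonzero), " all-zero sample(s)")
  counts <- x$counts[nonzero, , drop = FALSE]
  meta <- x$meta[nonzero, , drop = FALSE]
  key <- paste0(ifelse(meta$treatment == "treated", "NT", "NC"), meta$nest_id,
                "_", ifelse(meta$phase == "before", "B", "A"))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) < 2) {
      warning("build_networks: ", k, " has < 2 samples; skipped")
      next
    }
    W <- counts[rows, , drop = FALSE]
    rownames(W) <- meta$sample_id[rows]
    W <- W[, colSums(W) > 0, drop = FALSE]
    out[[k]] <- interaction_matrix(W, nest_id = meta$nest_id[rows[1]],
                                   phase = meta$phase[rows[1]],
                                   treatment = meta$treatment[rows[1]])
  }
  out[order(names(out))]
}

#' Descriptive diet summary of a read-count table
#'
#' Deterministic descriptive statistics of the filtered dataset: total
#' number of plant taxa detected, the per-sample taxon-count distribution,
#' and the monofloral/polyfloral split (monofloral = exactly one nonzero
#' taxon; polyfloral split into two-taxon and more-than-two-taxon pellets).
#'
#' @param x a [read_count_table()].
#' @return list with `n_taxa`, `n_samples`, `n_empty`, `taxa_per_sample`
#'   (vector), `mean_taxa`, `sd_taxa`, `min_taxa`, `max_taxa`,
#'   `monofloral`, `polyfloral`, `two_taxa`, `more_than_two`, `total_reads`.
#' @export
summarize_diet <- function(x) {
  stopifnot(inherits(x, "read_count_table"))
  if (!nrow(x$counts)) stop("summarize_diet: empty dataset")
  k <- rowSums(x$counts > 0)
  nz <- k[k > 0]
  list(n_taxa = sum(colSums(x$counts) > 0),
       n_samples = length(nz),
       n_empty = sum(k == 0),
       taxa_per_sample = nz,
       mean_taxa = mean(nz),
       sd_taxa = stats::sd(nz),
       min_taxa = min(nz),
       max_taxa = max(nz),
       monofloral = sum(nz == 1),
       polyfloral = sum(nz > 1),
       two_taxa = sum(nz == 2),
       more_than_two = sum(nz > 2),
       total_reads = sum(x$counts))
}

#' Read a plain-text key = value pipeline configuration
#'
#' @param path text file with one `key = value` per line; `#` comments and
#'   blank lines are ignored. Values are parsed as numbers where possible.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("read_pipeline_config: malformed line(s): ",
                     paste(lines[bad], collapse = "; "))
  out <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, vapply(kv, `[[`, "", 1))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: load (or simulate) read counts,
#' ROC/Youden filtering, diet summary, network construction, node- and
#' network-level indices, before/after permutation swap tests per nest,
#' PERMANOVA on pollen composition, and Chao2 coverage per nest. All outputs
#' are written under `out_dir` together with a JSON run manifest recording
#' the seed and configuration, so a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config named list (or path to a `key = value` file, read with
#'   [read_pipeline_config()]). Recognised entries: `read_counts` (CSV path)
#'   or `interactions` (S1-dialect CSV path; filtering is skipped because
#'   that file is downstream of the filter) — if neither is given, data are
#'   simulated from [synth_config()] defaults; `filtering` (logical, default
#'   TRUE for read counts); `swap_index` (default `"LD"`); `n_swaps`
#'   (default 1000); `n_perm` (default 999); `restarts` (default 10);
#'   `seed` (default 1); `out_dir` (default `tempfile("pollinet_run")`).
#' @return list with `summary`, `thresholds`, `networks`, `node_report`,
#'   `network_report`, `swap_tests`, `permanova`, `coverage`, `manifest`
#'   (invisible file paths inside).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  get <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  seed <- as.integer(get("seed", 1L))
  n_swaps <- as.integer(get("n_swaps", 1000L))
  n_perm <- as.integer(get("n_perm", 999L))
  restarts <- as.integer(get("restarts", 10L))
  swap_index <- as.character(get("swap_index", "LD"))
  out_dir <- get("out_dir", tempfile("pollinet_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  nets <- NULL
  thresholds <- NULL
  rct <- NULL
  if (!is.null(config$interactions)) {
    # already-filtered interaction file: the filter is not re-applied
    nets <- stage("read_interactions", read_interactions(config$interactions))
    filtered <- NULL
  } else {
    rct <- if (!is.null(config$read_counts)) {
      stage("read_read_counts", read_read_counts(config$read_counts))
    } else {
      stage("simulate", simulate_read_counts(synth_config(seed = seed))$table)
    }
    if (isTRUE(as.logical(get("filtering", TRUE)))) {
      fd <- stage("filter", filter_dataset(rct))
      filtered <- fd$filtered
      thresholds <- fd$thresholds
      utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"),
                       row.names = FALSE)
    } else {
      filtered <- rct
    }
    nets <- stage("build_networks", suppressMessages(build_networks(filtered)))
  }
  message(sprintf("[pipeline] networks built: %d", length(nets)))

  node_report <- stage("node_indices",
                       do.call(rbind, lapply(nets, node_indices)))
  network_report <- stage("network_indices",
                          do.call(rbind, lapply(nets, network_indices,
                                                restarts = restarts, seed = seed)))
  write_index_report(rbind(node_report, network_report),
                     file.path(out_dir, "index_report.csv"), overwrite = TRUE)

  # before/after comparison per nest where both phases exist
  swap_tests <- list()
  nest_tags <- unique(sub("_[BA]$", "", names(nets)))
  for (tag in nest_tags) {
    b <- nets[[paste0(tag, "_B")]]; a <- nets[[paste0(tag, "_A")]]
    if (is.null(b) || is.null(a)) next
    swap_tests[[tag]] <- stage(paste0("swap_test:", tag),
                               network_swap_test(b, a, index = swap_index,
                                                 n_swaps = n_swaps, seed = seed))
  }

  perm <- NULL
  summary <- NULL
  coverage <- list()
  if (!is.null(rct)) {
    summary <- stage("summarize_diet", summarize_diet(filtered))
    perm <- stage("permanova",
                  tryCatch(pollen_permanova(filtered, n_perm = n_perm, seed = seed),
                           error = function(e) NULL))
    for (nest in unique(filtered$meta$nest_id)) {
      rows <- filtered$meta$nest_id == nest
      inc <- (filtered$counts[rows, , drop = FALSE] > 0) * 1
      if (sum(inc) > 0 && nrow(inc) >= 2)
        coverage[[as.character(nest)]] <- stage("chao2", chao2_coverage(inc))
    }
  }

  manifest <- list(package_version = as.character(utils::packageVersion("pollinet")),
                   seed = seed, n_swaps = n_swaps, n_perm = n_perm,
                   restarts = restarts, swap_index = swap_index,
                   config = config[setdiff(names(config), "out_dir")],
                   networks = names(nets))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, thresholds = thresholds, networks = nets,
                 node_report = node_report, network_report = network_report,
                 swap_tests = swap_tests, permanova = perm, coverage = coverage,
                 manifest = manifest, out_dir = out_dir))
}
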