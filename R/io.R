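#' Read individual-by-plant interaction matrices (S1-dialect CSV)
#'
#' Parses a CSV in the supplementary-dataset dialect: one row per sampled
#' bumblebee, with a bee-id column (values like `"BB12"`), a nest column
#' (values like `"NT1"`, `"NC3"`: `NT` = treated, `NC` = control, suffix =
#' nest id), a treatment column (`TREATED`/`UNTREATED`), a phase column
#' (`B` = before, `A` = after) and the remaining columns holding numeric
#' interaction weights per plant taxon. One network is returned per
#' (nest, phase) combination; plant columns whose total is zero within a
#' given network are dropped from that network.
#'
#' @param path CSV file path.
#' @param dialect currently only `"s1"`.
#' @return named list of [interaction_matrix()] objects, names like `"NT1_B"`.
#' @export
read_interactions <- function(path, dialect = "s1") {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(raw)) stop("read_interactions: empty file")
  char_like <- function(col) is.character(col) || is.factor(col)
  cols <- names(raw)

  find_col <- function(pred, what) {
    hit <- which(vapply(raw, function(col) char_like(col) && all(pred(as.character(col))), logical(1)))
    if (!length(hit)) stop("read_interactions: cannot locate ", what, " column")
    hit[1]
  }
  bee_col <- find_col(function(v) all(grepl("^BB[0-9]+$", v)), "bumblebee id")
  nest_col <- find_col(function(v) all(grepl("^N[TC][0-9]+$", v)), "nest")
  phase_col <- which(vapply(raw, function(col) {
    char_like(col) && all(nchar(as.character(col)) == 1)
  }, logical(1)))
  if (!length(phase_col)) stop("read_interactions: cannot locate phase column")
  phase_col <- phase_col[1]
  treat_col <- which(vapply(raw, function(col) {
    char_like(col) && all(toupper(as.character(col)) %in% c("TREATED", "UNTREATED"))
  }, logical(1)))
  treat_col <- if (length(treat_col)) treat_col[1] else NA_integer_

  phase_code <- toupper(as.character(raw[[phase_col]]))
  if (!all(phase_code %in% c("B", "A")))
    stop("read_interactions: unknown phase code(s): ",
         paste(setdiff(unique(phase_code), c("B", "A")), collapse = ", "))
  nest_code <- as.character(raw[[nest_col]])
  nest_id <- as.integer(sub("^N[TC]", "", nest_code))
  treatment <- ifelse(grepl("^NT", nest_code), "treated", "control")
  if (!is.na(treat_col)) {
    stated <- ifelse(toupper(as.character(raw[[treat_col]])) == "TREATED",
                     "treated", "control")
    if (!all(stated == treatment))
      stop("read_interactions: treatment column contradicts nest codes")
  }
  phase <- ifelse(phase_code == "B", "before", "after")
  bee <- as.character(raw[[bee_col]])

  meta_cols <- stats::na.omit(c(bee_col, nest_col, phase_col, treat_col))
  value_cols <- setdiff(seq_along(raw), meta_cols)
  if (!length(value_cols)) stop("read_interactions: no plant columns")
  Wall <- as.matrix(raw[, value_cols, drop = FALSE])
  suppressWarnings(storage.mode(Wall) <- "numeric")
  if (anyNA(Wall)) stop("read_interactions: non-numeric interaction cells")
  if (any(Wall < 0)) stop("read_interactions: negative interaction cells")

  key <- paste(nest_code, phase_code, sep = "_")
  if (anyDuplicated(paste(bee, key)))
    stop("read_interactions: duplicate (bee, network) row ids")

  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    W <- Wall[rows, , drop = FALSE]
    rownames(W) <- bee[rows]
    W <- W[, colSums(W) > 0, drop = FALSE]
    out[[k]] <- interaction_matrix(W, nest_id = nest_id[rows[1]],
                                   phase = phase[rows[1]],
                                   treatment = treatment[rows[1]])
  }
  out
}

#' Write interaction matrices to an S1-dialect CSV
#'
#' Inverse of [read_interactions()]: all networks are written into one file
#' with bee id, nest, treatment and phase columns followed by the union of
#' plant columns (zeros where a plant is absent from a network).
#'
#' @param nets named list of [interaction_matrix()] objects.
#' @param path output CSV path.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_interactions <- function(nets, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("write_interactions: ", path, " exists (use overwrite = TRUE)")
  plants <- sort(unique(unlist(lapply(nets, function(n) colnames(n$W)))))
  rows <- lapply(nets, function(n) {
    W <- matrix(0, nrow(n$W), length(plants), dimnames = list(rownames(n$W), plants))
    W[, colnames(n$W)] <- n$W
    data.frame(bee = rownames(n$W),
               nest = sprintf("%s%d", if (n$treatment == "treated") "NT" else "NC", n$nest_id),
               treatment = if (n$treatment == "treated") "TREATED" else "UNTREATED",
               phase = if (n$phase == "before") "B" else "A",
               W, check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample OTU read-count CSV
#'
#' Expects the first column to hold sample ids, metadata columns `nest_id`,
#' `treatment` and `phase`, and the remaining columns integer read counts per
#' OTU. Column order is preserved.
#'
#' @param path CSV file path.
#' @return a [read_count_table()], or an empty one (with a warning) for a
#'   header-only file.
#' @export
read_read_counts <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("nest_id", "treatment", "phase")
  otu_cols <- setdiff(names(raw)[-1], need)
  if (!length(otu_cols)) stop("read_read_counts: no OTU columns")
  if (!nrow(raw)) {
    warning("read_read_counts: header-only file, returning empty collection")
    counts <- matrix(integer(0), 0, length(otu_cols), dimnames = list(NULL, otu_cols))
    meta <- data.frame(sample_id = character(0), nest_id = integer(0),
                       treatment = character(0), phase = character(0))
    return(structure(list(counts = counts, meta = meta), class = "read_count_table"))
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("read_read_counts: missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  counts <- as.matrix(raw[, otu_cols, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "numeric")
  if (anyNA(counts) || any(counts != floor(counts)))
    stop("read_read_counts: non-integer read value")
  meta <- data.frame(sample_id = as.character(raw[[1]]),
                     nest_id = as.integer(raw$nest_id),
                     treatment = as.character(raw$treatment),
                     phase = as.character(raw$phase),
                     stringsAsFactors = FALSE)
  read_count_table(counts, meta)
}

#' Write a read-count table to CSV
#' @param x a [read_count_table()].
#' @param path output CSV path.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_read_counts <- function(x, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("write_read_counts: ", path, " exists (use overwrite = TRUE)")
  df <- data.frame(sample_id = x$meta$sample_id,
                   nest_id = x$meta$nest_id,
                   treatment = x$meta$treatment,
                   phase = x$meta$phase,
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a long-format index report
#'
#' Serialises computed network- and node-level index values as a long CSV
#' with columns `network`, `index`, `scope`, `node`, `value` and a 2-decimal
#' `display` column matching the rounding convention of published index
#' tables.
#'
#' @param results data.frame with columns `network`, `index`, `scope`
#'   (`"network"`, `"bumblebee"` or `"plant"`), `node` (`NA` for
#'   network-level) and `value`; the output of [network_indices()] /
#'   [node_indices()] can be row-bound directly.
#' @param path output CSV path.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_index_report <- function(results, path, overwrite = FALSE) {
  if (is.null(results) || !nrow(results)) stop("write_index_report: empty input")
  if (file.exists(path) && !overwrite)
    stop("write_index_report: ", path, " exists (use overwrite = TRUE)")
  need <- c("network", "index", "scope", "node", "value")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("write_index_report: missing column(s): ",
                         paste(miss, collapse = ", "))
  results <- results[, need]
  results$display <- sprintf("%.2f", results$value)
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
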