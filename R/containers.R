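#' Read-count table for pollen pellet samples
#'
#' Bundles an integer matrix of sequencing read counts (samples in rows, OTUs
#' or plant taxa in columns) with the per-sample metadata the experimental
#' design requires: nest identity, treated/control status, and experimental
#' phase (before/after the workforce reduction).
#'
#' @param counts integer matrix, samples x OTUs; rownames are sample ids.
#' @param meta data.frame with columns `sample_id`, `nest_id`, `treatment`
#'   (`"treated"`/`"control"`), `phase` (`"before"`/`"after"`); one row per
#'   sample, in the same order as `counts`.
#' @return An object of class `read_count_table`.
#' @export
read_count_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- meta$sample_id
  if (ncol(counts) < 1L) stop("read_count_table: no OTU columns")
  if (any(counts < 0)) stop("read_count_table: negative read counts")
  if (any(counts != floor(counts))) stop("read_count_table: non-integer read counts")
  need <- c("sample_id", "nest_id", "treatment", "phase")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("read_count_table: missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("read_count_table: duplicate sample ids")
  if (nrow(meta) != nrow(counts)) stop("read_count_table: counts/meta row mismatch")
  if (!all(meta$treatment %in% c("treated", "control")))
    stop("read_count_table: treatment must be 'treated' or 'control'")
  if (!all(meta$phase %in% c("before", "after")))
    stop("read_count_table: phase must be 'before' or 'after'")
  rownames(counts) <- meta$sample_id
  structure(list(counts = counts, meta = as.data.frame(meta, stringsAsFactors = FALSE)),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("read_count_table: %d samples x %d OTUs, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.read_count_table <- function(x) dim(x$counts)

#' Bipartite individual-by-plant interaction matrix
#'
#' One foraging network: rows are individual bumblebees (their pollen
#' pellets), columns are plant taxa, cells are read counts (or presences).
#' Marginals are always recomputed from the stored matrix, never cached.
#'
#' @param W non-negative numeric matrix with row and column names.
#' @param nest_id nest identity (integer).
#' @param phase `"before"` or `"after"`.
#' @param treatment `"treated"` or `"control"`.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(W, nest_id = NA_integer_, phase = NA_character_,
                               treatment = NA_character_) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("interaction_matrix: negative cells")
  if (any(rowSums(W) == 0)) stop("interaction_matrix: all-zero rows (a pellet contains >= 1 taxon)")
  if (is.null(rownames(W))) rownames(W) <- paste0("BB", seq_len(nrow(W)))
  if (is.null(colnames(W))) colnames(W) <- paste0("plant", seq_len(ncol(W)))
  structure(list(W = W, nest_id = nest_id, phase = phase, treatment = treatment),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: nest %s, %s, %s; %d bees x %d plants, total weight %g\n",
              x$nest_id, x$treatment, x$phase, nrow(x$W), ncol(x$W), sum(x$W)))
  invisible(x)
}

#' Network id string for an interaction matrix
#' @param net an `interaction_matrix`.
#' @return character id like `"NT1_B"`.
#' @export
network_id <- function(net) {
  stopifnot(inherits(net, "interaction_matrix"))
  sprintf("%s%s_%s",
          if (identical(net$treatment, "treated")) "NT" else "NC",
          net$nest_id,
          if (identical(net$phase, "before")) "B" else "A")
}

# coerce interaction_matrix or plain matrix to a numeric matrix
as_weight_matrix <- function(net) {
  if (inherits(net, "interaction_matrix")) net$W else as.matrix(net)
}

#' Binarize an interaction matrix
#'
#' Applies the presence/absence rule `W > 0 -> 1`. The stored matrix always
#' keeps read counts; binarization is done lazily by the metrics that need
#' binary input.
#' @param net an `interaction_matrix` or matrix.
#' @return numeric 0/1 matrix.
#' @export
binarize <- function(net) {
  W <- as_weight_matrix(net)
  (W > 0) * 1
}

#' Marginal totals of a network
#'
#' Row totals, column totals and grand total of the weight matrix, recomputed
#' from the cells each call so they can never be stale.
#' @param net an `interaction_matrix` or matrix.
#' @return list with `b_row`, `b_col`, `total`.
#' @export
marginals <- function(net) {
  W <- as_weight_matrix(net)
  list(b_row = rowSums(W), b_col = colSums(W), total = sum(W))
}

# Shannon entropy of a non-negative weight vector (normalised internally).
# base = exp(1) for natural-log entropies, 2 for the link-density family.
shannon <- function(w, base = exp(1)) {
  w <- w[w > 0]
  if (!length(w)) return(0)
  p <- w / sum(w)
  -sum(p * log(p, base = base))
}

#' Pollen-quantity trait table
#'
#' Maps plant taxon names to ordinal pollen-production ranks P0 (low) to P5
#' (high) and their numeric values 0-5.
#'
#' @param plant character vector of taxon names.
#' @param rank character vector of ranks in `"P0"`..`"P5"`.
#' @return data.frame with columns `plant`, `rank`, `value`.
#' @export
trait_table <- function(plant, rank) {
  rank <- as.character(rank)
  ok <- rank %in% paste0("P", 0:5)
  if (!all(ok)) stop("trait_table: ranks must be P0..P5; offending: ",
                     paste(unique(rank[!ok]), collapse = ", "))
  data.frame(plant = canonical_plant(plant), rank = rank,
             value = as.integer(sub("^P", "", rank)),
             stringsAsFactors = FALSE)
}

#' Look up trait ranks for the plants of a network
#'
#' Plants present in the network but absent from the trait table are flagged
#' missing rather than dropped.
#' @param net an `interaction_matrix`.
#' @param traits a `trait_table()` data.frame.
#' @return data.frame `plant`, `rank`, `value`, `missing`.
#' @export
match_traits <- function(net, traits) {
  plants <- canonical_plant(colnames(as_weight_matrix(net)))
  i <- match(plants, traits$plant)
  data.frame(plant = plants,
             rank = ifelse(is.na(i), NA_character_, traits$rank[i]),
             value = ifelse(is.na(i), NA_integer_, traits$value[i]),
             missing = is.na(i),
             stringsAsFactors = FALSE)
}

# exact matching after whitespace trimming and case folding; shortened plant
# names are opaque keys
canonical_plant <- function(x) tolower(trimws(x))
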