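# Programmatic fixtures shared across test files.

# small S1-dialect interaction CSV: 2 nests x 2 phases, 3 bees each
write_s1_fixture <- function(path, negative_cell = FALSE, bad_phase = FALSE,
                             duplicate_bee = FALSE) {
  plants <- c("tara.off", "trif.pra", "cirs.arv", "camp.rot")
  rows <- expand.grid(bee = 1:3, phase = c("B", "A"), nest = c("NT1", "NC3"),
                      stringsAsFactors = FALSE)
  set.seed(42)
  W <- matrix(rpois(nrow(rows) * length(plants), 3), nrow(rows), length(plants),
              dimnames = list(NULL, plants))
  W[W < 2] <- 0
  W[rowSums(W) == 0, 1] <- 5
  if (negative_cell) W[1, 1] <- -1
  df <- data.frame(bee = paste0("BB", rows$bee),
                   nest = rows$nest,
                   treatment = ifelse(rows$nest == "NT1", "TREATED", "UNTREATED"),
                   phase = if (bad_phase) replace(rows$phase, 1, "Q") else rows$phase,
                   W, check.names = FALSE, stringsAsFactors = FALSE)
  if (duplicate_bee) df$bee[2] <- df$bee[1]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# deterministic toy read-count table: 4 samples, 5 OTUs
toy_read_counts <- function() {
  counts <- rbind(c(1000, 800, 3, 0, 0),
                  c(500, 0, 0, 2, 0),
                  c(0, 900, 850, 0, 4),
                  c(700, 0, 0, 0, 0))
  colnames(counts) <- paste0("otu", 1:5)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     nest_id = c(1L, 1L, 2L, 2L),
                     treatment = c("treated", "treated", "control", "control"),
                     phase = c("before", "after", "before", "after"),
                     stringsAsFactors = FALSE)
  read_count_table(counts, meta)
}

staircase3 <- matrix(c(1, 1, 1,
                       1, 1, 0,
                       1, 0, 0), 3, 3, byrow = TRUE,
                     dimnames = list(paste0("BB", 1:3), paste0("p", 1:3)))

two_block4 <- {
  W <- matrix(0, 4, 4, dimnames = list(paste0("BB", 1:4), paste0("p", 1:4)))
  W[1:2, 1:2] <- 1
  W[3:4, 3:4] <- 1
  W
}
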