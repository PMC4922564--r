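# Small in-code fixtures shared across test files.

make_msa <- function(rows, ids = NULL, position_labels = NULL) {
  ids <- ids %||% paste0("p", seq_along(rows))
  site_alignment(setNames(rows, ids), position_labels = position_labels)
}

make_clusters <- function(labels, ids = NULL) {
  ids <- ids %||% paste0("p", seq_along(labels))
  tibble::tibble(id = ids, cluster = labels)
}

# Two-level block similarity matrix with optional symmetric noise.
block_matrix <- function(blocks, within = 0.9, between = 0.1, sd = 0,
                         ids = paste0("p", seq_along(blocks))) {
  n <- length(blocks)
  m <- between + (within - between) * outer(blocks, blocks, `==`)
  if (sd > 0) {
    z <- matrix(rnorm(n * n, sd = sd), n, n)
    m <- m + (z + t(z)) / 2
  }
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

simple_evidence <- function(values, name = "ev", orientation = "similarity") {
  evidence_matrix(values, name = name, orientation = orientation)
}

`%||%` <- rlang::`%||%`
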