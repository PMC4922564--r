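# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (< 2^31) from a root seed and a stream tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

check_residues <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("unknown residue letter(s) %s in %s",
                  paste0("'", bad, "'", collapse = ", "), what))
  }
  invisible(chars)
}

# Split gapped alignment rows into a character matrix (rows = proteins).
site_char_matrix <- function(rows) {
  do.call(rbind, strsplit(unname(rows), ""))
}

upper_tri_values <- function(m) m[upper.tri(m)]
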