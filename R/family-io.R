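#' Construct a protein family table
#'
#' A protein family is represented as a tibble with one row per protein:
#' columns `id` (unique identifiers), `sequence` (amino-acid domain
#' subsequence, may be `NA`) and `label` (known subfamily/class name, may
#' be `NA`).
#'
#' @param id Character vector of unique protein identifiers.
#' @param sequence Optional character vector of amino-acid sequences.
#' @param label Optional character vector of subfamily labels.
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @export
#' @examples
#' protein_family(c("p1", "p2"), sequence = c("KAW", "KAY"))
protein_family <- function(id, sequence = NULL, label = NULL) {
  id <- as.character(id)
  if (length(id) == 0) abort("a protein family needs at least one id")
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate protein id(s): %s",
                  paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  tibble(
    id = id,
    sequence = if (is.null(sequence)) NA_character_ else as.character(sequence),
    label = if (is.null(label)) NA_character_ else as.character(label)
  )
}

#' Read a protein family from FASTA
#'
#' @param fasta Path to a (possibly gapped) FASTA file.
#' @param labels Optional path to a TSV with columns `id`, `label`.
#' @return A protein family tibble (see [protein_family()]).
#' @export
read_family <- function(fasta, labels = NULL) {
  seqs <- Biostrings::readBStringSet(fasta)
  fam <- protein_family(names(seqs), sequence = as.character(seqs))
  if (!is.null(labels)) {
    lab <- read_label_table(labels)
    fam$label <- lab$label[match(fam$id, lab$id)]
  }
  fam
}

#' Write a protein family to FASTA
#'
#' @param family Protein family tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_family <- function(family, path) {
  keep <- !is.na(family$sequence)
  x <- Biostrings::BStringSet(setNames(family$sequence[keep], family$id[keep]))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a pairwise score table
#'
#' Reads a TSV with header columns `id_a`, `id_b`, `value` holding one
#' real-valued score per unordered protein pair (precomputed upstream:
#' structural alignment statistics, context scores, signature distances,
#' ...).  A pair listed twice -- in either order -- is an error.
#'
#' @param path TSV path.
#' @param name Evidence identifier (defaults to the file name sans
#'   extension).
#' @param ids Optional character vector of known protein ids; rows
#'   referencing other ids are an error.
#' @return Tibble with columns `id_a`, `id_b`, `value` and attribute
#'   `name`.
#' @export
read_pair_table <- function(path, name = NULL, ids = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    id_a = readr::col_character(),
    id_b = readr::col_character(),
    value = readr::col_double()
  ))
  validate_pair_table(df, name = name, ids = ids)
}

validate_pair_table <- function(df, name, ids = NULL) {
  if (!all(c("id_a", "id_b", "value") %in% names(df))) {
    abort(sprintf("pair table '%s' must have columns id_a, id_b, value", name))
  }
  if (any(!is.finite(df$value) & !is.na(df$value))) {
    abort(sprintf("pair table '%s' has non-finite values", name))
  }
  if (any(df$id_a == df$id_b)) {
    abort(sprintf("pair table '%s' lists self-pairs", name))
  }
  key <- paste(pmin(df$id_a, df$id_b), pmax(df$id_a, df$id_b))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(sprintf("duplicate pair(s) in table '%s': %s", name,
                  paste(head(dup, 5), collapse = "; ")))
  }
  if (!is.null(ids)) {
    bad <- setdiff(unique(c(df$id_a, df$id_b)), ids)
    if (length(bad) > 0) {
      abort(sprintf("pair table '%s' references unknown id(s): %s", name,
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  out <- tibble(id_a = df$id_a, id_b = df$id_b, value = df$value)
  attr(out, "name") <- name
  out
}

#' Write a pairwise score table
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `value`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_tsv(pairs[, c("id_a", "id_b", "value")], path)
  invisible(path)
}

read_label_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), label = readr::col_character()
  ))
}

#' Read a per-protein property table
#'
#' TSV with an `id` column, any number of scalar columns (molecular
#' weight, isoelectric point, instability index, class molar percentages,
#' GRAVY, ...) and optional set-valued columns (annotation identifiers
#' separated by commas), declared through `set_columns`.
#'
#' @param path TSV path.
#' @param set_columns Character vector of column names to parse as
#'   comma-separated identifier sets (become list-columns).
#' @param ids Optional known ids for cross-reference validation.
#' @return Tibble keyed by `id`.
#' @export
read_property_table <- function(path, set_columns = character(), ids = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_guess()
  ))
  if (!"id" %in% names(df)) abort("property table must have an 'id' column")
  for (col in intersect(set_columns, names(df))) {
    df[[col]] <- lapply(strsplit(as.character(df[[col]]), ","),
                        function(x) setdiff(trimws(x), c("", "NA")))
  }
  scalar_cols <- setdiff(names(df), c("id", set_columns))
  for (col in scalar_cols) {
    v <- df[[col]]
    if (is.numeric(v) && any(!is.finite(v) & !is.na(v))) {
      abort(sprintf("property column '%s' has non-finite values", col))
    }
  }
  if (!is.null(ids)) {
    bad <- setdiff(df$id, ids)
    if (length(bad) > 0) {
      abort(sprintf("property table references unknown id(s): %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  df
}

#' Load a family and all its evidence inputs
#'
#' Convenience loader binding together the FASTA family, any number of
#' pairwise score tables, a property table and a label table, with all
#' cross-references validated.  Missing per-pair entries stay missing (a
#' mask, resolved at normalization) rather than being fabricated.
#'
#' @param fasta Path to the family FASTA.
#' @param pairs Character vector of pair-table TSV paths (possibly empty).
#' @param properties Optional property-table TSV path.
#' @param labels Optional label TSV path (`id`, `label`).
#' @param set_columns Passed to [read_property_table()].
#' @return List with elements `family` (tibble), `pairs` (named list of
#'   pair tibbles) and `properties` (tibble or `NULL`).
#' @export
load_family_inputs <- function(fasta, pairs = character(), properties = NULL,
                               labels = NULL, set_columns = character()) {
  family <- read_family(fasta, labels = labels)
  pair_tables <- lapply(pairs, read_pair_table, ids = family$id)
  names(pair_tables) <- vapply(pair_tables, attr, "", "name")
  props <- if (!is.null(properties)) {
    read_property_table(properties, set_columns = set_columns,
                        ids = family$id)
  }
  list(family = family, pairs = pair_tables, properties = props)
}

#' Filter a family by domain-subsequence length
#'
#' Keeps proteins whose subsequence length lies within one sample standard
#' deviation of the family mean length; statistics are computed on the
#' input family (so the filter is contractive, not idempotent on its own
#' re-computed statistics).
#'
#' @param family Protein family tibble; all rows must have sequences.
#' @return The filtered family tibble.
#' @export
#' @examples
#' fam <- protein_family(paste0("p", 1:4),
#'                       sequence = strrep("A", c(100, 100, 100, 200)))
#' filter_by_length(fam)  # drops the length-200 outlier
filter_by_length <- function(family) {
  if (any(is.na(family$sequence))) {
    abort("filter_by_length requires a sequence for every protein")
  }
  len <- nchar(family$sequence)
  if (length(len) < 2) abort("length filter undefined for fewer than 2 sequences")
  keep <- abs(len - mean(len)) <= sd(len)
  family[keep, , drop = FALSE]
}

#' Filter a family by identity to reference structures
#'
#' Keeps proteins having at least `threshold` percent sequence identity to
#' at least one reference structure (the minimum a homology modeller will
#' accept).
#'
#' @param family Protein family tibble.
#' @param identities Tibble with columns `id`, `reference`, `identity`
#'   (percent in \[0, 100\]).
#' @param threshold Identity percent threshold (default 30).
#' @param on_missing What to do with proteins having no identity entries:
#'   `"error"` (default) or `"drop"`.
#' @return The filtered family tibble.
#' @export
filter_by_reference_identity <- function(family, identities, threshold = 30,
                                         on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (any(identities$identity < 0 | identities$identity > 100)) {
    abort("identity values must lie in [0, 100]")
  }
  best <- tapply(identities$identity, identities$id, max)
  missing <- setdiff(family$id, names(best))
  if (length(missing) > 0 && on_missing == "error") {
    abort(sprintf("no identity entries for id(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  keep <- family$id %in% names(best)[best >= threshold]
  family[keep, , drop = FALSE]
}
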