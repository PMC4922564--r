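#' Construct an active-site alignment
#'
#' A fixed-width gapped alignment of the residues of each family protein
#' that superpose onto a reference structure's pocket positions: one
#' string per protein over the 20 amino acids plus `'-'` (no
#' correspondence in the model).
#'
#' @param rows Named character vector (protein id -> gapped string), all
#'   of equal length.
#' @param position_labels Optional integer/character vector of length
#'   `width` mapping alignment positions to reference-structure residue
#'   numbers (used when rendering SDP labels like "K11_523").
#' @return Object of class `site_alignment` (a named character vector
#'   with attributes `width` and `position_labels`).
#' @export
site_alignment <- function(rows, position_labels = NULL) {
  if (length(rows) == 0) abort("empty alignment")
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    abort("alignment rows need unique protein ids as names")
  }
  w <- unique(nchar(rows))
  if (length(w) != 1) abort("all alignment rows must have the same width")
  bad <- setdiff(unique(unlist(strsplit(rows, ""))), c(AA_ALPHABET, "-"))
  if (length(bad) > 0) {
    abort(sprintf("invalid alignment character(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(position_labels) && length(position_labels) != w) {
    abort("position_labels must have one entry per alignment column")
  }
  structure(rows, width = w, position_labels = position_labels,
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat(sprintf("<site_alignment: %d proteins x %d positions>\n",
              length(x), attr(x, "width")))
  invisible(x)
}

#' @export
`[.site_alignment` <- function(x, i) {
  site_alignment(unclass(x)[i], position_labels = attr(x, "position_labels"))
}

#' Read / write an active-site alignment as aligned FASTA
#'
#' @param path Aligned FASTA path.
#' @return A `site_alignment`.
#' @export
read_site_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  site_alignment(setNames(as.character(seqs), names(seqs)))
}

#' @rdname read_site_alignment
#' @param msa A `site_alignment`.
#' @export
write_site_alignment <- function(msa, path) {
  x <- Biostrings::BStringSet(setNames(as.character(unclass(msa)), names(msa)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Residue conservation at an alignment position
#'
#' The modal non-gap residue at a position and its fraction.  By default
#' the denominator counts all rows (a residue must be present and
#' identical in the required fraction of the whole family); set
#' `denominator = "ungapped"` to count only non-gap rows.
#'
#' @param msa A `site_alignment`.
#' @param position Column index.
#' @param denominator `"all"` (default) or `"ungapped"`.
#' @return List with elements `residue` (character, `NA` for an all-gap
#'   column) and `fraction`.
#' @export
#' @examples
#' msa <- site_alignment(c(p1 = "A", p2 = "A", p3 = "B", p4 = "-"))
#' position_conservation(msa, 1)  # A at 2/4 = 0.5
position_conservation <- function(msa, position,
                                  denominator = c("all", "ungapped")) {
  denominator <- match.arg(denominator)
  w <- attr(msa, "width")
  if (position < 1 || position > w) abort("invalid alignment position")
  col <- substr(unclass(msa), position, position)
  res <- col[col != "-"]
  if (length(res) == 0) return(list(residue = NA_character_, fraction = 0))
  tab <- sort(table(res), decreasing = TRUE)
  denom <- if (denominator == "all") length(col) else length(res)
  list(residue = names(tab)[1], fraction = as.numeric(tab[1]) / denom)
}

#' Select the putative active site among candidate pockets
#'
#' Applies the conservation rule: among pockets having at least
#' `min_conserved` positions whose modal residue is conserved in at least
#' `min_fraction` of the family (boundary inclusive), the pocket with the
#' largest detection score wins; score ties break lexicographically by
#' pocket id for reproducibility.
#'
#' @param pockets Named list of pockets, each a list with elements `msa`
#'   (a [site_alignment()]) and `score` (finite real).
#' @param min_conserved Minimum count of conserved positions (default 3).
#' @param min_fraction Minimum conservation fraction (default 0.5).
#' @param denominator Passed to [position_conservation()].
#' @return The selected pocket id (character scalar) with attribute
#'   `conserved_counts` (named integer vector over all pockets).
#' @export
select_putative_active_site <- function(pockets, min_conserved = 3,
                                        min_fraction = 0.5,
                                        denominator = c("all", "ungapped")) {
  denominator <- match.arg(denominator)
  if (length(pockets) == 0) abort("empty pocket set")
  if (is.null(names(pockets))) abort("pockets must be named")
  counts <- vapply(pockets, function(p) {
    w <- attr(p$msa, "width")
    sum(vapply(seq_len(w), function(i) {
      position_conservation(p$msa, i, denominator)$fraction >= min_fraction
    }, logical(1)))
  }, integer(1))
  qualifying <- names(pockets)[counts >= min_conserved]
  if (length(qualifying) == 0) {
    abort(sprintf(
      "no qualifying pocket (need >= %d positions conserved at >= %.0f%%); conserved counts: %s",
      min_conserved, 100 * min_fraction,
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  scores <- vapply(pockets[qualifying], function(p) p$score, 0)
  ord <- order(-scores, qualifying)
  structure(qualifying[ord[1]], conserved_counts = counts)
}

#' Read a pocket set from a directory
#'
#' Each pocket is an aligned FASTA file; a TSV (`pocket_id`, `score`)
#' supplies the detection scores.
#'
#' @param dir Directory of aligned FASTA files named `<pocket_id>.fasta`.
#' @param scores Path to the score TSV.
#' @return Named list of pockets as consumed by
#'   [select_putative_active_site()].
#' @export
read_pockets <- function(dir, scores) {
  sc <- readr::read_tsv(scores, col_types = readr::cols(
    pocket_id = readr::col_character(), score = readr::col_double()))
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  ids <- sub("\\.fasta$", "", basename(files))
  pockets <- lapply(seq_along(files), function(i) {
    s <- sc$score[match(ids[i], sc$pocket_id)]
    if (is.na(s)) abort(sprintf("no score for pocket '%s'", ids[i]))
    list(msa = read_site_alignment(files[i]), score = s)
  })
  setNames(pockets, ids)
}
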