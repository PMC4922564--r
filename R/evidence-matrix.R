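#' Construct an evidence matrix
#'
#' An evidence matrix holds one source of pairwise functional-similarity
#' evidence for a protein family: a named symmetric N x N real matrix, an
#' orientation (`"similarity"`: larger means more similar;
#' `"distance"`: smaller means more similar) and a symmetric logical mask
#' of missing pairs (context-type evidence is typically available only for
#' a subset of pairs).
#'
#' @param values Symmetric numeric matrix with identical row/column names
#'   (protein ids).  `NA` entries are recorded as missing.
#' @param name Evidence identifier (see [isofam_matrix_names]).
#' @param orientation `"similarity"` or `"distance"`.
#' @param normalized Logical flag; set by [normalize_evidence()].
#' @return An object of class `evidence_matrix`.
#' @export
evidence_matrix <- function(values, name,
                            orientation = c("similarity", "distance"),
                            normalized = FALSE) {
  orientation <- match.arg(orientation)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("evidence values must be a square matrix")
  }
  if (is.null(rownames(values))) {
    abort("evidence matrix needs protein ids as dimnames")
  }
  if (!identical(rownames(values), colnames(values))) {
    abort("row and column ids must match")
  }
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE))) {
    abort(sprintf("evidence matrix '%s' is not symmetric", name))
  }
  missing <- is.na(values)
  structure(
    list(name = name, values = values, orientation = orientation,
         missing = missing, normalized = normalized),
    class = "evidence_matrix"
  )
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat(sprintf("<evidence_matrix '%s': %d proteins, %s-like%s, %d missing pairs>\n",
              x$name, nrow(x$values), x$orientation,
              if (x$normalized) ", normalized" else "",
              sum(x$missing[upper.tri(x$missing)])))
  invisible(x)
}

#' @export
as_tibble.evidence_matrix <- function(x, ...) {
  ids <- rownames(x$values)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    value = x$values[idx]
  )
}

#' Build an evidence matrix from a long pair table
#'
#' Pairs absent from the table are recorded in the missing mask, never
#' fabricated.
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `value` (one row per
#'   unordered pair).
#' @param ids Character vector of all protein ids (fixes matrix order).
#' @param name Evidence identifier; defaults to the table's `name`
#'   attribute.
#' @param orientation `"similarity"` or `"distance"`.
#' @return An `evidence_matrix`.
#' @export
evidence_from_pairs <- function(pairs, ids, name = NULL,
                                orientation = c("similarity", "distance")) {
  orientation <- match.arg(orientation)
  name <- name %||% attr(pairs, "name") %||% "evidence"
  pairs <- validate_pair_table(pairs, name = name, ids = ids)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(pairs$id_a, ids); ib <- match(pairs$id_b, ids)
  m[cbind(ia, ib)] <- pairs$value
  m[cbind(ib, ia)] <- pairs$value
  diag(m) <- 0
  evidence_matrix(m, name = name, orientation = orientation)
}

#' Normalize an evidence matrix to a common similarity orientation
#'
#' Min-max rescales the present off-diagonal values to \[0, 1\] (or to
#' \[-1, 1\] when negative raw values exist), then reverses the interval
#' for distance-like matrices (`x -> 1 - x`, resp. `x -> -x`) so that
#' larger always means more similar.  Missing pairs are imputed at the
#' interval's minimum-similarity value (absence of evidence contributes no
#' similarity); the diagonal is set to the maximum-similarity value.
#' A constant matrix maps to all zeros with a warning.
#'
#' @param m An `evidence_matrix`.
#' @return The normalized `evidence_matrix` (orientation becomes
#'   `"similarity"`, `normalized` flag set).  Idempotent.
#' @export
#' @examples
#' m <- evidence_matrix(matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3,
#'                             dimnames = rep(list(c("a", "b", "c")), 2)),
#'                      name = "difMolWeight", orientation = "distance")
#' normalize_evidence(m)$values
normalize_evidence <- function(m) {
  stopifnot(inherits(m, "evidence_matrix"))
  if (m$normalized) return(m)
  v <- m$values
  off <- upper.tri(v)
  present <- off & !m$missing
  if (!any(present)) abort(sprintf("matrix '%s' has no present pair values", m$name))
  vals <- v[present]
  lo <- min(vals); hi <- max(vals)
  signed <- lo < 0
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  if (hi == lo) {
    warn(sprintf("matrix '%s' is constant; normalizing to all zeros", m$name))
    scaled <- rep(0, length(vals))
  } else if (signed) {
    scaled <- -1 + 2 * (vals - lo) / (hi - lo)
  } else {
    scaled <- (vals - lo) / (hi - lo)
  }
  if (m$orientation == "distance" && hi != lo) {
    scaled <- if (signed) -scaled else 1 - scaled
  }
  out[present] <- scaled
  out[t(present)] <- t(out)[t(present)]
  fill_min <- if (signed) -1 else 0
  fill_max <- 1
  out[is.na(out)] <- fill_min
  diag(out) <- fill_max
  res <- evidence_matrix(out, name = m$name, orientation = "similarity",
                         normalized = TRUE)
  res$missing <- m$missing
  res
}

#' Pearson correlation between two evidence matrices
#'
#' Computed over the upper-triangle pairs present in both matrices; used
#' to quantify redundancy between evidence sources.
#'
#' @param a,b `evidence_matrix` objects over the same protein set.
#' @return Pearson correlation coefficient.
#' @export
evidence_correlation <- function(a, b) {
  stopifnot(inherits(a, "evidence_matrix"), inherits(b, "evidence_matrix"))
  if (!identical(rownames(a$values), rownames(b$values))) {
    abort("matrices cover different protein sets")
  }
  keep <- upper.tri(a$values) & !a$missing & !b$missing
  x <- a$values[keep]; y <- b$values[keep]
  if (length(x) < 2) abort("fewer than 2 common pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant matrix")
  cor(x, y)
}

#' Write / read an evidence matrix as TSV + JSON sidecar
#'
#' The TSV holds the long pair form (`id_a`, `id_b`, `value`; missing
#' pairs omitted); the `.json` sidecar records name, orientation and the
#' normalized flag.
#'
#' @param m An `evidence_matrix`.
#' @param path TSV output path (`.json` sidecar placed alongside).
#' @return `path`, invisibly.
#' @export
write_evidence <- function(m, path) {
  df <- as_tibble(m)
  df <- df[!is.na(df$value), , drop = FALSE]
  readr::write_tsv(df, path)
  meta <- list(name = m$name, orientation = m$orientation,
               normalized = m$normalized, ids = rownames(m$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pairs <- read_pair_table(path, name = meta$name)
  m <- evidence_from_pairs(pairs, ids = meta$ids, name = meta$name,
                           orientation = meta$orientation)
  m$normalized <- isTRUE(meta$normalized)
  if (m$normalized) diag(m$values) <- 1
  m
}
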