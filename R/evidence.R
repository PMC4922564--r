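#' Pairwise sequence alignment scores
#'
#' Optimal global (Needleman-Wunsch) or local (Smith-Waterman) alignment
#' score under BLOSUM62 with affine gap penalties, via
#' [Biostrings::pairwiseAlignment()].  A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param a,b Amino-acid strings over the 20-letter alphabet.
#' @param type `"global"` or `"local"`.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return The optimal alignment score (local scores are floored at 0).
#' @export
#' @examples
#' alignment_score("KAW", "KAW")             # 20
#' alignment_score("KAW", "GKAWG", "local")  # 20
alignment_score <- function(a, b, type = c("global", "local"),
                            gap_open = 10, gap_extend = 4) {
  type <- match.arg(type)
  if (nchar(a) == 0 || nchar(b) == 0) abort("empty sequence")
  check_residues(a); check_residues(b)
  Biostrings::pairwiseAlignment(
    a, b, type = type, substitutionMatrix = blosum62_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
}

#' Alignment-score evidence matrix for a family
#'
#' Computes all pairwise global or local alignment scores for the family's
#' sequences.
#'
#' @param family Protein family tibble with sequences.
#' @param type `"global"` (matrix `seqAliG`) or `"local"` (`seqAliL`).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A similarity-oriented `evidence_matrix`.
#' @export
alignment_score_matrix <- function(family, type = c("global", "local"),
                                   gap_open = 10, gap_extend = 4) {
  type <- match.arg(type)
  ids <- family$id
  if (any(is.na(family$sequence))) abort("all proteins need sequences")
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    js <- seq_len(n)[-seq_len(i)]
    if (length(js) == 0) next
    sc <- Biostrings::pairwiseAlignment(
      family$sequence[js], family$sequence[i], type = type,
      substitutionMatrix = blosum62_matrix,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
    m[i, js] <- sc; m[js, i] <- sc
  }
  diag(m) <- vapply(family$sequence, function(s) alignment_score(s, s, type,
                    gap_open, gap_extend), 0, USE.NAMES = FALSE)
  name <- if (type == "global") "seqAliG" else "seqAliL"
  evidence_matrix(m, name = name, orientation = "similarity")
}

# Columns where neither gapped string has a gap.
comparable_columns <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) abort("active-site strings differ in length")
  list(a = ca, b = cb, ok = ca != "-" & cb != "-")
}

#' Active-site identity percentage
#'
#' Percent of identical residues over the comparable columns of two
#' fixed-width gapped active-site strings.  Columns where either string
#' has a gap are excluded from numerator and denominator (gaps encode
#' modelling failure, not function).  Returns 0 with a warning when no
#' column is comparable.
#'
#' @param a,b Gapped strings of equal length.
#' @return Identity percent in \[0, 100\].
#' @export
#' @examples
#' active_site_identity("KGDI-", "KGDIF")  # 100
active_site_identity <- function(a, b) {
  cc <- comparable_columns(a, b)
  if (!any(cc$ok)) {
    warn("no comparable (gap-free) columns; identity set to 0")
    return(0)
  }
  100 * sum(cc$a[cc$ok] == cc$b[cc$ok]) / sum(cc$ok)
}

#' Active-site BLOSUM62 score
#'
#' Sum of BLOSUM62 substitution scores over the comparable (gap-free)
#' columns of two fixed-width gapped active-site strings.
#'
#' @inheritParams active_site_identity
#' @return Summed BLOSUM62 score (0 with a warning if no comparable
#'   column).
#' @export
#' @examples
#' active_site_blosum62("KC", "RC")  # 2 + 9 = 11
active_site_blosum62 <- function(a, b) {
  cc <- comparable_columns(a, b)
  if (!any(cc$ok)) {
    warn("no comparable (gap-free) columns; score set to 0")
    return(0)
  }
  sum(blosum62_matrix[cbind(cc$a[cc$ok], cc$b[cc$ok])])
}

#' Active-site evidence matrices for a family
#'
#' Builds the two active-site comparison matrices (`ASid`: identity
#' percent; `ASscr`: BLOSUM62 score) from a fixed-width active-site
#' alignment.
#'
#' @param msa Active-site alignment (see [site_alignment()]).
#' @return Named list of two similarity-oriented `evidence_matrix`
#'   objects.
#' @export
active_site_matrices <- function(msa) {
  ids <- names(msa)
  n <- length(ids)
  mid <- matrix(0, n, n, dimnames = list(ids, ids))
  mscr <- mid
  for (i in seq_len(n)) {
    for (j in i:n) {
      mid[i, j] <- mid[j, i] <- suppressWarnings(
        active_site_identity(msa[[i]], msa[[j]]))
      mscr[i, j] <- mscr[j, i] <- suppressWarnings(
        active_site_blosum62(msa[[i]], msa[[j]]))
    }
  }
  list(ASid = evidence_matrix(mid, "ASid", "similarity"),
       ASscr = evidence_matrix(mscr, "ASscr", "similarity"))
}

#' Scalar-difference evidence matrix
#'
#' Distance-like evidence from per-protein scalar properties: entry (i, j)
#' is `|v_i - v_j|`; missing where either value is absent.
#'
#' @param values Named numeric vector (protein id -> scalar).
#' @param name Evidence identifier (e.g. `"difMolWeight"`).
#' @return A distance-oriented `evidence_matrix`.
#' @export
scalar_difference_matrix <- function(values, name) {
  if (any(!is.finite(values) & !is.na(values))) abort("non-finite property value")
  if (sum(!is.na(values)) < 2) abort("need the scalar for at least 2 proteins")
  m <- abs(outer(values, values, `-`))
  dimnames(m) <- list(names(values), names(values))
  evidence_matrix(m, name = name, orientation = "distance")
}

#' Vector-distance evidence matrix
#'
#' Distance-like evidence from per-protein real arrays (structural
#' signatures, composition arrays): pairwise Euclidean or squared
#' Euclidean distances.
#'
#' @param vectors Numeric matrix, one row per protein (rownames = ids).
#' @param name Evidence identifier (e.g. `"csmDist"`, `"aaCompDist"`).
#' @param metric `"euclidean"` or `"squared-euclidean"`.
#' @return A distance-oriented `evidence_matrix`.
#' @export
vector_distance_matrix <- function(vectors, name,
                                   metric = c("euclidean", "squared-euclidean")) {
  metric <- match.arg(metric)
  d <- as.matrix(stats::dist(vectors, method = "euclidean"))
  if (metric == "squared-euclidean") d <- d^2
  dimnames(d) <- list(rownames(vectors), rownames(vectors))
  evidence_matrix(d, name = name, orientation = "distance")
}

#' Shared-annotation evidence matrix
#'
#' Similarity-like evidence counting the annotation identifiers (domains,
#' terms) two proteins have in common.
#'
#' @param sets Named list of character vectors (protein id -> identifier
#'   set; may be empty).
#' @param name Evidence identifier (e.g. `"interpro"`, `"go"`).
#' @return A similarity-oriented `evidence_matrix`.
#' @export
shared_annotation_matrix <- function(sets, name) {
  ids <- names(sets)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  sets <- lapply(sets, unique)
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  evidence_matrix(m, name = name, orientation = "similarity")
}

#' Sequence-derived physicochemical properties
#'
#' Computes, per protein: molecular weight (sum of average residue masses
#' plus one water), molar percentage of each amino-acid class
#' ([amino_acid_classes]), GRAVY (mean Kyte-Doolittle hydropathy) and the
#' 20-entry composition array (observed molar percent divided by the
#' Dayhoff reference percent, [dayhoff_frequencies]).  Isoelectric point
#' and instability index are accepted as inputs elsewhere, not computed.
#'
#' @param family Protein family tibble with sequences.
#' @return Tibble with columns `id`, `mol_weight`, `gravy`,
#'   `pct_<class>` for each class, and list-column `composition`.
#' @export
sequence_properties <- function(family) {
  if (any(is.na(family$sequence))) abort("all proteins need sequences")
  rows <- lapply(seq_len(nrow(family)), function(i) {
    seq <- family$sequence[i]
    if (nchar(seq) == 0) abort("empty sequence")
    chars <- check_residues(seq, family$id[i])
    n <- length(chars)
    counts <- table(factor(chars, levels = AA_ALPHABET))
    molar_pct <- 100 * as.numeric(counts) / n
    names(molar_pct) <- AA_ALPHABET
    cls <- vapply(amino_acid_classes,
                  function(set) sum(molar_pct[set]), 0)
    tibble(
      id = family$id[i],
      mol_weight = sum(residue_masses[chars]) + isofam_water_mass,
      gravy = mean(kyte_doolittle[chars]),
      !!!setNames(as.list(cls), paste0("pct_", names(cls))),
      composition = list(molar_pct / dayhoff_frequencies)
    )
  })
  dplyr::bind_rows(rows)
}

#' Property-difference evidence matrices
#'
#' Builds the standard property-derived evidence matrices from a
#' properties table: scalar-difference matrices for every requested
#' scalar column and the squared-Euclidean composition-distance matrix
#' (`aaCompDist`) when a `composition` list-column is present.
#'
#' @param props Tibble as returned by [sequence_properties()] (or read
#'   from file), keyed by `id`.
#' @param columns Named character vector mapping evidence identifiers to
#'   scalar column names, e.g. `c(difMolWeight = "mol_weight")`.
#' @return Named list of distance-oriented `evidence_matrix` objects.
#' @export
property_difference_matrices <- function(props,
    columns = c(difMolWeight = "mol_weight", difGRAVY = "gravy",
                difAliphRes = "pct_aliphatic", difAromRes = "pct_aromatic",
                difPolarRes = "pct_polar", difChargedRes = "pct_charged",
                difBasicRes = "pct_basic", difAcidicRes = "pct_acidic")) {
  columns <- columns[unname(columns) %in% names(props)]
  out <- lapply(names(columns), function(nm) {
    scalar_difference_matrix(setNames(props[[columns[[nm]]]], props$id), nm)
  })
  names(out) <- names(columns)
  if ("composition" %in% names(props)) {
    comp <- do.call(rbind, props$composition)
    rownames(comp) <- props$id
    out$aaCompDist <- vector_distance_matrix(comp, "aaCompDist",
                                             metric = "squared-euclidean")
  }
  out
}
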