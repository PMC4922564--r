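#' Pointwise mutual information
#'
#' `ln p(x, y) / (p(x) p(y))`, the amount by which the co-occurrence of
#' two events differs from the independence expectation.  Returns `-Inf`
#' when the joint probability is 0 (callers floor at 0).
#'
#' @param p_joint Joint probability `p(x, y)`.
#' @param p_x,p_y Marginal probabilities, strictly positive.
#' @return PMI in nats.
#' @export
#' @examples
#' pmi(0.5, 0.5, 0.5)  # ln 2
pmi <- function(p_joint, p_x, p_y) {
  if (any(c(p_joint, p_x, p_y) < 0) || any(c(p_joint, p_x, p_y) > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (p_x <= 0 || p_y <= 0) abort("marginal probabilities must be positive")
  if (p_joint == 0) return(-Inf)
  log(p_joint / (p_x * p_y))
}

# Per-position residue x cluster counts over non-gap rows.
# Returns NULL for an all-gap column.
position_counts <- function(chars, cluster_of) {
  ok <- chars != "-"
  if (!any(ok)) return(NULL)
  table(cluster = cluster_of[ok],
        residue = factor(chars[ok], levels = AA_ALPHABET))
}

# Core partial-MI computation for one position.
# Probability space: the non-gap rows at this position (cluster marginals
# included).  For cluster j and residue k:
#   PMI_j  = ln( p(c_j, r_k) / (p(c_j) p(r_k)) )
#   PMI_~j = same for the complement of c_j
#   MI_jk  = w_j PMI_j + w_~j PMI_~j, with w = within-(complement-)cluster
#            frequency of r_k; floored to 0 when PMI_j <= 0; 0 * ln 0 = 0.
position_partial_mi <- function(counts) {
  n <- sum(counts)
  n_clust <- rowSums(counts)      # per-cluster non-gap rows
  n_res <- colSums(counts)        # per-residue totals
  clusters <- rownames(counts)
  out <- list()
  for (j in seq_along(clusters)) {
    nj <- n_clust[j]
    if (nj == 0) next
    present <- which(counts[j, ] > 0)
    for (k in present) {
      njk <- counts[j, k]
      pmi_j <- log(njk * n / (nj * n_res[k]))
      w_j <- njk / nj
      njk_c <- n_res[k] - njk
      nj_c <- n - nj
      if (nj_c > 0 && njk_c > 0) {
        pmi_c <- log(njk_c * n / (nj_c * n_res[k]))
        w_c <- njk_c / nj_c
        term_c <- w_c * pmi_c
      } else {
        term_c <- 0  # residue absent from (or no) complement: 0 * ln 0
      }
      mi <- if (pmi_j <= 0) 0 else w_j * pmi_j + term_c
      out[[length(out) + 1]] <- list(
        cluster = clusters[j], residue = colnames(counts)[k],
        partial_mi = max(mi, 0), f = w_j, pmi = pmi_j)
    }
  }
  out
}

#' Partial mutual information of one (position, cluster, residue) triple
#'
#' The contribution of residue `residue` to distinguishing cluster
#' `cluster` at alignment position `position`: the within-cluster
#' frequency-weighted PMI of the residue in the cluster plus the
#' complement-weighted PMI in the union of the other clusters, floored at
#' 0 when the cluster-side PMI is non-positive.  Rows gapped at the
#' position are dropped from the probability space entirely.
#'
#' @param msa A [site_alignment()].
#' @param clusters Cluster assignment tibble (`id`, `cluster`).
#' @param position Alignment column index.
#' @param cluster Cluster value.
#' @param residue One-letter residue code.
#' @return Non-negative partial MI in nats.
#' @export
residue_cluster_mi <- function(msa, clusters, position, cluster, residue) {
  cl <- cluster_vector(clusters, names(msa))
  chars <- substr(unclass(msa), position, position)
  if (!as.character(cluster) %in% cl) abort("unknown cluster")
  counts <- position_counts(chars, cl)
  if (is.null(counts)) return(0)
  # cluster entirely gapped at this position: contributes nothing
  if (!as.character(cluster) %in% rownames(counts)) return(0)
  parts <- position_partial_mi(counts)
  for (p in parts) {
    if (p$cluster == as.character(cluster) && p$residue == residue) {
      return(p$partial_mi)
    }
  }
  0
}

#' Mutual information of one (position, cluster) pair
#'
#' Sum over the residues present in the cluster at the position, each
#' weighted by its within-cluster frequency.
#'
#' @inheritParams residue_cluster_mi
#' @return Non-negative MI in nats.
#' @export
position_cluster_mi <- function(msa, clusters, position, cluster) {
  cl <- cluster_vector(clusters, names(msa))
  chars <- substr(unclass(msa), position, position)
  counts <- position_counts(chars, cl)
  if (is.null(counts)) return(0)
  parts <- position_partial_mi(counts)
  sum(vapply(parts, function(p) {
    if (p$cluster == as.character(cluster)) p$f * p$partial_mi else 0
  }, 0))
}

cluster_vector <- function(clusters, ids) {
  if (is.data.frame(clusters)) {
    cl <- setNames(clusters$cluster, clusters$id)
  } else {
    cl <- clusters
  }
  missing <- setdiff(ids, names(cl))
  if (length(missing) > 0) {
    abort(sprintf("no cluster label for id(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  as.character(cl[ids])
}

#' Overall active-site mutual information of a clustering
#'
#' The cluster-quality measure used as the evolutionary fitness: partial
#' MIs are computed for every (position, cluster, residue) triple,
#' aggregated per (position, cluster) with within-cluster frequency
#' weights, then averaged over positions and clusters
#' (`MI = (1/P)(1/C) sum_i sum_j MI_pi(c_j)`).  The unnormalized double
#' sum is reported alongside, since family-level comparisons are sometimes
#' quoted on that scale.
#'
#' @param msa A [site_alignment()] covering all clustered proteins.
#' @param clusters Cluster assignment tibble (`id`, `cluster`).
#' @param outer_weight Apply the within-cluster frequency weight when
#'   aggregating residues into `MI_pi(c_j)` (the literal reading of the
#'   measure; default `TRUE`).  `FALSE` sums unweighted partial MIs, for
#'   sensitivity analysis.
#' @return Object of class `mi_report`: list with `overall` (averaged
#'   MI), `unnormalized` (plain double sum), `per_position` (tibble:
#'   `position`, `cluster`, `mi`), `per_residue` (tibble: `position`,
#'   `cluster`, `residue`, `partial_mi`, `f`), `P`, `C`.
#' @export
overall_mi <- function(msa, clusters, outer_weight = TRUE) {
  cl <- cluster_vector(clusters, names(msa))
  P <- attr(msa, "width")
  if (P == 0) abort("alignment has no positions")
  cluster_levels <- unique(cl)
  C <- length(cluster_levels)
  mat <- site_char_matrix(unclass(msa))
  acc <- vector("list", P)
  for (i in seq_len(P)) {
    counts <- position_counts(mat[, i], cl)
    if (is.null(counts)) next
    parts <- position_partial_mi(counts)
    if (length(parts) == 0) next
    acc[[i]] <- list(
      position = rep.int(i, length(parts)),
      cluster = vapply(parts, `[[`, "", "cluster"),
      residue = vapply(parts, `[[`, "", "residue"),
      partial_mi = vapply(parts, `[[`, 0, "partial_mi"),
      f = vapply(parts, `[[`, 0, "f"))
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  pull <- function(fld) unlist(lapply(acc, `[[`, fld), use.names = FALSE)
  per_residue <- tibble(
    position = as.integer(pull("position") %||% integer()),
    cluster = as.character(pull("cluster") %||% character()),
    residue = as.character(pull("residue") %||% character()),
    partial_mi = as.double(pull("partial_mi") %||% double()),
    f = as.double(pull("f") %||% double()))
  contrib <- if (outer_weight) per_residue$f * per_residue$partial_mi
             else per_residue$partial_mi
  if (nrow(per_residue) > 0) {
    key <- paste(sprintf("%08d", per_residue$position), per_residue$cluster,
                 sep = "\r")
    sums <- rowsum(contrib, key)
    kk <- strsplit(rownames(sums), "\r", fixed = TRUE)
    per_position <- tibble(
      position = as.integer(vapply(kk, `[`, "", 1)),
      cluster = vapply(kk, `[`, "", 2),
      mi = as.double(sums[, 1]))
  } else {
    per_position <- tibble(position = integer(), cluster = character(),
                           mi = double())
  }
  total <- sum(per_position$mi)
  structure(
    list(overall = total / (P * C), unnormalized = total,
         per_position = per_position, per_residue = per_residue,
         P = P, C = C, outer_weight = outer_weight,
         position_labels = attr(msa, "position_labels")),
    class = "mi_report")
}

#' @export
print.mi_report <- function(x, ...) {
  cat(sprintf("<mi_report: MI = %.4f (unnormalized %.4f), P = %d, C = %d>\n",
              x$overall, x$unnormalized, x$P, x$C))
  invisible(x)
}

#' Rank cluster-discriminating residues (SDP identification)
#'
#' Residues with positive partial MI, in decreasing order of partial MI
#' (ties broken by position index then residue, for determinism).  When
#' the alignment carries reference-structure position labels, a rendered
#' label like `"K11_523"` (residue, alignment position, structure residue
#' number) is added.
#'
#' @param report An [overall_mi()] report.
#' @param cluster Optional cluster to restrict to (default: all).
#' @param top Keep at most this many rows per cluster (default all).
#' @return Tibble with columns `cluster`, `residue`, `position`,
#'   `partial_mi` (and `label` when position labels are available).
#' @export
rank_discriminative_residues <- function(report, cluster = NULL, top = Inf) {
  df <- report$per_residue
  df <- df[df$partial_mi > 0, , drop = FALSE]
  if (!is.null(cluster)) df <- df[df$cluster %in% as.character(cluster), ]
  df <- dplyr::arrange(df, .data$cluster, dplyr::desc(.data$partial_mi),
                       .data$position, .data$residue)
  df <- dplyr::slice_head(dplyr::group_by(df, .data$cluster), n = top)
  df <- dplyr::ungroup(df)
  if (!is.null(report$position_labels)) {
    df$label <- sprintf("%s%d_%s", df$residue, df$position,
                        report$position_labels[df$position])
  }
  df[, c("cluster", "residue", "position", "partial_mi",
         intersect("label", names(df)))]
}

#' Per-cluster active-site composition profile
#'
#' Logo-ready residue/gap frequency table: for every cluster and
#' alignment position, the frequency of each of the 20 residues and the
#' gap character among the cluster's rows (frequencies at a position sum
#' to 1).
#'
#' @inheritParams overall_mi
#' @return Tibble of class `cluster_profile` with columns `cluster`,
#'   `position`, `residue`, `freq`.
#' @export
cluster_profile <- function(msa, clusters) {
  cl <- cluster_vector(clusters, names(msa))
  mat <- site_char_matrix(unclass(msa))
  P <- attr(msa, "width")
  rows <- list()
  for (cj in unique(cl)) {
    sub <- mat[cl == cj, , drop = FALSE]
    for (i in seq_len(P)) {
      tab <- table(factor(sub[, i], levels = c(AA_ALPHABET, "-")))
      freq <- as.numeric(tab) / nrow(sub)
      keep <- freq > 0
      rows[[length(rows) + 1]] <- tibble(
        cluster = cj, position = i,
        residue = names(tab)[keep], freq = freq[keep])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cluster_profile", class(out))
  out
}

#' Write cluster profiles as logo-ready TSV matrices
#'
#' One TSV per cluster: rows = positions, columns = residues plus gap,
#' cells = frequencies (consumable by standard logo renderers).
#'
#' @param profile A [cluster_profile()] tibble.
#' @param dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_cluster_profiles <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(profile$cluster), function(cj) {
    wide <- tidyr::pivot_wider(
      profile[profile$cluster == cj, c("position", "residue", "freq")],
      names_from = "residue", values_from = "freq", values_fill = 0)
    path <- file.path(dir, sprintf("profile_cluster_%s.tsv", cj))
    readr::write_tsv(wide, path)
    path
  }, "")
  invisible(paths)
}
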