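#' Class-by-cluster contingency table from labelings
#'
#' @param truth Tibble (`id`, `label`) of ground-truth classes, or a
#'   named vector.
#' @param clusters Cluster assignment tibble (`id`, `cluster`), or a
#'   named vector.
#' @return Integer matrix (classes x clusters) with dimnames.
#' @export
contingency_from_labels <- function(truth, clusters) {
  tv <- if (is.data.frame(truth)) setNames(truth$label, truth$id) else truth
  cv <- if (is.data.frame(clusters)) setNames(clusters$cluster, clusters$id) else clusters
  if (!setequal(names(tv), names(cv))) abort("truth and clustering cover different ids")
  cv <- cv[names(tv)]
  tab <- table(class = as.character(tv), cluster = as.character(cv))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m
}

#' Read / write a contingency table as TSV
#'
#' Header row = cluster names; first column (`class`) = class names.
#'
#' @param path TSV path.
#' @return Integer matrix (classes x clusters).
#' @export
read_contingency <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    class = readr::col_character(), .default = readr::col_integer()))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$class
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_contingency
#' @param counts Contingency matrix.
#' @export
write_contingency <- function(counts, path) {
  df <- as_tibble(counts, rownames = "class")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Packaged gold-standard validation contingency tables
#'
#' Published class-by-cluster distributions of two SFLD enzyme
#' superfamilies over twelve clusters produced by the evidence-integration
#' framework: `"crotonase"` (12 families, N = 2,694) and `"enolase"`
#' (12 families, N = 4,791).
#'
#' @param which `"crotonase"` or `"enolase"`.
#' @return Integer contingency matrix.
#' @export
sfld_contingency <- function(which = c("crotonase", "enolase")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("sfld_", which, "_contingency.tsv"),
                      package = "isofam", mustWork = TRUE)
  read_contingency(path)
}

#' Pairwise agreement counts between a clustering and a classification
#'
#' Over all unordered object pairs: TP = same class and same cluster,
#' FP = different class but same cluster, FN = same class but different
#' cluster, TN = different in both.  Computed from the contingency table
#' via binomial identities.
#'
#' @param counts Contingency matrix (classes x clusters).
#' @return Tibble with columns `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
pairwise_counts <- function(counts) {
  n <- sum(counts)
  if (n < 2) abort("need at least 2 objects")
  tp <- sum(choose(counts, 2))
  same_cluster <- sum(choose(colSums(counts), 2))
  same_class <- sum(choose(rowSums(counts), 2))
  fp <- same_cluster - tp
  fn <- same_class - tp
  tn <- choose(n, 2) - tp - fp - fn
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, n = n)
}

#' Pairwise external validation measures
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1,
#' Rand index `(TP+TN)/(TP+FP+FN+TN)` and Jaccard coefficient
#' `TP/(TP+FP+FN)`.  A zero denominator makes the corresponding measure
#' an error.
#'
#' @param counts Result of [pairwise_counts()] (or a contingency matrix).
#' @return Tibble with columns `precision`, `recall`, `f1`, `rand`,
#'   `jaccard`.
#' @export
pairwise_measures <- function(counts) {
  if (is.matrix(counts)) counts <- pairwise_counts(counts)
  with(counts, {
    if (tp + fp == 0) abort("precision undefined: no same-cluster pairs")
    if (tp + fn == 0) abort("recall undefined: no same-class pairs")
    precision <- tp / (tp + fp)
    recall <- tp / (tp + fn)
    if (precision + recall == 0) abort("F1 undefined: precision + recall = 0")
    tibble(precision = precision, recall = recall,
           f1 = 2 * precision * recall / (precision + recall),
           rand = (tp + tn) / (tp + fp + fn + tn),
           jaccard = tp / (tp + fp + fn))
  })
}

partition_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Variation of information between two partitions
#'
#' `VI = H(S) + H(S') - 2 I(S, S')` in nats, from the row, column and
#' cell fractions of the contingency table (`0 ln 0 = 0`).  Zero iff the
#' partitions coincide.
#'
#' @param counts Contingency matrix (classes x clusters).
#' @return VI in nats.
#' @export
variation_of_information <- function(counts) {
  n <- sum(counts)
  if (n < 1) abort("empty contingency table")
  pr <- rowSums(counts) / n
  pc <- colSums(counts) / n
  pj <- counts / n
  mi <- sum(ifelse(pj > 0, pj * log(pj / outer(pr, pc)), 0))
  partition_entropy(pr) + partition_entropy(pc) - 2 * mi
}

#' Clustering edit distance
#'
#' Minimum number of split or merge operations transforming the
#' clustering into the classification: twice the number of co-occupied
#' (class, cluster) cells minus the numbers of classes and clusters.
#'
#' @param counts Contingency matrix (classes x clusters).
#' @return Non-negative integer.
#' @export
partition_edit_distance <- function(counts) {
  2L * sum(counts > 0) - nrow(counts) - ncol(counts)
}

#' Full external validation suite
#'
#' All seven agreement measures between a clustering and a ground-truth
#' classification: precision, recall, F1, Rand, Jaccard, variation of
#' information (nats) and edit distance.
#'
#' @param truth Ground truth (`id`/`label` tibble or named vector), or a
#'   contingency matrix if `clusters` is missing.
#' @param clusters Cluster assignment (`id`/`cluster` tibble or named
#'   vector); omit when `truth` is already a contingency matrix.
#' @return One-row tibble with the seven measures plus `n`.
#' @export
#' @examples
#' cluster_agreement(sfld_contingency("crotonase"))
cluster_agreement <- function(truth, clusters = NULL) {
  counts <- if (is.matrix(truth) && is.null(clusters)) truth
            else contingency_from_labels(truth, clusters)
  pm <- pairwise_measures(counts)
  dplyr::mutate(pm,
    vi = variation_of_information(counts),
    edit = partition_edit_distance(counts),
    n = sum(counts))
}
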