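#' Build a graph affinity matrix from a combined similarity matrix
#'
#' Adjacency of the totally connected similarity graph: the input is
#' shifted to be non-negative (affine shift by `-min` if any entry is
#' negative), the diagonal is zeroed (no self-loops), and rows that would
#' otherwise have zero degree receive a tiny floor so the graph stays
#' connected numerically.
#'
#' @param s Symmetric numeric matrix (the integrated pairwise similarity),
#'   with protein ids as dimnames.
#' @param eps Degree floor added to all-zero rows (default 1e-12).
#' @return Symmetric non-negative affinity matrix with zero diagonal.
#' @export
build_affinity <- function(s, eps = 1e-12) {
  if (inherits(s, "evidence_matrix")) s <- s$values
  if (!is.matrix(s) || nrow(s) != ncol(s)) abort("affinity input must be square")
  if (!isTRUE(all.equal(s, t(s), check.attributes = FALSE))) {
    abort("affinity input must be symmetric")
  }
  if (any(!is.finite(s))) abort("affinity input must be finite")
  w <- s
  mn <- min(w[upper.tri(w)])
  if (is.finite(mn) && mn < 0) w <- w - mn
  diag(w) <- 0
  deg <- rowSums(w)
  zero <- deg <= 0
  if (any(zero)) {
    w[zero, ] <- w[zero, ] + eps
    w[, zero] <- w[, zero] + eps
    diag(w) <- 0
  }
  w
}

# Embedding: eigenvectors of the random-walk Laplacian L_rw = I - D^-1 W
# for the K smallest eigenvalues, obtained through the equivalent
# symmetric generalized problem (L_sym = D^-1/2 (D - W) D^-1/2; the
# random-walk eigenvectors are D^-1/2 times the symmetric ones).
spectral_embedding <- function(w, k) {
  n <- nrow(w)
  d <- rowSums(w)
  if (any(d <= 0)) abort("affinity has an isolated vertex; use build_affinity()")
  inv_sqrt_d <- 1 / sqrt(d)
  lsym <- -(inv_sqrt_d * w) * rep(inv_sqrt_d, each = n)
  lsym <- t(lsym)  # symmetrize orientation of the scaling
  lsym <- (lsym + t(lsym)) / 2
  diag(lsym) <- diag(lsym) + 1
  e <- eigen(lsym, symmetric = TRUE)
  vals <- rev(e$values)[seq_len(k)]           # ascending
  idx <- rev(seq_len(n))[seq_len(k)]
  u <- e$vectors[, idx, drop = FALSE]
  list(vectors = u * inv_sqrt_d, values = vals)
}

# Greedy farthest-point (kmeans++-style) center seeding on embedding rows.
seed_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- colSums((t(x) - x[centers[1], ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, colSums((t(x) - x[centers[j], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' Spectral clustering with the random-walk Laplacian
#'
#' Computes the normalized asymmetric (random-walk) Laplacian
#' `L_rw = I - D^-1 W` of the affinity graph, embeds the proteins into the
#' eigenvectors of its K smallest eigenvalues, and partitions the
#' embedding rows with seeded, multiply-restarted K-means.  Guaranteed
#' non-empty clusters: K-means draws yielding an empty cluster are
#' re-seeded up to `retries` times before erroring.
#'
#' @param w Affinity matrix (see [build_affinity()]).
#' @param k Number of clusters (1 <= k <= N).
#' @param seed Integer seed; fixes the K-means initialization stream so
#'   repeated calls give identical labels.
#' @param restarts K-means restarts per attempt (default 10).
#' @param retries Empty-cluster re-seeding attempts (default 5).
#' @return Tibble with columns `id`, `cluster` (integers `1..k`);
#'   attributes `embedding` (N x K matrix) and `eigenvalues`.
#' @export
#' @examples
#' blocks <- rep(1:2, c(3, 4))
#' w <- build_affinity(outer(blocks, blocks, `==`) * 1)
#' rownames(w) <- colnames(w) <- paste0("p", 1:7)
#' spectral_cluster(w, 2, seed = 1)
spectral_cluster <- function(w, k, seed = 1L, restarts = 10, retries = 5) {
  n <- nrow(w)
  if (k < 1) abort("k must be at least 1")
  if (k > n) abort("k cannot exceed the number of proteins")
  ids <- rownames(w) %||% as.character(seq_len(n))
  if (k == 1) {
    out <- tibble(id = ids, cluster = rep(1L, n))
    return(out)
  }
  emb <- spectral_embedding(w, k)
  x <- emb$vectors
  if (nrow(unique(round(x, 10))) < k) {
    abort("fewer than k numerically distinct embedding rows")
  }
  labels <- with_seed(seed, {
    result <- NULL
    for (attempt in seq_len(retries)) {
      best <- NULL
      for (r in seq_len(restarts)) {
        centers <- seed_centers(x, k)
        km <- tryCatch(
          suppressWarnings(kmeans(x, centers = centers, iter.max = 100)),
          error = function(e) NULL)
        if (is.null(km) || length(unique(km$cluster)) < k) next
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      if (!is.null(best)) { result <- best$cluster; break }
    }
    result
  })
  if (is.null(labels)) {
    abort(sprintf("K-means produced an empty cluster in all %d attempts", retries))
  }
  # canonical label order: clusters numbered by first appearance
  labels <- match(labels, unique(labels))
  out <- tibble(id = ids, cluster = as.integer(labels))
  attr(out, "embedding") <- x
  attr(out, "eigenvalues") <- emb$values
  out
}
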