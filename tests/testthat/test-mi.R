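test_that("pointwise mutual information evaluates its definition", {
  expect_equal(pmi(0.25, 0.5, 0.5), 0)           # independence
  expect_equal(pmi(0.5, 0.5, 0.5), log(2))
  expect_lt(pmi(0.1, 0.5, 0.5), 0)               # complementary distribution
  expect_equal(pmi(0, 0.5, 0.5), -Inf)
  expect_error(pmi(1.5, 0.5, 0.5), "probabilities")
  expect_error(pmi(0.25, 0, 0.5), "positive")
})

two_by_two <- function(col) {
  list(msa = make_msa(col), clusters = make_clusters(rep(1:2, each = 2)))
}

test_that("partial MI of hand-computable columns matches the stated conventions", {
  # exclusive residue: MI(c1, A) = 1 * ln 2 + 0
  f <- two_by_two(c("A", "A", "C", "C"))
  expect_equal(residue_cluster_mi(f$msa, f$clusters, 1, 1, "A"), log(2))
  # independent residue distribution
  f2 <- two_by_two(c("A", "C", "A", "C"))
  expect_equal(residue_cluster_mi(f2$msa, f2$clusters, 1, 1, "A"), 0)
  # 3:1 split: 1 * ln(4/3) + 0.5 * ln(2/3)
  f3 <- two_by_two(c("A", "A", "A", "C"))
  expect_equal(residue_cluster_mi(f3$msa, f3$clusters, 1, 1, "A"),
               log(4 / 3) + 0.5 * log(2 / 3))
  # minority exclusive residue in cluster 2: 0.5 * ln 2
  expect_equal(residue_cluster_mi(f3$msa, f3$clusters, 1, 2, "C"),
               0.5 * log(2))
})

test_that("position MI weights residues by within-cluster frequency", {
  f <- two_by_two(c("A", "A", "C", "C"))
  expect_equal(position_cluster_mi(f$msa, f$clusters, 1, 1), log(2))
  f3 <- two_by_two(c("A", "A", "A", "C"))
  expect_equal(position_cluster_mi(f3$msa, f3$clusters, 1, 2),
               0.5 * (0.5 * log(2)))  # f_C = 0.5 times MI(c2, C)
  uniform <- two_by_two(c("A", "A", "A", "A"))
  expect_equal(position_cluster_mi(uniform$msa, uniform$clusters, 1, 1), 0)
})

test_that("partial MIs agree with a brute-force probability-table oracle", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    k <- sample(2:3, 1)
    col <- sample(c("A", "C", "D", "E", "-"), n, replace = TRUE)
    cl <- sample.int(k, n, replace = TRUE)
    cl[seq_len(k)] <- seq_len(k)  # every cluster non-empty
    msa <- make_msa(col)
    clusters <- make_clusters(cl)
    for (cj in seq_len(k)) {
      for (res in unique(col[col != "-"])) {
        expect_equal(
          residue_cluster_mi(msa, clusters, 1, cj, res),
          oracle_partial_mi(col, cl, cj, res),
          tolerance = 1e-9,
          label = sprintf("rep %d cluster %d residue %s", rep, cj, res))
      }
    }
  }
})

test_that("overall MI reaches its closed forms", {
  f <- two_by_two(c("A", "A", "C", "C"))
  expect_equal(overall_mi(f$msa, f$clusters)$overall, log(2))
  # C equal clusters with exclusive residues at every position -> ln C
  for (C in c(2, 3, 5)) {
    for (P in c(1, 10)) {
      res <- isofam:::AA_ALPHABET[seq_len(C)]
      rows <- rep(strrep(res, P), each = 4)
      msa <- make_msa(rows)
      clusters <- make_clusters(rep(seq_len(C), each = 4))
      rep_out <- overall_mi(msa, clusters)
      expect_equal(rep_out$overall, log(C), tolerance = 1e-12)
      expect_equal(rep_out$unnormalized, P * C * log(C), tolerance = 1e-12)
    }
  }
  # identical residue everywhere contributes nothing
  uni <- make_msa(rep("AAA", 6))
  expect_equal(overall_mi(uni, make_clusters(rep(1:2, each = 3)))$overall, 0)
})

test_that("MI is invariant under relabeling and reordering and non-negative", {
  set.seed(13)
  n <- 12
  rows <- replicate(n, paste(sample(c("A", "C", "D", "-"), 5, replace = TRUE),
                             collapse = ""))
  msa <- make_msa(rows)
  cl <- sample.int(3, n, replace = TRUE); cl[1:3] <- 1:3
  base <- overall_mi(msa, make_clusters(cl))
  expect_gte(base$overall, 0)
  expect_true(all(base$per_residue$partial_mi >= 0))
  # relabel clusters
  relab <- overall_mi(msa, make_clusters(c(3, 1, 2)[cl]))
  expect_equal(relab$overall, base$overall)
  # reorder proteins
  perm <- sample(n)
  reord <- overall_mi(make_msa(rows[perm], ids = paste0("p", perm)),
                      make_clusters(cl))
  expect_equal(reord$overall, base$overall)
  # aggregation invariant: overall equals the double-sum average
  expect_equal(base$overall,
               sum(base$per_position$mi) / (base$P * base$C))
})

test_that("cluster-side and complement-side PMIs have opposite signs", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    col <- sample(c("A", "C", "D"), n, replace = TRUE)
    cl <- sample.int(2, n, replace = TRUE); cl[1:2] <- 1:2
    counts <- isofam:::position_counts(col, as.character(cl))
    nn <- sum(counts); nr <- colSums(counts); ncl <- rowSums(counts)
    for (j in 1:2) {
      for (k in which(counts[j, ] > 0 & counts[j, ] < nr)) {
        p1 <- log(counts[j, k] * nn / (ncl[j] * nr[k]))
        njk_c <- nr[k] - counts[j, k]
        p2 <- log(njk_c * nn / ((nn - ncl[j]) * nr[k]))
        if (is.finite(p1) && is.finite(p2) && p1 != 0) {
          expect_true(sign(p1) == -sign(p2) || p2 == 0)
        }
      }
    }
  }
})

test_that("gapped rows are dropped from a position's probability space", {
  msa <- make_msa(c("A", "A", "-", "C"))
  clusters <- make_clusters(c(1, 1, 2, 2))
  # non-gap rows: A,A (c1), C (c2); cluster 1 exclusive A among 3 rows
  expect_equal(residue_cluster_mi(msa, clusters, 1, 1, "A"), log(3 / 2))
  allgap <- make_msa(c("-", "-", "-", "-"))
  expect_equal(overall_mi(allgap, clusters)$overall, 0)
})

test_that("SDP ranking orders by partial MI with deterministic tie-breaks", {
  # position 2 is a perfect SDP; positions 1 and 3 are uniform
  msa <- make_msa(c("AKA", "AKA", "ARA", "ARA"),
                  position_labels = c(101, 102, 103))
  clusters <- make_clusters(rep(1:2, each = 2))
  rep_out <- overall_mi(msa, clusters)
  rk <- rank_discriminative_residues(rep_out)
  expect_equal(rk$position, c(2L, 2L))
  expect_setequal(rk$residue, c("K", "R"))
  expect_equal(rk$label[rk$cluster == "1"], "K2_102")
  # all-uniform alignment yields an empty ranking
  expect_equal(nrow(rank_discriminative_residues(
    overall_mi(make_msa(rep("AA", 4)), clusters))), 0)
})

test_that("cluster profiles are frequency tables summing to one", {
  msa <- make_msa(c("AK", "AR", "C-", "CD"))
  clusters <- make_clusters(rep(1:2, each = 2))
  prof <- cluster_profile(msa, clusters)
  sums <- dplyr::summarise(dplyr::group_by(prof, cluster, position),
                           s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  p2 <- prof[prof$cluster == "1" & prof$position == 2, ]
  expect_setequal(p2$residue, c("K", "R"))
  expect_equal(p2$freq, c(0.5, 0.5))
  gap <- prof[prof$cluster == "2" & prof$position == 2 & prof$residue == "-", ]
  expect_equal(gap$freq, 0.5)
})
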