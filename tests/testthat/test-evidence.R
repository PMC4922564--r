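test_that("alignment scores reproduce hand-checked BLOSUM62 values", {
  expect_equal(alignment_score("KAW", "KAW"), 20)            # 5 + 4 + 11
  expect_equal(alignment_score("KAW", "GKAWG", "local"), 20) # best block KAW
  seqs <- c("KAWCDE", "MNPQRS")
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    expect_equal(alignment_score(s, s),
                 sum(isofam:::blosum62_matrix[cbind(chars, chars)]))
  }
  expect_equal(alignment_score("KAW", "MCD"), alignment_score("MCD", "KAW"))
  expect_gte(alignment_score("W", "D", "local"), 0)
  expect_error(alignment_score("", "KAW"), "empty")
  expect_error(alignment_score("KXZ", "KAW"), "unknown residue")
})

test_that("alignment scores match an independent affine-gap DP oracle", {
  set.seed(101)
  for (i in 1:15) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    expect_equal(alignment_score(a, b, "global"), oracle_align(a, b, "global"),
                 tolerance = 1e-12)
    expect_equal(alignment_score(a, b, "local"), oracle_align(a, b, "local"),
                 tolerance = 1e-12)
  }
})

test_that("alignment-score matrices are symmetric with self-scores on the diagonal", {
  fam <- protein_family(c("a", "b", "c"),
                        sequence = c("KAWCDE", "KAYCDE", "MNPQRS"))
  m <- alignment_score_matrix(fam, "global")
  expect_equal(m$name, "seqAliG")
  expect_equal(m$values, t(m$values))
  expect_equal(m$values["a", "a"], alignment_score("KAWCDE", "KAWCDE"))
  expect_equal(m$values["a", "b"], alignment_score("KAWCDE", "KAYCDE"))
})

test_that("active-site comparisons skip gap columns in both terms", {
  expect_equal(active_site_identity("KGDIF", "KGDIF"), 100)
  expect_equal(active_site_identity("KGDI-", "KGDIF"), 100)
  expect_equal(active_site_identity("KC", "RC"), 50)
  expect_equal(active_site_blosum62("KC", "KC"), 14)  # 5 + 9
  expect_equal(active_site_blosum62("KC", "RC"), 11)  # 2 + 9
  expect_warning(out <- active_site_blosum62("--", "AA"), "no comparable")
  expect_equal(out, 0)
  expect_error(active_site_identity("KC", "KCD"), "length")
  # symmetry
  expect_equal(active_site_identity("KGD-F", "KCDI-"),
               active_site_identity("KCDI-", "KGD-F"))
  expect_equal(active_site_blosum62("KGD-F", "KCDI-"),
               active_site_blosum62("KCDI-", "KGD-F"))
})

test_that("scalar, vector and annotation matrices follow their definitions", {
  w <- setNames(c(10, 10, 30), c("a", "b", "c"))
  m <- scalar_difference_matrix(w, "difMolWeight")
  expect_equal(m$orientation, "distance")
  expect_equal(sort(m$values[upper.tri(m$values)]), c(0, 20, 20))
  expect_equal(m$values, t(m$values))
  expect_true(all(scalar_difference_matrix(
    setNames(rep(2, 3), letters[1:3]), "x")$values == 0))

  vec <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(vector_distance_matrix(vec, "csmDist")$values["a", "b"], 5)
  expect_equal(vector_distance_matrix(vec, "aaCompDist",
                                      "squared-euclidean")$values["a", "b"], 25)

  sets <- list(a = c("x", "y", "z"), b = c("y", "z", "w"), c = character())
  sm <- shared_annotation_matrix(sets, "interpro")
  expect_equal(sm$values["a", "b"], 2)
  expect_equal(sm$values["a", "c"], 0)
  expect_equal(sm$values["a", "a"], 3)
})

test_that("sequence-derived properties match standard reference tables", {
  fam <- protein_family(c("g", "a", "h"),
                        sequence = c("G", "AAAA", "AILV"))
  props <- sequence_properties(fam)
  expect_equal(props$mol_weight[1],
               residue_masses[["G"]] + isofam_water_mass)
  expect_equal(props$pct_aliphatic[2], 100)  # A is aliphatic
  expect_equal(props$pct_aromatic[2], 0)
  expect_equal(props$gravy[3],
               mean(kyte_doolittle[c("A", "I", "L", "V")]))
  comp <- props$composition[[2]]
  expect_equal(unname(comp["A"]), 100 / dayhoff_frequencies[["A"]])
  expect_equal(unname(comp["W"]), 0)
  expect_error(sequence_properties(protein_family("b", sequence = "AXB")),
               "unknown residue")
})

test_that("property-difference matrices cover the requested columns", {
  fam <- protein_family(c("a", "b"), sequence = c("AAKK", "WWDD"))
  props <- sequence_properties(fam)
  mats <- property_difference_matrices(props)
  expect_true(all(c("difMolWeight", "difGRAVY", "aaCompDist") %in% names(mats)))
  expect_equal(mats$difMolWeight$values["a", "b"],
               abs(props$mol_weight[1] - props$mol_weight[2]))
})

test_that("normalization maps to the unit interval and reverses distances", {
  v <- matrix(c(0, 0, 2, 0, 0, 4, 2, 4, 0), 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  v[upper.tri(v)] <- c(0, 2, 4); v[lower.tri(v)] <- t(v)[lower.tri(v)]
  m <- normalize_evidence(simple_evidence(v, orientation = "distance"))
  expect_equal(sort(m$values[upper.tri(m$values)]), c(0, 0.5, 1))
  expect_equal(m$orientation, "similarity")
  expect_equal(diag(m$values), setNames(rep(1, 3), c("a", "b", "c")))

  neg <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  neg[upper.tri(neg)] <- c(-3, -1, 1); neg <- neg + t(neg)
  mn <- normalize_evidence(simple_evidence(neg))
  expect_equal(sort(mn$values[upper.tri(mn$values)]), c(-1, 0, 1))

  # idempotence
  expect_equal(normalize_evidence(m)$values, m$values)
})

test_that("missing pairs are imputed at minimum similarity after normalization", {
  v <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  v[upper.tri(v)] <- c(1, NA, 3); v[lower.tri(v)] <- t(v)[lower.tri(v)]
  m <- normalize_evidence(simple_evidence(v))
  expect_equal(m$values["a", "c"], 0)   # the missing pair
  expect_equal(m$values["a", "b"], 0)   # the raw minimum
  expect_equal(m$values["b", "c"], 1)
  expect_true(m$missing["a", "c"])
})

test_that("constant matrices normalize to zero with a warning", {
  v <- matrix(5, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  expect_warning(m <- normalize_evidence(simple_evidence(v)), "constant")
  expect_true(all(m$values[upper.tri(m$values)] == 0))
})

test_that("evidence correlation behaves as Pearson over shared pairs", {
  set.seed(5)
  ids <- paste0("p", 1:6)
  v <- matrix(0, 6, 6, dimnames = list(ids, ids))
  v[upper.tri(v)] <- runif(15); v <- v + t(v)
  a <- simple_evidence(v, "a")
  b <- simple_evidence(-v, "b")
  expect_equal(evidence_correlation(a, a), 1)
  expect_equal(evidence_correlation(a, b), -1)
  const <- simple_evidence(matrix(1 - diag(6), 6, dimnames = list(ids, ids)), "c")
  expect_error(evidence_correlation(a, const), "constant")
})

test_that("evidence TSV + sidecar round-trips values, orientation and mask", {
  dir <- withr::local_tempdir()
  v <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  v[upper.tri(v)] <- c(1, NA, 3); v[lower.tri(v)] <- t(v)[lower.tri(v)]
  m <- simple_evidence(v, name = "neighborhood")
  path <- file.path(dir, "neighborhood.tsv")
  write_evidence(m, path)
  back <- read_evidence(path)
  expect_equal(back$values, m$values)
  expect_equal(back$name, "neighborhood")
  expect_equal(back$missing["a", "c"], TRUE)
})
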