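norm_block <- function(blocks, name, sd = 0, seed = NULL) {
  v <- if (is.null(seed)) block_matrix(blocks, sd = sd) else
    isofam:::with_seed(seed, block_matrix(blocks, sd = sd))
  normalize_evidence(simple_evidence(v, name = name))
}

test_that("equations render and parse in canonical term order", {
  coef <- c(ASid = 2L, seqAliG = 1L, ASscr = 1L)
  expect_equal(render_equation(coef), "2ASid + ASscr + seqAliG")
  expect_equal(render_equation(c(seqAliG = 1L)), "seqAliG")
  expect_equal(render_equation(c(strAliScr = 3L, interpro = 1L,
                                 neighborhood = 1L)),
               "interpro + neighborhood + 3strAliScr")
  expect_equal(render_equation(c(aaCompDist = 1L, ASscr = 3L, ASid = 1L)),
               "ASid + 3ASscr + aaCompDist")  # C-locale: uppercase first
  # round-trip on printed-style fixtures
  for (eq in c("2ASid + ASscr + seqAliG", "seqAliG",
               "interpro + neighborhood + 3strAliScr",
               "5ASid + difAliphRes + 2go + seqAliG + 3seqAliL + 2strAliId")) {
    expect_equal(render_equation(parse_equation(eq)), eq)
  }
  expect_error(parse_equation("2*bad term"), "cannot parse")
})

test_that("tree genomes expose coefficients as leaf multiplicities", {
  t1 <- isofam:::gp_node(isofam:::gp_leaf("ASid"),
                         isofam:::gp_node(isofam:::gp_leaf("ASid"),
                                          isofam:::gp_leaf("go")))
  expect_equal(tree_coefficients(t1), c(ASid = 2L, go = 1L))
  expect_equal(isofam:::tree_depth(t1), 3L)
})

test_that("crossover conserves leaves and respects the depth bound", {
  set.seed(5)
  a <- isofam:::gp_node(isofam:::gp_leaf("x"), isofam:::gp_leaf("x"))
  b <- isofam:::gp_node(isofam:::gp_leaf("y"), isofam:::gp_leaf("y"))
  seen_mixed <- FALSE
  for (i in 1:50) {
    kids <- crossover_trees(a, b, max_depth = 4)
    leaves_total <- length(isofam:::tree_leaves(kids[[1]])) +
      length(isofam:::tree_leaves(kids[[2]]))
    expect_lte(leaves_total, 8)  # never exceeds combined parental leaves
    expect_lte(isofam:::tree_depth(kids[[1]]), 4)
    expect_true(all(vapply(kids, function(k)
      length(isofam:::tree_leaves(k)) >= 1, TRUE)))
    co <- tree_coefficients(kids[[1]])
    if (identical(co, c(x = 1L, y = 1L))) seen_mixed <- TRUE
  }
  expect_true(seen_mixed)  # {x:2} x {y:2} can yield {x:1, y:1}
})

test_that("mutation and crossover are reproducible under a fixed seed", {
  a <- isofam:::gp_node(isofam:::gp_leaf("x"), isofam:::gp_leaf("y"))
  m1 <- isofam:::with_seed(4, mutate_tree(a, c("x", "y", "z"), 5))
  m2 <- isofam:::with_seed(4, mutate_tree(a, c("x", "y", "z"), 5))
  expect_identical(m1, m2)
  expect_gte(length(isofam:::tree_leaves(m1)), 1)
  c1 <- isofam:::with_seed(4, crossover_trees(a, a, 5))
  c2 <- isofam:::with_seed(4, crossover_trees(a, a, 5))
  expect_identical(c1, c2)
})

test_that("combining evidence is an entrywise weighted sum with validation", {
  blocks <- rep(1:2, each = 4)
  m1 <- norm_block(blocks, "informative")
  m2 <- norm_block(blocks, "other")
  s <- combine_evidence(list(informative = m1, other = m2),
                        c(informative = 2L, other = 1L))
  expect_equal(s, 2 * m1$values + m2$values)
  expect_error(combine_evidence(list(informative = m1), c(nope = 1L)),
               "unknown matrix")
  raw <- simple_evidence(block_matrix(blocks), name = "raw")
  expect_error(combine_evidence(list(raw = raw), c(raw = 1L)), "normalized")
})

test_that("evaluating a block-structured combination attains the MI closed form", {
  blocks <- rep(1:2, each = 4)
  m <- norm_block(blocks, "informative")
  msa <- make_msa(rep(c("A", "C"), each = 4), ids = paste0("p", 1:8))
  out <- evaluate_combination(c(informative = 1L), list(informative = m),
                              msa, k = 2, seed = 1)
  expect_equal(out$fitness, log(2))
  # scaling all coefficients leaves the assignment unchanged
  out3 <- evaluate_combination(c(informative = 3L), list(informative = m),
                               msa, k = 2, seed = 1)
  expect_equal(out3$assignment$cluster, out$assignment$cluster)
  expect_equal(out3$fitness, out$fitness)
  # determinism
  out_b <- evaluate_combination(c(informative = 1L), list(informative = m),
                                msa, k = 2, seed = 1)
  expect_identical(out_b$assignment, out$assignment)
})

make_gp_problem <- function(n = 24, seed = 2) {
  blocks <- rep(1:2, each = n / 2)
  mats <- list(
    informative1 = norm_block(blocks, "informative1", sd = 0.05, seed = seed),
    noise1 = normalize_evidence(simple_evidence(
      isofam:::with_seed(seed + 1, isofam:::symmetrize_noise(n, 1)) |>
        (\(z) { dimnames(z) <- rep(list(paste0("p", 1:n)), 2); z })(),
      name = "noise1")),
    noise2 = normalize_evidence(simple_evidence(
      isofam:::with_seed(seed + 2, isofam:::symmetrize_noise(n, 1)) |>
        (\(z) { dimnames(z) <- rep(list(paste0("p", 1:n)), 2); z })(),
      name = "noise2"))
  )
  msa <- make_msa(rep(c("AK", "CD"), each = n / 2), ids = paste0("p", 1:n))
  list(mats = mats, msa = msa)
}

test_that("evolution is elitist, reproducible and finds the informative matrix", {
  prob <- make_gp_problem()
  cfg <- gp_config(population = 16, generations = 8, seed = 11)
  fit <- evolve_combination(prob$mats, prob$msa, 2, cfg)
  # elitism: per-generation best fitness non-decreasing
  expect_true(all(diff(fit$history$best_fitness) >= -1e-12))
  expect_gte(fit$fitness, fit$history$best_fitness[1])
  # the planted informative matrix carries the signal
  expect_true("informative1" %in% names(fit$coefficients))
  # full reproducibility
  fit2 <- evolve_combination(prob$mats, prob$msa, 2, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$assignment, fit2$assignment)
})

test_that("a single available matrix yields a single-term individual", {
  prob <- make_gp_problem()
  fit <- evolve_combination(prob$mats["informative1"], prob$msa, 2,
                            gp_config(population = 8, generations = 3, seed = 2))
  expect_equal(names(fit$coefficients), "informative1")
})

test_that("tidy and glance summarise a GP fit", {
  prob <- make_gp_problem()
  fit <- evolve_combination(prob$mats, prob$msa, 2,
                            gp_config(population = 8, generations = 3, seed = 5))
  td <- tidy(fit)
  expect_true(all(c("term", "coefficient") %in% names(td)))
  expect_true(all(td$coefficient >= 1))
  gl <- glance(fit)
  expect_equal(gl$fitness, fit$fitness)
  expect_equal(gl$equation, fit$equation)
})

test_that("configuration invariants are enforced", {
  expect_error(gp_config(p_crossover = 0.5, p_mutation = 0.1,
                         p_reproduction = 0.1), "sum to 1")
  expect_error(gp_config(population = 1), "population")
})
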