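# ---- addition-tree genome ---------------------------------------------------
# Individuals are addition-only expression trees whose leaves are evidence
# matrix names; a matrix's integer coefficient is its leaf multiplicity.
# This reproduces printed equation forms (e.g. "2ASid + ASscr + seqAliG")
# without a separate constant mechanism.

gp_leaf <- function(name) list(type = "leaf", name = name)
gp_node <- function(l, r) list(type = "node", l = l, r = r)

random_tree <- function(names, max_depth, p_leaf = 0.3) {
  if (max_depth <= 1 || runif(1) < p_leaf) {
    gp_leaf(sample(names, 1))
  } else {
    gp_node(random_tree(names, max_depth - 1, p_leaf),
            random_tree(names, max_depth - 1, p_leaf))
  }
}

tree_depth <- function(tree) {
  if (tree$type == "leaf") 1L else 1L + max(tree_depth(tree$l), tree_depth(tree$r))
}

tree_leaves <- function(tree) {
  if (tree$type == "leaf") tree$name else c(tree_leaves(tree$l), tree_leaves(tree$r))
}

#' Integer coefficients of an addition-tree individual
#'
#' @param individual A GP individual (as found in the `best` element of an
#'   [evolve_combination()] fit) or a raw addition tree.
#' @return Named integer vector of leaf multiplicities.
#' @export
tree_coefficients <- function(individual) {
  tree <- individual$tree %||% individual
  leaves <- tree_leaves(tree)
  tab <- table(leaves)
  setNames(as.integer(tab), names(tab))
}

# All subtree positions as integer paths ("" root; 1 = left, 2 = right).
tree_paths <- function(tree, path = integer()) {
  if (tree$type == "leaf") return(list(path))
  c(list(path),
    tree_paths(tree$l, c(path, 1L)),
    tree_paths(tree$r, c(path, 2L)))
}

get_subtree <- function(tree, path) {
  for (step in path) tree <- if (step == 1L) tree$l else tree$r
  tree
}

set_subtree <- function(tree, path, sub) {
  if (length(path) == 0) return(sub)
  if (path[1] == 1L) tree$l <- set_subtree(tree$l, path[-1], sub)
  else tree$r <- set_subtree(tree$r, path[-1], sub)
  tree
}

#' Subtree crossover of two addition-tree individuals
#'
#' Randomly selects one subtree in each parent and switches them.
#' Offspring exceeding the depth bound are rejected and the parents
#' returned unchanged (cloned).
#'
#' @param a,b Addition trees (or individuals with a `tree` element).
#' @param max_depth Depth bound for offspring.
#' @return List of two trees.
#' @export
crossover_trees <- function(a, b, max_depth = 6) {
  a <- a$tree %||% a; b <- b$tree %||% b
  pa <- tree_paths(a); pb <- tree_paths(b)
  cut_a <- pa[[sample.int(length(pa), 1)]]
  cut_b <- pb[[sample.int(length(pb), 1)]]
  sub_a <- get_subtree(a, cut_a); sub_b <- get_subtree(b, cut_b)
  child1 <- set_subtree(a, cut_a, sub_b)
  child2 <- set_subtree(b, cut_b, sub_a)
  if (tree_depth(child1) > max_depth || tree_depth(child2) > max_depth) {
    list(a, b)
  } else {
    list(child1, child2)
  }
}

#' Subtree mutation of an addition-tree individual
#'
#' Replaces a random subtree with a freshly grown random addition tree
#' over the matrix-name alphabet, within the depth bound.
#'
#' @param a Addition tree (or individual with a `tree` element).
#' @param names Matrix-name alphabet.
#' @param max_depth Depth bound for the result.
#' @return The mutated tree.
#' @export
mutate_tree <- function(a, names, max_depth = 6) {
  a <- a$tree %||% a
  paths <- tree_paths(a)
  cut <- paths[[sample.int(length(paths), 1)]]
  budget <- max(1L, max_depth - length(cut))
  set_subtree(a, cut, random_tree(names, min(budget, 3L)))
}

# ---- configuration ----------------------------------------------------------

#' Genetic-programming run configuration
#'
#' Defaults: population 50, 30 generations, crossover/mutation/
#' reproduction rates 0.8/0.1/0.1 (mutually exclusive), tournament size 3,
#' maximum tree depth 6, one elite.  One clustering seed is used per run
#' so selection compares individuals, not K-means draws.
#'
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param p_crossover,p_mutation,p_reproduction Operator rates (sum to 1).
#' @param tournament Tournament size for selection.
#' @param max_depth Maximum addition-tree depth.
#' @param elites Number of elite individuals copied unchanged.
#' @param seed Root seed for the whole run.
#' @return List of class `gp_config`.
#' @export
gp_config <- function(population = 50, generations = 30,
                      p_crossover = 0.8, p_mutation = 0.1,
                      p_reproduction = 0.1, tournament = 3,
                      max_depth = 6, elites = 1, seed = 1L) {
  rates <- c(p_crossover, p_mutation, p_reproduction)
  if (abs(sum(rates) - 1) > 1e-8) abort("operator rates must sum to 1")
  if (population < 2) abort("population must be at least 2")
  structure(list(population = population, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 p_reproduction = p_reproduction, tournament = tournament,
                 max_depth = max_depth, elites = elites,
                 seed = as.integer(seed)),
            class = "gp_config")
}

# ---- evaluation -------------------------------------------------------------

#' Combine evidence matrices with integer coefficients
#'
#' Entrywise weighted sum `s = sum coeff_m * matrix_m` over normalized
#' evidence matrices.
#'
#' @param matrices Named list of normalized `evidence_matrix` objects.
#' @param coefficients Named non-negative integer vector; names must be a
#'   subset of `names(matrices)` and at least one coefficient positive.
#' @return The combined symmetric similarity matrix.
#' @export
combine_evidence <- function(matrices, coefficients) {
  unknown <- setdiff(names(coefficients), names(matrices))
  if (length(unknown) > 0) {
    abort(sprintf("coefficient for unknown matrix name(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  coefficients <- coefficients[coefficients > 0]
  if (length(coefficients) == 0) abort("at least one positive coefficient required")
  not_norm <- names(coefficients)[!vapply(matrices[names(coefficients)],
                                          function(m) m$normalized, TRUE)]
  if (length(not_norm) > 0) {
    abort(sprintf("matrices must be normalized before combination: %s",
                  paste(not_norm, collapse = ", ")))
  }
  Reduce(`+`, Map(function(nm, co) co * matrices[[nm]]$values,
                  names(coefficients), coefficients))
}

#' Evaluate one evidence combination
#'
#' Applies the combination to every protein pair, spectrally clusters the
#' resulting similarity matrix and returns the clustering's active-site
#' MI as fitness.
#'
#' @param coefficients Named integer coefficient vector (or an individual
#'   with a `tree`).
#' @param matrices Named list of normalized `evidence_matrix` objects.
#' @param msa A [site_alignment()].
#' @param k Number of clusters.
#' @param seed Clustering seed.
#' @return List with `fitness`, `assignment` (tibble) and `mi_report`.
#' @export
evaluate_combination <- function(coefficients, matrices, msa, k, seed = 1L) {
  if (is.list(coefficients)) coefficients <- tree_coefficients(coefficients)
  s <- combine_evidence(matrices, coefficients)
  assignment <- spectral_cluster(build_affinity(s), k, seed = seed)
  report <- overall_mi(msa, assignment)
  list(fitness = report$overall, assignment = assignment, mi_report = report)
}

# Tournament selection by fitness (returns an index).
tournament_pick <- function(fitness, size) {
  idx <- sample.int(length(fitness), size, replace = TRUE)
  idx[which.max(fitness[idx])]
}

#' Evolve an evidence combination maximizing clustering MI
#'
#' Genetic programming over addition-only trees of evidence-matrix names:
#' starting from random combinations, tournament selection with crossover,
#' mutation and reproduction (mutually exclusive, applied at the
#' configured rates) plus elitism searches for the combination whose
#' spectral clustering has maximal active-site mutual information.
#' Fitness evaluations are cached by coefficient vector (the clustering
#' seed is held fixed across individuals within a run).
#'
#' @param matrices Named list of normalized `evidence_matrix` objects.
#' @param msa A [site_alignment()].
#' @param k Number of clusters.
#' @param config A [gp_config()].
#' @return Object of class `isofam_gp`: list with `best` (individual),
#'   `coefficients`, `equation`, `fitness`, `assignment`, `mi_report`,
#'   `history` (tibble: generation, best/mean fitness, best equation) and
#'   `config`.
#' @export
evolve_combination <- function(matrices, msa, k, config = gp_config()) {
  if (length(matrices) == 0) abort("need at least one evidence matrix")
  alphabet <- names(matrices)
  cluster_seed <- derive_seed(config$seed, "cluster")
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(tree) {
    key <- paste(deparse(tree_coefficients(tree)), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- evaluate_combination(tree_coefficients(tree), matrices, msa, k,
                                seed = cluster_seed)$fitness
    cache[[key]] <- val
    val
  }
  run <- with_seed(derive_seed(config$seed, "evolve"), {
    pop <- replicate(config$population,
                     random_tree(alphabet, sample(2:config$max_depth, 1)),
                     simplify = FALSE)
    history <- list()
    for (gen in seq_len(config$generations + 1)) {
      fit <- vapply(pop, fitness_of, 0)
      best_i <- which.max(fit)
      history[[gen]] <- tibble(
        generation = gen - 1L, best_fitness = max(fit),
        mean_fitness = mean(fit),
        best_equation = render_equation(tree_coefficients(pop[[best_i]])))
      if (gen > config$generations) break
      elite_order <- order(-fit)
      next_pop <- pop[elite_order[seq_len(config$elites)]]
      while (length(next_pop) < config$population) {
        op <- sample(c("cx", "mut", "rep"), 1,
                     prob = c(config$p_crossover, config$p_mutation,
                              config$p_reproduction))
        if (op == "cx") {
          p1 <- pop[[tournament_pick(fit, config$tournament)]]
          p2 <- pop[[tournament_pick(fit, config$tournament)]]
          kids <- crossover_trees(p1, p2, config$max_depth)
          next_pop <- c(next_pop, kids[seq_len(min(2, config$population -
                                                     length(next_pop)))])
        } else if (op == "mut") {
          p1 <- pop[[tournament_pick(fit, config$tournament)]]
          next_pop <- c(next_pop, list(mutate_tree(p1, alphabet,
                                                   config$max_depth)))
        } else {
          next_pop <- c(next_pop,
                        pop[tournament_pick(fit, config$tournament)])
        }
      }
      pop <- next_pop
    }
    list(pop = pop, fit = fit, history = dplyr::bind_rows(history))
  })
  best_i <- which.max(run$fit)
  best_tree <- run$pop[[best_i]]
  coef <- tree_coefficients(best_tree)
  eval <- evaluate_combination(coef, matrices, msa, k, seed = cluster_seed)
  structure(
    list(best = list(tree = best_tree), coefficients = coef,
         equation = render_equation(coef), fitness = eval$fitness,
         assignment = eval$assignment, mi_report = eval$mi_report,
         history = run$history, config = config, k = k,
         cluster_seed = cluster_seed, matrix_names = alphabet),
    class = "isofam_gp")
}

#' @export
print.isofam_gp <- function(x, ...) {
  cat(sprintf("<isofam_gp: %s  (MI = %.4f, k = %d)>\n",
              x$equation, x$fitness, x$k))
  invisible(x)
}

# ---- equation rendering -----------------------------------------------------

#' Render an integer coefficient vector as an integration equation
#'
#' Coefficient-prefixed matrix names joined by " + ", coefficient 1
#' omitted, terms sorted by name in the C locale (uppercase before
#' lowercase) -- the order in which published integration equations list
#' their terms, e.g. `"2ASid + ASscr + seqAliG"`.
#'
#' @param coefficients Named non-negative integer vector.
#' @return Equation text, e.g. `"2ASid + ASscr + seqAliG"`.
#' @export
render_equation <- function(coefficients) {
  coefficients <- coefficients[coefficients > 0]
  ordered <- sort(names(coefficients), method = "radix")
  terms <- vapply(ordered, function(nm) {
    co <- coefficients[[nm]]
    if (co == 1) nm else paste0(co, nm)
  }, "")
  paste(terms, collapse = " + ")
}

#' Parse an integration equation back to coefficients
#'
#' Inverse of [render_equation()].
#'
#' @param text Equation text.
#' @return Named integer coefficient vector.
#' @export
parse_equation <- function(text) {
  terms <- strsplit(text, "\\s*\\+\\s*")[[1]]
  m <- regmatches(terms, regexec("^([0-9]*)([A-Za-z][A-Za-z0-9_]*)$", terms))
  bad <- vapply(m, length, 0L) != 3
  if (any(bad)) abort(sprintf("cannot parse term(s): %s",
                              paste(terms[bad], collapse = ", ")))
  coef <- vapply(m, function(x) if (x[2] == "") 1L else as.integer(x[2]), 0L)
  setNames(coef, vapply(m, `[`, "", 3))
}
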