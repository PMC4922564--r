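#' Tidy a GP integration fit
#'
#' One row per evidence matrix with positive coefficient in the best
#' individual.
#'
#' @param x An `isofam_gp` fit.
#' @param ... Unused.
#' @return Tibble with columns `term`, `coefficient`.
#' @export
tidy.isofam_gp <- function(x, ...) {
  coef <- x$coefficients
  ordered <- sort(names(coef), method = "radix")
  tibble(term = ordered, coefficient = as.integer(coef[ordered]))
}

#' Glance at a GP integration fit
#'
#' @param x An `isofam_gp` fit.
#' @param ... Unused.
#' @return One-row tibble: `fitness`, `k`, `n_terms`, `generations`,
#'   `population`, `seed`, `equation`.
#' @export
glance.isofam_gp <- function(x, ...) {
  tibble(fitness = x$fitness, k = x$k,
         n_terms = length(x$coefficients),
         generations = x$config$generations,
         population = x$config$population,
         seed = x$config$seed, equation = x$equation)
}

#' Tidy an MI report
#'
#' @param x An [overall_mi()] report.
#' @param ... Unused.
#' @return The per-residue partial MI tibble (`position`, `cluster`,
#'   `residue`, `partial_mi`, `f`).
#' @export
tidy.mi_report <- function(x, ...) x$per_residue

#' Glance at an MI report
#'
#' @param x An [overall_mi()] report.
#' @param ... Unused.
#' @return One-row tibble: `mi`, `mi_unnormalized`, `positions`,
#'   `clusters`.
#' @export
glance.mi_report <- function(x, ...) {
  tibble(mi = x$overall, mi_unnormalized = x$unnormalized,
         positions = x$P, clusters = x$C)
}
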