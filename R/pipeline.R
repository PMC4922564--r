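#' End-to-end subfamily detection
#'
#' Orchestrates the full run: normalize the evidence matrices, optionally
#' choose the putative active site among candidate pockets, evolve an
#' evidence combination maximizing the clustering's active-site MI, and
#' assemble the report (assignment, equation, MI report, per-cluster
#' composition profiles, SDP ranking, provenance).  When `out_dir` is
#' given the artifacts are written there as TSV/JSON/text files.
#'
#' @param matrices Named list of `evidence_matrix` objects (normalized or
#'   raw; raw ones are normalized here).
#' @param msa A [site_alignment()] of the putative active site, or `NULL`
#'   when `pockets` is supplied.
#' @param k Number of clusters.
#' @param config A [gp_config()]; its seed drives all randomness.
#' @param pockets Optional pocket set; the putative active site is then
#'   selected by the conservation rule before scoring.
#' @param out_dir Optional output directory for artifacts.
#' @return Object of class `isofam_run`: list with `fit` (the
#'   [evolve_combination()] result), `assignment`, `equation`, `fitness`,
#'   `mi_report`, `profile`, `sdp_ranking`, `selected_pocket` and
#'   `provenance`.
#' @export
detect_subfamilies <- function(matrices, msa = NULL, k, config = gp_config(),
                               pockets = NULL, out_dir = NULL) {
  selected_pocket <- NA_character_
  if (is.null(msa)) {
    if (is.null(pockets)) abort("supply either msa or pockets")
    selected_pocket <- select_putative_active_site(pockets)
    msa <- pockets[[selected_pocket]]$msa
  }
  normalized <- lapply(matrices, function(m) {
    if (m$normalized) m else normalize_evidence(m)
  })
  fit <- evolve_combination(normalized, msa, k, config)
  profile <- cluster_profile(msa, fit$assignment)
  ranking <- rank_discriminative_residues(fit$mi_report)
  run <- structure(
    list(fit = fit, assignment = fit$assignment, equation = fit$equation,
         fitness = fit$fitness, mi_report = fit$mi_report,
         profile = profile, sdp_ranking = ranking,
         selected_pocket = selected_pocket,
         provenance = list(
           seed = config$seed, k = k, config = unclass(config),
           matrices = names(matrices),
           package_version = as.character(utils::packageVersion("isofam")))),
    class = "isofam_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.isofam_run <- function(x, ...) {
  cat(sprintf("<isofam_run: %s  (MI = %.4f, k = %d clusters)>\n",
              x$equation, x$fitness, x$provenance$k))
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$assignment, file.path(dir, "assignment.tsv"))
  writeLines(run$equation, file.path(dir, "equation.txt"))
  rep <- run$mi_report
  jsonlite::write_json(
    list(overall = rep$overall, unnormalized = rep$unnormalized,
         P = rep$P, C = rep$C,
         per_position = rep$per_position, per_residue = rep$per_residue),
    file.path(dir, "mi_report.json"), auto_unbox = TRUE, digits = NA)
  write_cluster_profiles(run$profile, file.path(dir, "profiles"))
  readr::write_tsv(run$sdp_ranking, file.path(dir, "sdp_ranking.tsv"))
  readr::write_tsv(run$fit$history, file.path(dir, "history.tsv"))
  jsonlite::write_json(run$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Validate a run against ground-truth labels
#'
#' @param run An `isofam_run` (or a cluster assignment tibble).
#' @param truth Tibble (`id`, `label`) or named label vector.
#' @return One-row tibble of the seven agreement measures (see
#'   [cluster_agreement()]).
#' @export
evaluate_run <- function(run, truth) {
  clusters <- if (inherits(run, "isofam_run")) run$assignment else run
  cluster_agreement(truth, clusters)
}
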