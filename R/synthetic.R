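#' Planted-subfamily benchmark specification
#'
#' Describes a synthetic protein family with known subfamily structure:
#' cluster sizes, active-site composition (specificity determining
#' positions with distinct dominant residues per subfamily, family-wide
#' conserved positions, and uniform-random positions), residue noise and
#' gap rates, and a plan of evidence matrices (informative two-level
#' block matrices, redundant correlated copies, pure-noise matrices,
#' optionally with missing pairs).
#'
#' Defaults describe a comfortable recovery regime: 60 proteins in 3
#' equal subfamilies, 10 active-site positions (3 SDP + 4 conserved + 3
#' random), 5% SDP residue noise, 2% gaps, one informative matrix
#' (within-block mean 0.9, between 0.1, Gaussian noise sd 0.05) plus two
#' noise matrices.
#'
#' @param n Number of proteins.
#' @param k Number of planted subfamilies.
#' @param sizes Integer subfamily sizes summing to `n` (default as equal
#'   as possible).
#' @param n_sdp,n_conserved,n_random Counts of position types (sum =
#'   alignment width).
#' @param sdp_noise Probability an SDP residue is flipped to a random
#'   residue.
#' @param gap_rate Per-cell gap probability.
#' @param evidence Tibble or data.frame with columns `name`, `role`
#'   (`"informative"`, `"redundant"`, `"noise"`), optional `rho`
#'   (redundant copies) and `missing` (masked pair fraction).
#' @param within_mean,between_mean Block means of informative matrices.
#' @param noise_sd Gaussian noise sd added to informative/redundant
#'   matrices (noise matrices use sd 1).
#' @param seq_length Length of the full domain subsequences emitted for
#'   each protein.
#' @return List of class `synthetic_family_spec`.
#' @export
synthetic_family_spec <- function(n = 60, k = 3, sizes = NULL,
                                  n_sdp = 3, n_conserved = 4, n_random = 3,
                                  sdp_noise = 0.05, gap_rate = 0.02,
                                  evidence = tibble(
                                    name = c("informative1", "noise1", "noise2"),
                                    role = c("informative", "noise", "noise")),
                                  within_mean = 0.9, between_mean = 0.1,
                                  noise_sd = 0.05, seq_length = 80) {
  if (is.null(sizes)) {
    sizes <- rep(n %/% k, k)
    sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  }
  if (sum(sizes) != n) abort("subfamily sizes must sum to n")
  if (k > 20) abort("cannot plant more than 20 distinct dominant residues")
  stopifnot(sdp_noise >= 0, sdp_noise <= 1, gap_rate >= 0, gap_rate <= 1)
  evidence <- as_tibble(evidence)
  if (!"rho" %in% names(evidence)) evidence$rho <- NA_real_
  if (!"missing" %in% names(evidence)) evidence$missing <- 0
  evidence$missing[is.na(evidence$missing)] <- 0
  structure(list(n = n, k = k, sizes = sizes, n_sdp = n_sdp,
                 n_conserved = n_conserved, n_random = n_random,
                 sdp_noise = sdp_noise, gap_rate = gap_rate,
                 evidence = evidence, within_mean = within_mean,
                 between_mean = between_mean, noise_sd = noise_sd,
                 seq_length = seq_length),
            class = "synthetic_family_spec")
}

symmetrize_noise <- function(n, sd) {
  z <- matrix(rnorm(n * n, sd = sd), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}

#' Generate a planted-subfamily benchmark family
#'
#' Draws, reproducibly from `seed`, a protein family with known subfamily
#' labels, an active-site alignment with planted SDPs (one dominant
#' residue per subfamily, distinct across subfamilies), an evidence
#' matrix set following the spec's plan, full-length sequences whose
#' composition drifts per subfamily, and per-protein scalar properties.
#'
#' @param spec A [synthetic_family_spec()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with elements `family` (tibble `id`, `sequence`, `label`),
#'   `msa` ([site_alignment()]), `matrices` (named list of unnormalized
#'   `evidence_matrix`), `properties` (tibble) and `spec`.
#' @export
generate_family <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  with_seed(seed, {
    n <- spec$n; k <- spec$k
    ids <- sprintf("prot%03d", seq_len(n))
    labels <- rep(paste0("sub", seq_len(k)), spec$sizes)
    block <- rep(seq_len(k), spec$sizes)

    # --- active-site alignment ---
    width <- spec$n_sdp + spec$n_conserved + spec$n_random
    cols <- matrix("", n, width)
    type <- rep(c("sdp", "conserved", "random"),
                c(spec$n_sdp, spec$n_conserved, spec$n_random))
    for (p in seq_len(width)) {
      if (type[p] == "sdp") {
        dominant <- sample(AA_ALPHABET, k)
        col <- dominant[block]
        flip <- runif(n) < spec$sdp_noise
        col[flip] <- sample(AA_ALPHABET, sum(flip), replace = TRUE)
      } else if (type[p] == "conserved") {
        col <- rep(sample(AA_ALPHABET, 1), n)
      } else {
        col <- sample(AA_ALPHABET, n, replace = TRUE)
      }
      gap <- runif(n) < spec$gap_rate
      col[gap] <- "-"
      cols[, p] <- col
    }
    msa <- site_alignment(setNames(apply(cols, 1, paste, collapse = ""), ids))

    # --- evidence matrices ---
    base_block <- spec$between_mean +
      (spec$within_mean - spec$between_mean) * outer(block, block, `==`)
    diag(base_block) <- 0
    matrices <- list()
    informative_store <- list()
    for (r in seq_len(nrow(spec$evidence))) {
      nm <- spec$evidence$name[r]
      role <- spec$evidence$role[r]
      if (role == "informative") {
        v <- base_block + symmetrize_noise(n, spec$noise_sd)
        informative_store[[length(informative_store) + 1]] <- v
      } else if (role == "redundant") {
        if (length(informative_store) == 0) {
          abort("redundant matrix requires a preceding informative matrix")
        }
        rho <- spec$evidence$rho[r]
        if (is.na(rho)) rho <- 0.8
        src <- informative_store[[length(informative_store)]]
        amp <- stats::sd(upper_tri_values(src))
        noise <- symmetrize_noise(n, amp)
        v <- rho * src + sqrt(max(0, 1 - rho^2)) * noise
      } else {
        v <- symmetrize_noise(n, 1)
      }
      dimnames(v) <- list(ids, ids)
      frac <- spec$evidence$missing[r]
      if (frac > 0) {
        idx <- which(upper.tri(v), arr.ind = TRUE)
        drop <- idx[runif(nrow(idx)) < frac, , drop = FALSE]
        v[drop] <- NA
        v[drop[, 2:1, drop = FALSE]] <- NA
      }
      matrices[[nm]] <- evidence_matrix(v, name = nm,
                                        orientation = "similarity")
    }

    # --- sequences: subfamily-specific residue bias over a common core ---
    bias <- lapply(seq_len(k), function(j) {
      w <- rep(1, 20)
      w[sample.int(20, 4)] <- 3
      w / sum(w)
    })
    sequences <- vapply(seq_len(n), function(i) {
      paste(sample(AA_ALPHABET, spec$seq_length, replace = TRUE,
                   prob = bias[[block[i]]]), collapse = "")
    }, "")

    family <- protein_family(ids, sequence = sequences, label = labels)

    # --- scalar properties with overlapping per-subfamily distributions ---
    centers <- seq_len(k)
    properties <- tibble(
      id = ids,
      iso_point = rnorm(n, mean = 6 + centers[block], sd = 0.5),
      instability = rnorm(n, mean = 35 + 5 * centers[block], sd = 3)
    )
    list(family = family, msa = msa, matrices = matrices,
         properties = properties, spec = spec)
  })
}

#' Generate a candidate pocket set with a designated active site
#'
#' Builds `n_pockets` candidate pocket alignments for the synthetic
#' family: the designated pocket satisfies the conservation rule (at
#' least 3 positions conserved in at least half the family) while the
#' others are uniform-random and fail it.
#'
#' @param spec A [synthetic_family_spec()].
#' @param n_pockets Number of candidate pockets.
#' @param which_is_site Index of the designated true-site pocket.
#' @param scores Optional numeric vector of pocket scores (default gives
#'   the designated pocket the top score).
#' @param seed Integer seed.
#' @return Named list of pockets (`msa`, `score`) as consumed by
#'   [select_putative_active_site()].
#' @export
generate_pockets <- function(spec, n_pockets = 3, which_is_site = 1,
                             scores = NULL, seed = 1L) {
  if (which_is_site < 1 || which_is_site > n_pockets) {
    abort("which_is_site out of range")
  }
  site <- generate_family(spec, seed = derive_seed(seed, "site"))$msa
  with_seed(derive_seed(seed, "pockets"), {
    n <- spec$n
    ids <- names(site)
    if (is.null(scores)) {
      scores <- runif(n_pockets, 1, 10)
      scores[which_is_site] <- max(scores) + 1
    }
    pockets <- lapply(seq_len(n_pockets), function(p) {
      if (p == which_is_site) {
        msa <- site
      } else {
        w <- attr(site, "width")
        rows <- vapply(seq_len(n), function(i) {
          paste(sample(AA_ALPHABET, w, replace = TRUE), collapse = "")
        }, "")
        msa <- site_alignment(setNames(rows, ids))
      }
      list(msa = msa, score = scores[p])
    })
    setNames(pockets, sprintf("pocket%02d", seq_len(n_pockets)))
  })
}

#' Write a synthetic benchmark to loader-compatible files
#'
#' Emits the same formats the loaders read: family FASTA, label TSV,
#' active-site aligned FASTA, one pair TSV (+ JSON sidecar) per evidence
#' matrix, and the property TSV.
#'
#' @param data Result of [generate_family()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_family <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_family(data$family, file.path(dir, "family.fasta"))
  readr::write_tsv(data$family[, c("id", "label")], file.path(dir, "labels.tsv"))
  write_site_alignment(data$msa, file.path(dir, "active_site.fasta"))
  for (m in data$matrices) {
    write_evidence(m, file.path(dir, paste0(m$name, ".tsv")))
  }
  readr::write_tsv(data$properties, file.path(dir, "properties.tsv"))
  invisible(dir)
}
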