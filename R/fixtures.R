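# Synthetic rigid-body fixtures: toy complexes, decoy ensembles with a
# controllable quality spectrum, and planted linear energy models. These
# exercise the full pipeline (parse -> type -> featurize -> train ->
# evaluate) without any external data; each pseudo-atom is its own residue
# so residue-level contact metrics remain meaningful.

#' Fixture specification
#'
#' @param n_atoms atoms per partner.
#' @param n_types pseudo-atom types (a [toy_typing_table()] of this size is
#'   attached).
#' @param n_decoys decoys per complex.
#' @param min_sep minimum intra-partner atom separation (Angstrom).
#' @param contact_gap target receptor-ligand gap at the native interface
#'   (Angstrom); the native pose keeps all cross distances above 2 A and at
#'   least 3 residue contacts at 5 A.
#' @param tiers named list of rigid-body perturbation tiers, each
#'   `c(translation A, rotation degrees)`; magnitude 0 reproduces the
#'   native pose exactly.
#' @param tier_fractions decoy fractions per tier (recycled/normalized).
#' @param max_tries bounded retries for clash-free placement / class
#'   coverage.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_atoms = 30L, n_types = 4L, n_decoys = 100L,
                         min_sep = 2.0, contact_gap = 3.5,
                         tiers = list(high = c(0.2, 2),
                                      medium = c(0.8, 6),
                                      acceptable = c(2.0, 12),
                                      incorrect = c(15, 180)),
                         tier_fractions = c(0.10, 0.15, 0.25, 0.50),
                         max_tries = 200L) {
  stopifnot(n_atoms >= 4L, n_types >= 1L, n_decoys >= 1L)
  structure(list(n_atoms = as.integer(n_atoms), n_types = as.integer(n_types),
                 n_decoys = as.integer(n_decoys), min_sep = min_sep,
                 contact_gap = contact_gap, tiers = tiers,
                 tier_fractions = rep_len(tier_fractions, length(tiers)) /
                   sum(rep_len(tier_fractions, length(tiers))),
                 max_tries = as.integer(max_tries)),
            class = "fixture_spec")
}

# Sequentially place n points with pairwise separation >= min_sep inside a
# ball whose radius scales with n^(1/3).
random_cluster <- function(n, min_sep, max_tries) {
  radius <- max(4, 1.3 * min_sep * n^(1 / 3))
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- 0
  for (i in 2:n) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- runif(3, -radius, radius)
      if (sum(cand^2) > radius^2) next
      if (min(sqrt(colSums((t(pts[seq_len(i - 1), , drop = FALSE]) - cand)^2))) >=
          min_sep) {
        pts[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("generation error: could not place clash-free atom ", i)
  }
  pts
}

random_rotation_matrix <- function(max_angle_deg) {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- runif(1, 0, max_angle_deg) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

partner_df <- function(xyz, types, chain) {
  n <- nrow(xyz)
  data.frame(chain = chain, resno = seq_len(n), insert = "",
             resid = "PSD", elety = paste0("X", types),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = "X", stringsAsFactors = FALSE)
}

#' Generate a toy rigid-body complex
#'
#' Two clash-free clusters of typed pseudo-atoms docked along a random
#' direction so the native interface has at least 3 residue contacts at
#' 5 Angstrom and no cross distance below 2 Angstrom. Every atom is its own
#' residue; both partners cover all pseudo-atom types when
#' `n_atoms >= n_types`.
#'
#' @param spec a [fixture_spec()].
#' @return A typed [typed_structure()] (toy table attached).
#' @export
make_toy_complex <- function(spec = fixture_spec()) {
  table <- toy_typing_table(spec$n_types)
  rec_xyz <- random_cluster(spec$n_atoms, spec$min_sep, spec$max_tries)
  lig_xyz <- random_cluster(spec$n_atoms, spec$min_sep, spec$max_tries)
  # types: guarantee coverage of all types on each partner, rest random
  draw_types <- function(n)
    c(seq_len(spec$n_types) - 1L,
      sample.int(spec$n_types, max(0L, n - spec$n_types),
                 replace = TRUE) - 1L)[seq_len(n)]
  rec_t <- draw_types(spec$n_atoms)
  lig_t <- draw_types(spec$n_atoms)
  lig0 <- sweep(lig_xyz, 2, colMeans(lig_xyz))
  # scan approach directions; along each, slide the ligand in from a
  # generous gap while clash-free (no cross distance below 2 A). Prefer
  # interfaces with >= 6 contacts (finer Fnat granularity for the quality
  # spectrum); fall back to the best clash-free pose with >= 3 contacts.
  best <- NULL; best_contacts <- 0L
  for (try in seq_len(spec$max_tries)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    rec_ext <- max(rec_xyz %*% dir)
    base <- rec_ext - min(lig0 %*% dir)
    for (gap in seq(min(spec$contact_gap, 4.5), 2.0, by = -0.1)) {
      lig_try <- sweep(lig0, 2, (base + gap) * dir, "+")
      d <- cross_dist(rec_xyz, lig_try)
      if (min(d) < 2.0) break # clash; this direction won't improve
      nc <- sum(d < 5)
      if (nc > best_contacts) {
        best <- lig_try; best_contacts <- nc
      }
    }
    if (best_contacts >= 6L) break
  }
  if (best_contacts >= 3L) {
    s <- typed_structure(partner_df(rec_xyz, rec_t, "A"),
                         partner_df(best, lig_t, "B"))
    return(assign_atom_types(s, table))
  }
  stop("generation error: no clash-free interface with >= 3 contacts")
}

# One rigid-body perturbation of the ligand: rotation about its centroid by
# up to rot_deg, then translation of length drawn in [0.5, 1] * trans.
perturb_ligand <- function(native, trans, rot_deg) {
  lig <- structure_coords(native, "ligand")
  ctr <- colMeans(lig)
  R <- random_rotation_matrix(rot_deg)
  shift_dir <- rnorm(3); shift_dir <- shift_dir / sqrt(sum(shift_dir^2))
  mag <- if (trans > 0) runif(1, 0.5, 1) * trans else 0
  new_lig <- sweep(sweep(lig, 2, ctr) %*% R, 2, ctr + mag * shift_dir, "+")
  out <- native
  out$ligand[, c("x", "y", "z")] <- new_lig
  out
}

#' Generate a decoy ensemble spanning the CAPRI quality spectrum
#'
#' Rigid-body ligand perturbations drawn from the spec's magnitude tiers.
#' With `ensure_classes = TRUE` the set is verified (via the quality
#' module) to contain at least one decoy in every star class `{0,1,2,3}`,
#' drawing replacement decoys from class-matched magnitudes as needed.
#'
#' @param native a typed [typed_structure()] from [make_toy_complex()].
#' @param spec a [fixture_spec()].
#' @param ensure_classes verify star-class coverage (default `TRUE`).
#' @return List with `decoys` (list of typed structures), `tier` (character
#'   per decoy) and, when `ensure_classes`, `records` (the
#'   [assess_decoys()] table).
#' @export
make_decoy_set <- function(native, spec = fixture_spec(),
                           ensure_classes = TRUE) {
  tiers <- spec$tiers
  counts <- diff(round(cumsum(c(0, spec$tier_fractions)) * spec$n_decoys))
  counts[length(counts)] <- spec$n_decoys - sum(counts[-length(counts)])
  tier_of <- rep(names(tiers), counts)
  decoys <- lapply(tier_of, function(tn)
    perturb_ligand(native, tiers[[tn]][1], tiers[[tn]][2]))
  names(decoys) <- sprintf("decoy%04d", seq_along(decoys))
  if (!ensure_classes)
    return(list(decoys = decoys, tier = tier_of))
  records <- assess_decoys(decoys, native)
  # translation/rotation ranges aimed at each star class, used when the
  # tiered draw left a class unpopulated
  class_mag <- list(`3` = list(t = c(0.05, 0.5), r = c(0.5, 4)),
                    `2` = list(t = c(0.2, 1.6), r = c(1, 8)),
                    `1` = list(t = c(0.8, 4.0), r = c(2, 16)),
                    `0` = list(t = c(8, 40), r = c(30, 180)))
  tries <- 0L
  while (length(missing <- setdiff(0:3, unique(records$stars))) > 0L) {
    tries <- tries + 1L
    if (tries > 4L * spec$max_tries)
      stop("generation error: star class ", missing[1],
           " unreachable under this spec")
    m <- class_mag[[as.character(sample(missing, 1))]]
    cand <- perturb_ligand(native, runif(1, m$t[1], m$t[2]),
                           runif(1, m$r[1], m$r[2]))
    rec <- assess_decoys(list(cand), native)
    if (rec$stars %in% missing) {
      # install the candidate in place of a decoy of the most abundant class
      rich <- as.integer(names(which.max(table(records$stars))))
      slot <- which(records$stars == rich)[1L]
      decoys[[slot]] <- cand
      records[slot, ] <- rec
      tier_of[slot] <- paste0("class", rec$stars)
    }
  }
  list(decoys = decoys, tier = tier_of, records = records)
}

#' Planted-potential energies for a decoy ensemble
#'
#' Ground-truth energies `E = planted . features + N(0, noise_sd)` used to
#' validate parameter recovery by both trainers.
#'
#' @param grid a `feature_grid`.
#' @param planted a compatible [parameter_vector()].
#' @param noise_sd Gaussian noise standard deviation (0 gives energies
#'   exactly linear in the features).
#' @return Numeric energy per decoy.
#' @export
planted_potential_energies <- function(grid, planted, noise_sd = 0) {
  e <- score_decoys(grid, planted)
  if (noise_sd > 0) e <- e + rnorm(length(e), 0, noise_sd)
  e
}

#' A complete planted-potential benchmark
#'
#' Generates `n_complexes` toy complexes with decoy ensembles, featurizes
#' them under `form`, draws (or accepts) a planted parameter vector, and
#' computes planted energies. Decoys in the best `good_fraction` of each
#' complex by planted energy are flagged "planted-good" and receive uniform
#' normalized training weights, standing in for near-native quality
#' weights.
#'
#' @param n_complexes number of complexes.
#' @param spec a [fixture_spec()] (quality-class coverage is not enforced
#'   here; the planted energies define goodness).
#' @param form a [potential_form()].
#' @param planted optional [parameter_vector()]; by default values are
#'   drawn once from `Uniform(-3, 3)` per feature column.
#' @param noise_sd energy noise (default 0.05).
#' @param good_fraction fraction of decoys flagged planted-good (default
#'   0.1).
#' @param seed RNG seed; generation is fully reproducible.
#' @return List of class `planted_benchmark`: `grids`, `energies`, `good`
#'   (logical per decoy), `weights` (normalized per complex), `planted`,
#'   `natives`, `spec`, `seed`.
#' @export
make_planted_benchmark <- function(n_complexes = 10L, spec = fixture_spec(),
                                   form = potential_form("step",
                                                         bin_edges = c(0, 4, 6)),
                                   planted = NULL, noise_sd = 0.05,
                                   good_fraction = 0.1, seed = 1L) {
  set.seed(seed)
  table <- toy_typing_table(spec$n_types)
  nf <- n_features(form, table)
  if (is.null(planted)) {
    planted <- if (form$kind == "vdw") {
      P <- n_pair_types(spec$n_types)
      vdw_from_sigma_eps(form, sigma = runif(P, 2.5, 4.5),
                         epsilon = runif(P, 0, 5),
                         n_types = spec$n_types, table_hash = table$hash)
    } else {
      parameter_vector(form, values = runif(nf, -3, 3),
                       n_types = spec$n_types, table_hash = table$hash)
    }
  }
  natives <- vector("list", n_complexes)
  grids <- vector("list", n_complexes)
  energies <- vector("list", n_complexes)
  good <- vector("list", n_complexes)
  weights <- vector("list", n_complexes)
  for (i in seq_len(n_complexes)) {
    natives[[i]] <- make_toy_complex(spec)
    ds <- make_decoy_set(natives[[i]], spec, ensure_classes = FALSE)
    grids[[i]] <- build_feature_grid(ds$decoys, form,
                                     complex_id = sprintf("cplx%02d", i))
    e <- planted_potential_energies(grids[[i]], planted, noise_sd)
    energies[[i]] <- e
    n_good <- max(1L, round(good_fraction * length(e)))
    g <- rank_decoys(e) <= n_good
    good[[i]] <- g
    weights[[i]] <- as.numeric(g) / sum(g)
  }
  structure(list(grids = grids, energies = energies, good = good,
                 weights = weights, planted = planted, natives = natives,
                 spec = spec, seed = seed),
            class = "planted_benchmark")
}
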