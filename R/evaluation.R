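#' Top-N success for one complex
#'
#' @param ranks integer ranks (a permutation of `1..n`, see
#'   [rank_decoys()]).
#' @param good logical flag per decoy (e.g. `stars >= 1`, or the inserted
#'   native).
#' @param n_top N.
#' @return `TRUE` iff any flagged decoy has rank `<= n_top`.
#' @export
topn_success <- function(ranks, good, n_top) {
  stopifnot(length(ranks) == length(good),
            identical(sort(as.integer(ranks)), seq_along(ranks)))
  any(good & ranks <= n_top)
}

#' Enrichment fraction for one complex
#'
#' Fraction of all near-native decoys captured in the best-scored
#' `percentile` of the set; the slice holds `ceiling(percentile * n)`
#' decoys (at least 1).
#'
#' @param ranks integer ranks.
#' @param good logical near-native flags.
#' @param percentile top slice as a fraction (e.g. 0.01 for the top 1
#'   percent).
#' @return Fraction in `[0, 1]`, or `NA` when the complex has no
#'   near-native decoys (such complexes are excluded from enrichment
#'   averages).
#' @export
enrichment_fraction <- function(ranks, good, percentile) {
  stopifnot(length(ranks) == length(good), percentile > 0, percentile <= 1)
  m <- sum(good)
  if (m == 0L) return(NA_real_)
  top <- max(1L, ceiling(percentile * length(ranks)))
  sum(good & ranks <= top) / m
}

#' Insert the native complex into a feature grid
#'
#' Appends the native's feature row (typed with the same table) and flags
#' it, so assessments can include or exclude the artificial
#' native-identification problem. The appended row equals featurizing the
#' native directly.
#'
#' @param grid a `feature_grid`.
#' @param native a typed [typed_structure()].
#' @return The augmented grid (`native` flag `TRUE` on the new row).
#' @export
insert_native <- function(grid, native) {
  if (!identical(native$table_hash, grid$table_hash))
    stop("compatibility error: native typed with a different table")
  grid_append(grid, setNames(list(native), "native"), native = TRUE)
}

#' Per-class scoring contribution of one parameter
#'
#' `p = sigma_AB * nc_class / nc_tot`: the parameter value weighted by how
#' much of the feature's overall occurrence falls in a decoy class
#' (native, near-native, incorrect). Defined as 0 when `nc_tot = 0`.
#'
#' @param sigma_ab parameter value(s).
#' @param nc_class mean feature value over the class.
#' @param nc_tot mean feature value over all decoys.
#' @return Contribution(s) `p`.
#' @export
class_contribution <- function(sigma_ab, nc_class, nc_tot) {
  ifelse(nc_tot > 0, sigma_ab * nc_class / nc_tot, 0)
}

#' Discriminating contribution of one parameter
#'
#' The absolute form `dp = sigma_AB * |nc_near_native - nc_incorrect| /
#' nc_tot` together with the signed difference
#' `p_incorrect - p_near_native`, which is what ranking plots display.
#' False-positive / false-negative flags mark parameters whose sign
#' contradicts the mean-count ordering: positive parameters whose feature
#' is more frequent in near-natives (false positive) and negative
#' parameters whose feature is more frequent in incorrect decoys (false
#' negative).
#'
#' @param sigma_ab parameter value(s).
#' @param nc_nearnat,nc_incorrect,nc_tot mean feature values over
#'   near-native, incorrect and all decoys.
#' @return data.frame with `dp_abs`, `dp_signed`, `false_positive`,
#'   `false_negative`.
#' @export
discriminating_contribution <- function(sigma_ab, nc_nearnat, nc_incorrect,
                                        nc_tot) {
  p_nn <- class_contribution(sigma_ab, nc_nearnat, nc_tot)
  p_inc <- class_contribution(sigma_ab, nc_incorrect, nc_tot)
  data.frame(
    dp_abs = ifelse(nc_tot > 0,
                    sigma_ab * abs(nc_nearnat - nc_incorrect) / nc_tot, 0),
    dp_signed = p_inc - p_nn,
    false_positive = sigma_ab > 0 & nc_nearnat > nc_incorrect,
    false_negative = sigma_ab < 0 & nc_incorrect > nc_nearnat)
}

#' Per-parameter contribution report across an ensemble
#'
#' Computes mean feature values over native, near-native and incorrect
#' decoys (pooled across complexes) and the resulting class and
#' discriminating contributions for every parameter of a potential.
#'
#' @param grids list of `feature_grid`s.
#' @param classes list of integer star classes per decoy (native rows may
#'   instead be flagged in the grid's `native` field).
#' @param p a compatible [parameter_vector()].
#' @return data.frame, one row per parameter column, with the layout
#'   columns, `sigma`, `nc_nat`, `nc_nearnat`, `nc_incorrect`, `nc_tot`,
#'   `p_nat`, `p_nearnat`, `p_incorrect`, `dp_abs`, `dp_signed` and flags.
#' @export
contribution_report <- function(grids, classes, p) {
  stopifnot(length(grids) == length(classes))
  feats <- do.call(rbind, lapply(grids, `[[`, "features"))
  native <- unlist(lapply(grids, `[[`, "native"), use.names = FALSE)
  stars <- unlist(classes, use.names = FALSE)
  stopifnot(length(stars) == nrow(feats))
  w <- check_grid_param(grids[[1L]], p)
  nearnat <- !native & stars >= 1L
  incorrect <- !native & stars == 0L
  col_mean <- function(sel) {
    if (!any(sel)) return(rep(0, ncol(feats)))
    colMeans(feats[sel, , drop = FALSE])
  }
  nc_nat <- col_mean(native)
  nc_nn <- col_mean(nearnat)
  nc_inc <- col_mean(incorrect)
  nc_tot <- colMeans(feats)
  dp <- discriminating_contribution(w, nc_nn, nc_inc, nc_tot)
  cbind(grids[[1L]]$layout,
        data.frame(sigma = w, nc_nat = nc_nat, nc_nearnat = nc_nn,
                   nc_incorrect = nc_inc, nc_tot = nc_tot,
                   p_nat = class_contribution(w, nc_nat, nc_tot),
                   p_nearnat = class_contribution(w, nc_nn, nc_tot),
                   p_incorrect = class_contribution(w, nc_inc, nc_tot)),
        dp)
}

#' Evaluate a scoring across complexes
#'
#' The three standard assessments for a set of scored decoy ensembles:
#' per-complex best rank of a flagged (near-native or native) decoy,
#' success fractions at several top-N cutoffs, and mean enrichment
#' fractions at several percentiles (complexes without any flagged decoy
#' are excluded from enrichment averages but count as failures in success
#' rates).
#'
#' @param ranks_list list of integer rank vectors, one per complex.
#' @param good_list list of logical flags per complex.
#' @param top_ns top-N cutoffs.
#' @param percentiles enrichment percentiles (fractions).
#' @return List of class `evaluation_report`: `best_rank` (per complex,
#'   `NA` if no flagged decoy), `success` (named fraction per cutoff),
#'   `enrichment` (named mean fraction per percentile), `n_complexes`.
#' @export
evaluation_report <- function(ranks_list, good_list,
                              top_ns = c(1, 10, 100, 500, 1000),
                              percentiles = c(0.001, 0.01, 0.02, 0.05)) {
  stopifnot(length(ranks_list) == length(good_list))
  nc <- length(ranks_list)
  best_rank <- vapply(seq_len(nc), function(i) {
    g <- good_list[[i]]
    if (!any(g)) NA_real_ else min(ranks_list[[i]][g])
  }, 0)
  success <- vapply(top_ns, function(N)
    mean(vapply(seq_len(nc), function(i)
      topn_success(ranks_list[[i]], good_list[[i]], N), TRUE)), 0)
  enrich <- vapply(percentiles, function(q) {
    f <- vapply(seq_len(nc), function(i)
      enrichment_fraction(ranks_list[[i]], good_list[[i]], q), 0)
    if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
  }, 0)
  structure(list(best_rank = best_rank,
                 success = setNames(success, paste0("top", top_ns)),
                 enrichment = setNames(enrich, paste0("top", percentiles * 100,
                                                      "pct")),
                 n_complexes = nc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report over %d complexes\n", x$n_complexes))
  cat("  success:   ", paste(sprintf("%s=%.3f", names(x$success), x$success),
                             collapse = "  "), "\n")
  cat("  enrichment:", paste(sprintf("%s=%.3f", names(x$enrichment),
                                     x$enrichment), collapse = "  "), "\n")
  invisible(x)
}

#' Random-scoring baseline
#'
#' The same assessments under uniformly random rankings, averaged over
#' `n_shuffles` shuffles. For a complex with `m` flagged decoys among `n`,
#' the expected top-N success is the hypergeometric
#' `1 - choose(n - m, N) / choose(n, N)` and the expected enrichment at
#' percentile `q` is approximately `q`; the sampled baseline converges to
#' these.
#'
#' @param n_list decoy counts per complex (or list of rank vectors, whose
#'   lengths are used).
#' @param good_list list of logical flags per complex.
#' @param n_shuffles number of random rankings.
#' @param seed RNG seed (same seed, identical report).
#' @param top_ns,percentiles as in [evaluation_report()].
#' @return An averaged `evaluation_report` (with `best_rank` the per-complex
#'   mean best rank over shuffles).
#' @export
random_baseline <- function(n_list, good_list, n_shuffles = 100L, seed = 1L,
                            top_ns = c(1, 10, 100, 500, 1000),
                            percentiles = c(0.001, 0.01, 0.02, 0.05)) {
  stopifnot(n_shuffles >= 1L)
  ns <- if (is.list(n_list)) lengths(n_list) else as.integer(n_list)
  stopifnot(length(ns) == length(good_list))
  set.seed(seed)
  acc_succ <- numeric(length(top_ns))
  acc_enr <- numeric(length(percentiles))
  acc_best <- numeric(length(ns))
  for (b in seq_len(n_shuffles)) {
    ranks <- lapply(ns, sample.int)
    rep_b <- evaluation_report(ranks, good_list, top_ns, percentiles)
    acc_succ <- acc_succ + rep_b$success
    acc_enr <- acc_enr + rep_b$enrichment
    acc_best <- acc_best + rep_b$best_rank
  }
  structure(list(best_rank = acc_best / n_shuffles,
                 success = acc_succ / n_shuffles,
                 enrichment = acc_enr / n_shuffles,
                 n_complexes = length(ns), n_shuffles = n_shuffles),
            class = "evaluation_report")
}
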