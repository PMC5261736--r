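#' Regression targets from quality assessments
#'
#' Maps a structural assessment to a regression target `y` such that better
#' decoys always get more negative `y` (trained potentials score good poses
#' low). Two modes:
#' \describe{
#'   \item{`negative`}{`y = -q`, for quality-increasing assessments
#'     (`stars`, `fnat`).}
#'   \item{`negative-reciprocal`}{`y = -1 / max(q, eps_q)`, for
#'     deviation-type assessments (`irmsd`, `lrmsd`), making small
#'     deviations strongly negative; `eps_q` caps the blow-up as the
#'     deviation approaches zero while preserving monotonicity.}
#' }
#'
#' @param records a `quality_records` data.frame (see [assess_decoys()]).
#' @param mode `"negative"` or `"negative-reciprocal"`.
#' @param assessment column to use: `"stars"`, `"fnat"`, `"irmsd"`,
#'   `"lrmsd"`.
#' @param eps_q floor for the reciprocal mode (assessment units).
#' @return Numeric target per decoy.
#' @export
regression_targets <- function(records,
                               mode = c("negative", "negative-reciprocal"),
                               assessment = c("stars", "fnat", "irmsd",
                                              "lrmsd"),
                               eps_q = 1e-3) {
  mode <- match.arg(mode)
  assessment <- match.arg(assessment)
  q <- records[[assessment]]
  if (is.null(q)) stop("records lack assessment column ", assessment)
  switch(mode,
         "negative" = -as.numeric(q),
         "negative-reciprocal" = -1 / pmax(as.numeric(q), eps_q))
}

#' Row-wise fraction normalization of a feature grid
#'
#' Each decoy's feature row is divided by its own sum, turning absolute
#' contact counts / buried areas into fractions so complexes with large
#' interfaces do not dominate a regression fit. All-zero rows are left zero
#' and flagged (attribute `zero_rows` on the returned grid).
#'
#' @param grid a `feature_grid`.
#' @return The normalized grid.
#' @export
fraction_normalize <- function(grid) {
  stopifnot(inherits(grid, "feature_grid"))
  s <- rowSums(grid$features)
  zero <- s == 0
  grid$features[!zero, ] <- grid$features[!zero, , drop = FALSE] / s[!zero]
  attr(grid, "zero_rows") <- which(zero)
  grid
}

#' Least-squares parameter fits
#'
#' Ordinary least squares (`mode = "ols"`, via QR) minimizes
#' `||X w - y||^2`; non-negative least squares (`mode = "nnls"`,
#' Lawson-Hanson via \pkg{pracma}) adds `w >= 0` elementwise. When the
#' unconstrained optimum is already non-negative the two coincide.
#'
#' @param X design matrix (decoys x features).
#' @param y targets (see [regression_targets()]).
#' @param mode `"ols"` or `"nnls"`.
#' @return Numeric coefficient vector (rank-deficient OLS columns get 0).
#' @export
fit_linear <- function(X, y, mode = c("ols", "nnls")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L)
  if (all(X == 0)) stop("fit error: degenerate all-zero design matrix")
  if (mode == "ols") {
    co <- stats::lm.fit(X, y)$coefficients
    co[is.na(co)] <- 0
    unname(co)
  } else {
    pracma::lsqnonneg(X, y)$x
  }
}

#' Train a potential by linear regression
#'
#' Pools the (optionally fraction-normalized) feature rows of all training
#' complexes into one design matrix, builds targets from the quality
#' records, and fits with [fit_linear()]. For the vdw form the design is
#' `[f8, -f6]` and the fitted non-negative coefficients are
#' `(alpha, beta)`, so the scoring convention `E = alpha . f8 - beta . f6`
#' is applied at scoring time, not at fitting time.
#'
#' @param grids list of compatible `feature_grid`s.
#' @param targets list of numeric target vectors, one per complex (e.g.
#'   from [regression_targets()]).
#' @param mode `"ols"` or `"nnls"` (vdw defaults to nnls so `alpha`,
#'   `beta` stay non-negative).
#' @param normalize fraction-normalize rows first (default `TRUE` for
#'   step/bsa, `FALSE` for vdw).
#' @return A [parameter_vector()].
#' @export
train_lr <- function(grids, targets, mode = NULL, normalize = NULL) {
  stopifnot(length(grids) >= 1L, length(grids) == length(targets))
  form <- grids[[1L]]$form
  for (g in grids[-1]) {
    if (!grids_compatible(grids[[1L]], g))
      stop("grid compatibility error: training grids differ in form/table")
  }
  mode <- mode %||% if (form$kind == "vdw") "nnls" else "ols"
  normalize <- normalize %||% (form$kind != "vdw")
  if (normalize) grids <- lapply(grids, fraction_normalize)
  X <- do.call(rbind, lapply(grids, `[[`, "features"))
  y <- unlist(targets, use.names = FALSE)
  lambda <- grids[[1L]]$n_types
  if (form$kind == "vdw") {
    P <- n_pair_types(lambda)
    design <- cbind(X[, seq_len(P), drop = FALSE],
                    -X[, P + seq_len(P), drop = FALSE])
    co <- fit_linear(design, y, mode)
    parameter_vector(form, alpha = co[seq_len(P)], beta = co[P + seq_len(P)],
                     n_types = lambda, table_hash = grids[[1L]]$table_hash)
  } else {
    parameter_vector(form, values = fit_linear(X, y, mode),
                     n_types = lambda, table_hash = grids[[1L]]$table_hash)
  }
}

#' Cross-validated training with scaled averaging or best-set selection
#'
#' Splits the training complexes into `k` folds; each fold's held-out
#' complexes form its validation set and the trainer runs on the rest,
#' producing `k` parameter sets. Two combination rules:
#' \describe{
#'   \item{`"scaled_average"`}{(step/bsa) each parameter set is divided by
#'     the standard deviation of its own entries - one scalar per set -
#'     and the scaled sets are averaged elementwise.}
#'   \item{`"best"`}{(vdw) the single set with the highest validation
#'     performance (from `validate`) is returned.}
#' }
#'
#' @param grids list of `feature_grid`s (one per complex).
#' @param aux list of per-complex auxiliary data (quality records, weights,
#'   targets ...) subset alongside `grids` and passed to the trainer.
#' @param k number of folds (`>= 2`, `<=` number of complexes).
#' @param trainer `function(grids, aux) -> parameter_vector`.
#' @param combine `"scaled_average"` or `"best"`.
#' @param validate `function(params, grids, aux) -> scalar` scored on each
#'   fold's validation complexes (higher is better); required for
#'   `combine = "best"`.
#' @return List of class `crossval_result`: `params` (combined
#'   [parameter_vector()]), `fold_params`, `validation` (per-fold scores,
#'   if `validate` given), `folds` (fold id per complex).
#' @export
crossval_average <- function(grids, aux, k = 5L, trainer,
                             combine = c("scaled_average", "best"),
                             validate = NULL) {
  combine <- match.arg(combine)
  n <- length(grids)
  stopifnot(length(aux) == n)
  if (k < 2L || k > n)
    stop("split error: need 2 <= k <= number of complexes (", n, ")")
  if (combine == "best" && is.null(validate))
    stop("combine = 'best' needs a validate function")
  folds <- rep_len(seq_len(k), n)
  fold_params <- vector("list", k)
  val_scores <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_params[[f]] <- trainer(grids[tr], aux[tr])
    if (!is.null(validate))
      val_scores[f] <- validate(fold_params[[f]], grids[!tr], aux[!tr])
  }
  params <- if (combine == "best") {
    fold_params[[which.max(val_scores)]]
  } else {
    mats <- lapply(fold_params, param_weights)
    scaled <- lapply(mats, function(v) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) v else v / s
    })
    avg <- Reduce(`+`, scaled) / k
    p1 <- fold_params[[1L]]
    if (p1$form$kind == "vdw") {
      P <- length(p1$alpha)
      parameter_vector(p1$form, alpha = avg[seq_len(P)],
                       beta = -avg[P + seq_len(P)],
                       n_types = p1$n_types, table_hash = p1$table_hash)
    } else {
      parameter_vector(p1$form, values = avg, n_types = p1$n_types,
                       table_hash = p1$table_hash)
    }
  }
  structure(list(params = params, fold_params = fold_params,
                 validation = val_scores, folds = folds),
            class = "crossval_result")
}
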