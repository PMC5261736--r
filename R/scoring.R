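#' Potential parameter vectors
#'
#' Trained parameters for one [potential_form()]. For `step` and `bsa`
#' forms, `values` holds one weight per feature column and the score of a
#' decoy is the dot product with its feature row. For the `vdw` form the
#' parameters are `alpha = epsilon * sigma^8` and `beta = epsilon * sigma^6`
#' per type pair, scored as `E = alpha . f8 - beta . f6`; the `(sigma,
#' epsilon)` view is derived exactly as `sigma = sqrt(alpha/beta)`,
#' `epsilon = beta / sigma^6`. Lower (more negative) scores mean better
#' poses.
#'
#' @param form a [potential_form()].
#' @param values numeric weights (step/bsa), one per feature column.
#' @param alpha,beta vdw blocks, one value per canonical type pair.
#' @param n_types number of atom types of the typing table used.
#' @param table_hash hash of that table (compatibility checks).
#' @return Object of class `parameter_vector`.
#' @export
parameter_vector <- function(form, values = NULL, alpha = NULL, beta = NULL,
                             n_types, table_hash = NA_character_) {
  stopifnot(inherits(form, "potential_form"))
  if (form$kind == "vdw") {
    P <- n_pair_types(n_types)
    stopifnot(length(alpha) == P, length(beta) == P)
    out <- list(form = form, alpha = as.numeric(alpha),
                beta = as.numeric(beta))
  } else {
    stopifnot(!is.null(values))
    out <- list(form = form, values = as.numeric(values))
  }
  out$n_types <- as.integer(n_types)
  out$table_hash <- table_hash
  structure(out, class = "parameter_vector")
}

#' @export
print.parameter_vector <- function(x, ...) {
  n <- if (x$form$kind == "vdw") 2L * length(x$alpha) else length(x$values)
  cat(sprintf("parameter_vector: %s form, %d parameters, %d types\n",
              x$form$kind, n, x$n_types))
  invisible(x)
}

#' @rdname parameter_vector
#' @param p a vdw `parameter_vector`.
#' @return `vdw_sigma_eps()`: data.frame with `pair`, `sigma`, `epsilon`
#'   (`NA` where `beta = 0`).
#' @export
vdw_sigma_eps <- function(p) {
  stopifnot(inherits(p, "parameter_vector"), p$form$kind == "vdw")
  sigma <- ifelse(p$beta > 0, sqrt(p$alpha / p$beta), NA_real_)
  data.frame(pair = seq_along(p$alpha) - 1L, sigma = sigma,
             epsilon = ifelse(is.na(sigma), NA_real_, p$beta / sigma^6))
}

#' @rdname parameter_vector
#' @param sigma,epsilon per-pair vdw parameters (Angstrom, energy units).
#' @export
vdw_from_sigma_eps <- function(form, sigma, epsilon, n_types,
                               table_hash = NA_character_) {
  parameter_vector(form, alpha = epsilon * sigma^8, beta = epsilon * sigma^6,
                   n_types = n_types, table_hash = table_hash)
}

# Flat weight vector w such that score = features %*% w for any form.
param_weights <- function(p) {
  if (p$form$kind == "vdw") c(p$alpha, -p$beta) else p$values
}

check_grid_param <- function(grid, p) {
  if (!identical(grid$form$kind, p$form$kind) ||
      !identical(grid$n_types, p$n_types))
    stop("compatibility error: parameter vector does not match grid layout")
  if (!is.na(p$table_hash) && !identical(p$table_hash, grid$table_hash))
    stop("compatibility error: parameter vector typed with a different table")
  w <- param_weights(p)
  if (length(w) != ncol(grid$features))
    stop("compatibility error: parameter length != feature columns")
  invisible(w)
}

#' Score decoys from a feature grid
#'
#' One matrix-vector product; no structure access. Lower scores are better.
#'
#' @param grid a `feature_grid`.
#' @param p a compatible [parameter_vector()].
#' @return Numeric score per decoy (named by decoy id).
#' @export
score_decoys <- function(grid, p) {
  w <- check_grid_param(grid, p)
  setNames(as.numeric(grid$features %*% w), grid$decoy_ids)
}

#' Rank decoys by score
#'
#' Rank 1 is the lowest (best) score; ties keep input order (stable), so
#' top-N metrics are reproducible.
#'
#' @param scores numeric scores.
#' @return Integer ranks, a permutation of `1..n`.
#' @examples
#' rank_decoys(c(-3, -1, -2)) # 1 3 2
#' @export
rank_decoys <- function(scores) {
  stopifnot(length(scores) >= 1L)
  r <- integer(length(scores))
  r[order(scores)] <- seq_along(scores)
  r
}

#' Save / load parameter vectors as JSON
#'
#' @param p a [parameter_vector()].
#' @param path file path.
#' @export
write_potential <- function(p, path) {
  stopifnot(inherits(p, "parameter_vector"))
  obj <- list(kind = p$form$kind, form = unclass(p$form),
              n_types = p$n_types, table_hash = p$table_hash)
  if (p$form$kind == "vdw") {
    obj$alpha <- p$alpha; obj$beta <- p$beta
  } else obj$values <- p$values
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  form <- do.call(potential_form, c(list(kind = obj$kind),
                                    obj$form[setdiff(names(obj$form), "kind")]))
  parameter_vector(form, values = obj$values, alpha = obj$alpha,
                   beta = obj$beta, n_types = obj$n_types,
                   table_hash = obj$table_hash %||% NA_character_)
}
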