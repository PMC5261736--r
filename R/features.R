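#' Potential functional forms
#'
#' Three forms are supported:
#' \describe{
#'   \item{`step`}{contact (step) potential: one parameter per (type pair,
#'     distance bin), bins half-open `[lo, hi)` over `bin_edges`. A distance
#'     exactly at an edge belongs to the bin whose lower edge it is.}
#'   \item{`vdw`}{soft Lennard-Jones potential `E = alpha * sum r^-8 -
#'     beta * sum r^-6` per type pair. Cross distances below `clash_floor`
#'     are shifted up to `clash_floor` (default 2 Angstrom) to damp the
#'     influence of clashes inherited from coarse-grained sampling; pairs
#'     beyond `cutoff` (default 12 Angstrom) are ignored.}
#'   \item{`bsa`}{buried-surface-area potential: one parameter per heavy
#'     atom type, feature = surface area of that type buried at the
#'     interface (probe radius default 1.4 Angstrom).}
#' }
#'
#' @param kind `"step"`, `"vdw"` or `"bsa"`.
#' @param bin_edges strictly increasing edges in Angstrom (step only).
#' @param clash_floor,cutoff vdw distance floor and summation cutoff (A).
#' @param probe_radius,n_points bsa probe radius (A) and quadrature points.
#' @return An object of class `potential_form`.
#' @examples
#' potential_form("step", bin_edges = c(0, 4, 6))
#' @export
potential_form <- function(kind = c("step", "vdw", "bsa"),
                           bin_edges = c(0, 10),
                           clash_floor = 2, cutoff = 12,
                           probe_radius = 1.4, n_points = 960L) {
  kind <- match.arg(kind)
  form <- switch(kind,
    step = {
      if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
        stop("step form needs >= 2 strictly increasing bin edges")
      list(kind = kind, bin_edges = as.numeric(bin_edges))
    },
    vdw = {
      if (clash_floor <= 0 || cutoff <= clash_floor)
        stop("vdw form needs 0 < clash_floor < cutoff")
      list(kind = kind, clash_floor = clash_floor, cutoff = cutoff)
    },
    bsa = {
      if (probe_radius <= 0) stop("bsa form needs probe_radius > 0")
      list(kind = kind, probe_radius = probe_radius,
           n_points = as.integer(n_points))
    })
  structure(form, class = "potential_form")
}

#' @export
print.potential_form <- function(x, ...) {
  desc <- switch(x$kind,
    step = paste0("edges [", paste(x$bin_edges, collapse = ", "), ") A"),
    vdw = sprintf("clash floor %g A, cutoff %g A", x$clash_floor, x$cutoff),
    bsa = sprintf("probe %g A, %d points/atom", x$probe_radius, x$n_points))
  cat(sprintf("potential_form '%s': %s\n", x$kind, desc))
  invisible(x)
}

# Column layout of a feature vector for a given form and typing table.
feature_layout <- function(form, table) {
  P <- n_pair_types(table$n_types)
  switch(form$kind,
    step = {
      B <- length(form$bin_edges) - 1L
      data.frame(column = seq_len(P * B),
                 pair = rep(seq_len(P) - 1L, each = B),
                 bin = rep(seq_len(B), times = P))
    },
    vdw = data.frame(column = seq_len(2L * P),
                     pair = c(seq_len(P) - 1L, seq_len(P) - 1L),
                     block = rep(c("r8", "r6"), each = P)),
    bsa = {
      ht <- which(table$heavy_flags) - 1L
      data.frame(column = seq_along(ht), type = ht,
                 label = table$labels[ht + 1L])
    })
}

n_features <- function(form, table) nrow(feature_layout(form, table))

check_typed <- function(s) {
  if (is.na(s$table_hash) || anyNA(s$receptor$type) || anyNA(s$ligand$type))
    stop("structure must be typed (assign_atom_types) before featurizing")
  invisible(TRUE)
}

#' Step (contact-count) features
#'
#' For every receptor-ligand atom pair the count of the (canonical type
#' pair, distance bin) cell containing the pair distance is incremented;
#' distances at or beyond the last edge (or below the first) are ignored.
#' Bins are half-open `[lo, hi)`.
#'
#' @param s a typed [typed_structure()].
#' @param bin_edges strictly increasing bin edges (Angstrom).
#' @return Numeric count vector of length
#'   `n_bins * n_types*(n_types+1)/2`, bin index fastest.
#' @export
step_features <- function(s, bin_edges) {
  check_typed(s)
  lambda <- s$table$n_types
  B <- length(bin_edges) - 1L
  P <- n_pair_types(lambda)
  d <- cross_dist(structure_coords(s, "receptor"), structure_coords(s, "ligand"))
  bin <- findInterval(d, bin_edges, left.open = FALSE, rightmost.closed = FALSE)
  keep <- bin >= 1L & bin <= B
  if (!any(keep)) return(numeric(P * B))
  pr <- canonical_pair_index(
    rep(s$receptor$type, times = ncol(d))[keep],
    rep(s$ligand$type, each = nrow(d))[keep], lambda)
  accumulate_by_index(rep(1, sum(keep)), pr * B + bin[keep], P * B)
}

#' Soft Lennard-Jones (r^-8 / r^-6) features
#'
#' Per canonical type pair, the sums `sum max(r, clash_floor)^-8` and
#' `sum max(r, clash_floor)^-6` over receptor-ligand pairs with
#' `r < cutoff`.
#'
#' @param s a typed [typed_structure()].
#' @param clash_floor,cutoff Angstrom.
#' @return Numeric vector `c(r8 block, r6 block)`, each of length
#'   `n_types*(n_types+1)/2`.
#' @export
vdw_features <- function(s, clash_floor = 2, cutoff = 12) {
  check_typed(s)
  stopifnot(clash_floor > 0, cutoff > clash_floor)
  lambda <- s$table$n_types
  P <- n_pair_types(lambda)
  d <- cross_dist(structure_coords(s, "receptor"), structure_coords(s, "ligand"))
  keep <- d < cutoff
  if (!any(keep)) return(numeric(2L * P))
  r <- pmax(d[keep], clash_floor)
  pr <- canonical_pair_index(
    rep(s$receptor$type, times = ncol(d))[keep],
    rep(s$ligand$type, each = nrow(d))[keep], lambda)
  c(accumulate_by_index(r^-8, pr + 1L, P),
    accumulate_by_index(r^-6, pr + 1L, P))
}

#' Buried-surface-area features
#'
#' For each heavy atom type, the solvent-accessible surface area lost upon
#' complexation: `sum over atoms of that type of [sasa(partner alone) -
#' sasa(complex)]`, both partners in their docked internal conformation
#' (rigid bodies, so the burial depends only on the interface). Per-type
#' sums are clamped at zero against quadrature noise.
#'
#' @param s a typed [typed_structure()] with heavy atoms on both partners.
#' @param probe probe radius (Angstrom).
#' @param n_points quadrature points per atom.
#' @param radii optional per-atom radii for `rbind(receptor, ligand)` atoms;
#'   default from [atom_radii()] on the element column.
#' @return Numeric vector over heavy types (ascending type index).
#' @export
bsa_features <- function(s, probe = 1.4, n_points = 960L, radii = NULL) {
  check_typed(s)
  rec <- s$receptor[s$receptor$heavy, , drop = FALSE]
  lig <- s$ligand[s$ligand$heavy, , drop = FALSE]
  if (nrow(rec) == 0L || nrow(lig) == 0L)
    stop("bsa features need heavy atoms on both partners")
  xr <- as.matrix(rec[, c("x", "y", "z")])
  xl <- as.matrix(lig[, c("x", "y", "z")])
  if (is.null(radii)) radii <- atom_radii(c(rec$element, lig$element))
  radii <- rep_len(radii, nrow(rec) + nrow(lig))
  rr <- radii[seq_len(nrow(rec))]
  rl <- radii[nrow(rec) + seq_len(nrow(lig))]
  alone <- c(sasa(xr, rr, probe, n_points), sasa(xl, rl, probe, n_points))
  complexed <- sasa(rbind(xr, xl), radii, probe, n_points)
  ht <- which(s$table$heavy_flags) - 1L
  per_type <- accumulate_by_index(alone - complexed,
                                  match(c(rec$type, lig$type), ht),
                                  length(ht))
  pmax(per_type, 0)
}

featurize_structure <- function(s, form) {
  switch(form$kind,
    step = step_features(s, form$bin_edges),
    vdw = vdw_features(s, form$clash_floor, form$cutoff),
    bsa = bsa_features(s, form$probe_radius, form$n_points))
}

#' Build a feature grid for a decoy ensemble
#'
#' Featurizes every decoy of one complex under one [potential_form()] and
#' stacks the vectors into a matrix, so any candidate parameter vector
#' scores the whole ensemble as a single matrix-vector product. All decoys
#' must be typed with the same table (enforced via the table hash).
#'
#' @param decoys list of typed [typed_structure()]s (optionally named).
#' @param form a [potential_form()].
#' @param complex_id identifier stored in the grid.
#' @return Object of class `feature_grid`: `features` (n_decoys x
#'   n_features), `form`, `n_types`, `table_hash`, `layout`, `decoy_ids`,
#'   `native` (logical per row, all `FALSE` here; see [insert_native()]).
#' @export
build_feature_grid <- function(decoys, form, complex_id = "complex") {
  stopifnot(length(decoys) >= 1L, inherits(form, "potential_form"))
  hashes <- vapply(decoys, function(d) d$table_hash, "")
  if (anyNA(hashes) || length(unique(hashes)) != 1L)
    stop("grid compatibility error: decoys must share one typing table")
  table <- decoys[[1L]]$table
  feats <- t(vapply(decoys, featurize_structure, numeric(n_features(form, table)),
                    form = form))
  ids <- names(decoys) %||% sprintf("decoy%04d", seq_along(decoys))
  structure(list(complex_id = complex_id, features = unname(feats),
                 form = form, n_types = table$n_types,
                 table_hash = table$hash,
                 layout = feature_layout(form, table),
                 decoy_ids = ids,
                 native = logical(length(decoys))),
            class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf("feature_grid '%s': %d decoys x %d features (%s form, %d types)\n",
              x$complex_id, nrow(x$features), ncol(x$features),
              x$form$kind, x$n_types))
  invisible(x)
}

grids_compatible <- function(a, b) {
  identical(a$table_hash, b$table_hash) &&
    identical(unclass(a$form), unclass(b$form)) &&
    identical(a$n_types, b$n_types)
}

#' Append decoys to an existing grid
#'
#' @param grid a `feature_grid`.
#' @param decoys list of typed structures, typed with the grid's table.
#' @param native logical flag(s) for the appended rows.
#' @return The extended grid; appending decoys typed with a different table
#'   is a compatibility error.
#' @export
grid_append <- function(grid, decoys, native = FALSE) {
  add <- build_feature_grid(decoys, grid$form, grid$complex_id)
  if (!grids_compatible(grid, add))
    stop("grid compatibility error: typing table or layout mismatch")
  grid$features <- rbind(grid$features, add$features)
  grid$decoy_ids <- c(grid$decoy_ids, add$decoy_ids)
  grid$native <- c(grid$native, rep_len(native, length(decoys)))
  grid
}

#' Save / load feature grids
#'
#' R-native serialization; `grid_load(grid_save(g, path))` is bit-identical.
#'
#' @param grid a `feature_grid`.
#' @param path file path.
#' @export
grid_save <- function(grid, path) {
  stopifnot(inherits(grid, "feature_grid"))
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname grid_save
#' @export
grid_load <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "feature_grid")) stop("not a feature grid: ", path)
  g
}
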