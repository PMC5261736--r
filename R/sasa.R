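# Solvent-accessible surface area by deterministic surface-point quadrature.
#
# Each atom carries a fixed golden-spiral point set on its solvent-expanded
# sphere (radius + probe); a point is accessible if it lies outside every
# other atom's expanded sphere. Deterministic for a fixed point count, which
# makes buried-surface features reproducible bit-for-bit.

# Fixed unit-sphere point set (golden-spiral / Fibonacci lattice), n x 3.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Per-element van der Waals radii (Angstrom); X is the pseudo-atom element
# used by synthetic fixtures.
element_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, X = 1.80)

#' Atomic radii for surface calculations
#'
#' @param element character vector of element symbols.
#' @param default radius for elements not in the shipped table.
#' @return Numeric radii in Angstrom.
#' @export
atom_radii <- function(element, default = 1.80) {
  r <- element_radii[toupper(element)]
  r[is.na(r)] <- default
  unname(r)
}

#' Solvent-accessible surface area per atom
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom radii (Angstrom), recycled if length 1.
#' @param probe probe (water) radius, default 1.4 Angstrom.
#' @param n_points quadrature points per atom (default 960).
#' @return Numeric vector of per-atom areas in Angstrom^2. An isolated atom
#'   returns the analytic sphere area `4*pi*(radius+probe)^2` to quadrature
#'   accuracy (exactly, since all points are then accessible).
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3L, probe > 0, n_points >= 12L)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("radii must be positive")
  pts <- sphere_points(n_points)
  rext <- radii + probe
  # neighbor lists from the pairwise upper bound rext_i + rext_j
  d <- cross_dist(coords, coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rext[i] + rext & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * rext[i]^2
      next
    }
    p <- sweep(pts * rext[i], 2, coords[i, ], "+")
    d2 <- outer(rowSums(p^2), rowSums(coords[nb, , drop = FALSE]^2), "+") -
      2 * tcrossprod(p, coords[nb, , drop = FALSE])
    buried <- rowSums(d2 < rep(rext[nb]^2, each = n_points)) > 0L
    out[i] <- 4 * pi * rext[i]^2 * (1 - mean(buried))
  }
  out
}
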