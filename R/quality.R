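#' Interface residue contacts
#'
#' Unordered (receptor residue, ligand residue) pairs having any heavy-atom
#' cross distance strictly below `cutoff`.
#'
#' @param s a [typed_structure()].
#' @param cutoff contact distance in Angstrom (default 5, the community
#'   convention for native-contact counting).
#' @return Character vector of contact keys
#'   `"chain:resno:insert--chain:resno:insert"` (receptor side first).
#' @export
interface_contacts <- function(s, cutoff = 5) {
  stopifnot(cutoff > 0)
  rec <- s$receptor[s$receptor$heavy, , drop = FALSE]
  lig <- s$ligand[s$ligand$heavy, , drop = FALSE]
  d <- cross_dist(as.matrix(rec[, c("x", "y", "z")]),
                  as.matrix(lig[, c("x", "y", "z")]))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(character(0))
  unique(paste(residue_keys(rec)[hit[, 1]],
               residue_keys(lig)[hit[, 2]], sep = "--"))
}

#' Fraction of native contacts (Fnat)
#'
#' @param decoy,native [typed_structure()]s sharing residue identifiers.
#' @param cutoff heavy-atom contact cutoff in Angstrom.
#' @return Fraction in `[0, 1]` of the native interface contacts present in
#'   the decoy.
#' @export
compute_fnat <- function(decoy, native, cutoff = 5) {
  nat <- interface_contacts(native, cutoff)
  if (length(nat) == 0L)
    stop("undefined quality: native complex has no interface contacts")
  dec <- interface_contacts(decoy, cutoff)
  length(intersect(dec, nat)) / length(nat)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid superposition of `mobile` onto `reference`
#' (row-vector convention: `x' = x %*% rotation + translation`).
#'
#' @param mobile,reference n x 3 coordinate matrices in correspondence.
#' @return List with `rotation` (3 x 3, proper), `translation` (length 3)
#'   and `rmsd` (Angstrom) after superposition.
#' @export
superpose_rmsd <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("pairing error: coordinate sets must be equal-sized n x 3 matrices")
  if (nrow(mobile) < 3L) stop("need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv <- svd(crossprod(A, B))
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% R
  list(rotation = R,
       translation = as.numeric(cr - cm %*% R),
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

apply_rigid <- function(xyz, fit) sweep(xyz %*% fit$rotation, 2, fit$translation, "+")

#' Ligand RMSD (Lrmsd)
#'
#' The decoy receptor is superposed onto the native receptor (all heavy
#' atoms) and the RMSD is taken over ligand heavy atoms. Invariant under any
#' global rigid motion of the decoy; a pure ligand translation of d Angstrom
#' gives exactly d.
#'
#' @param decoy,native [typed_structure()]s in atom correspondence.
#' @return Lrmsd in Angstrom.
#' @export
compute_lrmsd <- function(decoy, native) {
  check_correspondence(decoy, native)
  fit <- superpose_rmsd(structure_coords(decoy)[decoy$receptor$heavy, ],
                        structure_coords(native)[native$receptor$heavy, ])
  dl <- apply_rigid(structure_coords(decoy, "ligand")[decoy$ligand$heavy, ], fit)
  nl <- structure_coords(native, "ligand")[native$ligand$heavy, ]
  sqrt(mean(rowSums((dl - nl)^2)))
}

check_correspondence <- function(decoy, native) {
  for (p in c("receptor", "ligand")) {
    if (nrow(decoy[[p]]) != nrow(native[[p]]) ||
        !identical(residue_keys(decoy[[p]]), residue_keys(native[[p]])) ||
        !identical(toupper(decoy[[p]]$elety), toupper(native[[p]]$elety)))
      stop("pairing error: decoy and native ", p, " atoms do not correspond")
  }
  invisible(TRUE)
}

#' Interface RMSD (Irmsd)
#'
#' Interface residues are the native residues (both partners) with any heavy
#' atom within `interface_cutoff` of the partner. The RMSD is computed over
#' the backbone heavy atoms (N, CA, C, O) of those residues after
#' superposition on those same atoms. Structures without backbone atom names
#' (pseudo-atom fixtures) fall back to all heavy atoms of the interface
#' residues.
#'
#' @param decoy,native [typed_structure()]s in atom correspondence.
#' @param interface_cutoff Angstrom (default 10).
#' @return Irmsd in Angstrom.
#' @export
compute_irmsd <- function(decoy, native, interface_cutoff = 10) {
  check_correspondence(decoy, native)
  iface <- interface_contacts(native, interface_cutoff)
  if (length(iface) == 0L)
    stop("undefined quality: native has no interface at ",
         interface_cutoff, " A")
  parts <- strsplit(iface, "--", fixed = TRUE)
  rec_res <- unique(vapply(parts, `[`, "", 1L))
  lig_res <- unique(vapply(parts, `[`, "", 2L))
  pick <- function(df, res) {
    sel <- df[residue_keys(df) %in% res & df$heavy, , drop = FALSE]
    bb <- sel[toupper(sel$elety) %in% c("N", "CA", "C", "O"), , drop = FALSE]
    if (nrow(bb) >= 3L) bb else sel
  }
  idx_n <- rbind(pick(native$receptor, rec_res), pick(native$ligand, lig_res))
  idx_d <- rbind(pick(decoy$receptor, rec_res), pick(decoy$ligand, lig_res))
  superpose_rmsd(as.matrix(idx_d[, c("x", "y", "z")]),
                 as.matrix(idx_n[, c("x", "y", "z")]))$rmsd
}

#' CAPRI star classification
#'
#' Hierarchical classification: 3 stars if `Irmsd < 1` and `Fnat > 0.5`;
#' else 2 stars if `Irmsd < 2` and `Fnat > 0.3`; else 1 star if `Irmsd < 4`
#' and `Fnat > 0.1`; else 0. Decoys with at least one star are "near-native".
#' Vectorized.
#'
#' @param fnat fraction of native contacts in `[0, 1]`.
#' @param irmsd interface RMSD in Angstrom.
#' @return Integer star count in `{0, 1, 2, 3}`.
#' @examples
#' capri_classify(c(0.6, 0.35, 0.05), c(0.9, 1.5, 0.5)) # 3 2 0
#' @export
capri_classify <- function(fnat, irmsd) {
  stopifnot(all(fnat >= 0 & fnat <= 1), all(irmsd >= 0))
  ifelse(irmsd < 1 & fnat > 0.5, 3L,
    ifelse(irmsd < 2 & fnat > 0.3, 2L,
      ifelse(irmsd < 4 & fnat > 0.1, 1L, 0L)))
}

#' Assess a decoy set against its native complex
#'
#' @param decoys list of [typed_structure()]s.
#' @param native the native [typed_structure()].
#' @param fnat_cutoff,interface_cutoff contact cutoffs in Angstrom.
#' @return data.frame (one row per decoy) with `fnat`, `lrmsd`, `irmsd`,
#'   `stars`; class `quality_records`.
#' @export
assess_decoys <- function(decoys, native, fnat_cutoff = 5,
                          interface_cutoff = 10) {
  rows <- lapply(decoys, function(d) {
    fnat <- compute_fnat(d, native, fnat_cutoff)
    data.frame(fnat = fnat,
               lrmsd = compute_lrmsd(d, native),
               irmsd = compute_irmsd(d, native, interface_cutoff))
  })
  out <- do.call(rbind, rows)
  out$stars <- capri_classify(out$fnat, out$irmsd)
  rownames(out) <- names(decoys) %||% NULL
  class(out) <- c("quality_records", class(out))
  out
}

#' Per-complex normalized quality weights
#'
#' Raw training weights are taken per decoy from the chosen scheme - the
#' CAPRI star value, the Fnat value, an indicator on an inserted native, or
#' a custom function of the records - and then divided by their per-complex
#' sum. A complex whose raw weights are all zero keeps zero weights and is
#' flagged unusable for training (attribute `usable`).
#'
#' @param records a `quality_records` data.frame (from [assess_decoys()]);
#'   for `scheme = "native"` it must carry a logical `native` column.
#' @param scheme `"stars"`, `"fnat"`, `"native"`, or a function
#'   `records -> raw weights`.
#' @return Numeric weights summing to 1 (or all zero), with attribute
#'   `usable`.
#' @export
make_quality_weights <- function(records, scheme = "stars") {
  raw <- if (is.function(scheme)) {
    scheme(records)
  } else {
    switch(match.arg(scheme, c("stars", "fnat", "native")),
           stars = as.numeric(records$stars),
           fnat = records$fnat,
           native = {
             if (is.null(records$native))
               stop("'native' scheme needs a logical native column")
             as.numeric(records$native)
           })
  }
  if (length(raw) != nrow(records) || any(raw < 0))
    stop("raw quality weights must be one non-negative value per decoy")
  tot <- sum(raw)
  w <- if (tot > 0) raw / tot else raw
  attr(w, "usable") <- tot > 0
  w
}
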