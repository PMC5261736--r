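# Shared helpers: hand-built typed structures and independent brute-force
# oracles (plain double loops, kept deliberately separate from the package's
# vectorized implementations).

# Build a typed structure from raw coordinates and 0-based types, one
# pseudo-residue per atom, typed with a toy table.
manual_structure <- function(rec_xyz, lig_xyz, rec_types = NULL,
                             lig_types = NULL, n_types = 4L) {
  rec_xyz <- matrix(rec_xyz, ncol = 3)
  lig_xyz <- matrix(lig_xyz, ncol = 3)
  if (is.null(rec_types)) rec_types <- rep(0L, nrow(rec_xyz))
  if (is.null(lig_types)) lig_types <- rep(0L, nrow(lig_xyz))
  df <- function(xyz, types, chain) {
    data.frame(chain = chain, resno = seq_len(nrow(xyz)), insert = "",
               resid = "PSD", elety = paste0("X", types),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               element = "X", stringsAsFactors = FALSE)
  }
  assign_atom_types(
    typed_structure(df(rec_xyz, rec_types, "A"), df(lig_xyz, lig_types, "B")),
    toy_typing_table(n_types))
}

random_structure <- function(n_rec, n_lig, n_types = 4L, spread = 8) {
  manual_structure(matrix(runif(n_rec * 3, 0, spread), ncol = 3),
                   matrix(runif(n_lig * 3, 0, spread), ncol = 3),
                   sample.int(n_types, n_rec, replace = TRUE) - 1L,
                   sample.int(n_types, n_lig, replace = TRUE) - 1L,
                   n_types)
}

# O(n^2) oracles ------------------------------------------------------------

oracle_contacts <- function(s, cutoff) {
  rec <- s$receptor[s$receptor$heavy, ]
  lig <- s$ligand[s$ligand$heavy, ]
  out <- character(0)
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt(sum((c(rec$x[i], rec$y[i], rec$z[i]) -
                       c(lig$x[j], lig$y[j], lig$z[j]))^2))
      if (d < cutoff)
        out <- c(out, paste0(rec$chain[i], ":", rec$resno[i], ":", "--",
                             lig$chain[j], ":", lig$resno[j], ":"))
    }
  }
  unique(out)
}

oracle_step_features <- function(s, edges) {
  lambda <- s$table$n_types
  B <- length(edges) - 1L
  v <- numeric(n_pair_types(lambda) * B)
  for (i in seq_len(nrow(s$receptor))) {
    for (j in seq_len(nrow(s$ligand))) {
      d <- sqrt(sum((as.numeric(s$receptor[i, c("x", "y", "z")]) -
                       as.numeric(s$ligand[j, c("x", "y", "z")]))^2))
      for (b in seq_len(B)) {
        if (d >= edges[b] && d < edges[b + 1]) {
          p <- canonical_pair_index(s$receptor$type[i], s$ligand$type[j],
                                    lambda)
          v[p * B + b] <- v[p * B + b] + 1
        }
      }
    }
  }
  v
}

oracle_vdw_features <- function(s, clash_floor, cutoff) {
  lambda <- s$table$n_types
  P <- n_pair_types(lambda)
  v8 <- numeric(P); v6 <- numeric(P)
  for (i in seq_len(nrow(s$receptor))) {
    for (j in seq_len(nrow(s$ligand))) {
      d <- sqrt(sum((as.numeric(s$receptor[i, c("x", "y", "z")]) -
                       as.numeric(s$ligand[j, c("x", "y", "z")]))^2))
      if (d < cutoff) {
        r <- max(d, clash_floor)
        p <- canonical_pair_index(s$receptor$type[i], s$ligand$type[j],
                                  lambda) + 1L
        v8[p] <- v8[p] + r^-8
        v6[p] <- v6[p] + r^-6
      }
    }
  }
  c(v8, v6)
}

# rotation by angle about a given axis (Rodrigues)
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# apply a rigid motion to one partner (or both) of a typed structure
shift_partner <- function(s, partner, R = diag(3), t = c(0, 0, 0)) {
  xyz <- structure_coords(s, partner) %*% R
  xyz <- sweep(xyz, 2, t, "+")
  s[[partner]][, c("x", "y", "z")] <- xyz
  s
}

# a small all-amino-acid structure covering every entry of the shipped
# grouped all-atom table (atom names taken from the table itself, plus a
# wildcard-matched hydrogen per residue)
allaa_structure <- function() {
  tt <- default_typing_table()
  ent <- tt$entries[tt$entries$atom != "H*", ]
  residues <- unique(ent$residue)
  mk <- function(res_set, chain, base) {
    rows <- list()
    for (k in seq_along(res_set)) {
      res <- res_set[k]
      atoms <- c(ent$atom[ent$residue == res], "HB9") # HB9 hits the wildcard
      for (a in seq_along(atoms)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, resno = k, insert = "", resid = res,
          elety = atoms[a],
          x = base + k * 8, y = a * 0.9, z = 0,
          element = ifelse(substr(atoms[a], 1, 1) %in% c("H"), "H",
                           substr(atoms[a], 1, 1)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  typed_structure(mk(residues[1:10], "A", 0), mk(residues[11:20], "B", 4))
}
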