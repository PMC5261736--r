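#' Typed receptor-ligand structures
#'
#' A `typed_structure` holds the two rigid partners of one docked complex:
#' per-partner atom tables with coordinates (Angstrom), residue identity
#' (chain, residue number, insertion code; numbering as in the source file),
#' atom names, and - once [assign_atom_types()] has run - integer atom types
#' and heavy-atom flags from a [typing_table()].
#'
#' @param receptor,ligand data.frames with columns `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `x`, `y`, `z`, `element`.
#' @param table optional [typing_table()] already applied.
#' @return An object of class `typed_structure`.
#' @export
typed_structure <- function(receptor, ligand, table = NULL) {
  for (df in list(receptor, ligand)) {
    stopifnot(is.data.frame(df),
              all(c("chain", "resno", "insert", "resid", "elety",
                    "x", "y", "z", "element") %in% names(df)))
    if (nrow(df) == 0L) stop("receptor and ligand must both contain atoms")
  }
  fill <- function(df) {
    df$is_h <- df$element == "H"
    if (is.null(df$type)) df$type <- NA_integer_
    if (is.null(df$heavy)) df$heavy <- !df$is_h
    df
  }
  structure(list(receptor = fill(receptor), ligand = fill(ligand),
                 table = table,
                 table_hash = if (is.null(table)) NA_character_ else table$hash),
            class = "typed_structure")
}

#' @export
print.typed_structure <- function(x, ...) {
  cat(sprintf("typed_structure: receptor %d atoms, ligand %d atoms, %s\n",
              nrow(x$receptor), nrow(x$ligand),
              if (is.na(x$table_hash)) "untyped"
              else sprintf("typed (%s)", x$table$name %||% x$table_hash)))
  invisible(x)
}

#' @rdname typed_structure
#' @param s a `typed_structure`.
#' @param partner `"receptor"` or `"ligand"`.
#' @return `structure_coords()`: numeric matrix of coordinates (n x 3).
#' @export
structure_coords <- function(s, partner = c("receptor", "ligand")) {
  partner <- match.arg(partner)
  as.matrix(s[[partner]][, c("x", "y", "z")])
}

# residue identity keys (chain:resno:insert), one per atom
residue_keys <- function(df) paste(df$chain, df$resno, df$insert, sep = ":")

element_from_name <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", toupper(elety))
  ifelse(substr(nm, 1, 1) == "H", "H", substr(nm, 1, 1))
}

#' Read a two-partner complex from a PDB file
#'
#' Parses ATOM records with \pkg{bio3d}, keeps alternate location 'A' or
#' blank, and splits the atoms into receptor and ligand by chain identifier.
#' Hydrogens are retained and flagged (`is_h`); typing is left to
#' [assign_atom_types()].
#'
#' @param path PDB file.
#' @param receptor_chains,ligand_chains character vectors of chain ids.
#' @return An untyped [typed_structure()].
#' @examples
#' \dontrun{parse_pdb("complex.pdb", "A", "B")}
#' @export
parse_pdb <- function(path, receptor_chains, ligand_chains) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  take <- function(chains, role) {
    sel <- at[at$chain %in% chains, , drop = FALSE]
    if (nrow(sel) == 0L)
      stop("empty partner: no ATOM records for ", role, " chains {",
           paste(chains, collapse = ","), "} in ", path)
    elem <- sel$elesy
    bad <- is.na(elem) | trimws(elem) == ""
    elem[bad] <- element_from_name(sel$elety[bad])
    data.frame(chain = sel$chain, resno = sel$resno,
               insert = ifelse(is.na(sel$insert), "", sel$insert),
               resid = sel$resid, elety = sel$elety,
               x = sel$x, y = sel$y, z = sel$z,
               element = trimws(elem), stringsAsFactors = FALSE)
  }
  typed_structure(take(receptor_chains, "receptor"),
                  take(ligand_chains, "ligand"))
}

#' Write a structure back to PDB
#'
#' Receptor atoms are written first, then ligand atoms, with the chain,
#' residue and atom names held by the structure. Coordinates round to the
#' PDB fixed-column precision of 1e-3 Angstrom.
#'
#' @param s a [typed_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  df <- rbind(s$receptor[names(s$receptor) %in%
                           c("chain", "resno", "insert", "resid", "elety",
                             "x", "y", "z", "element")],
              s$ligand[names(s$ligand) %in%
                         c("chain", "resno", "insert", "resid", "elety",
                           "x", "y", "z", "element")])
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]))),
                   resno = df$resno, resid = df$resid, chain = df$chain,
                   insert = ifelse(df$insert == "", NA, df$insert),
                   elety = df$elety, eleno = seq_len(nrow(df)))
  invisible(path)
}

#' Assign atom types from a typing table
#'
#' Looks each atom up by `(residue name, atom name)`, falling back to the
#' residue's `"H*"` wildcard for hydrogens and to `"*"` residue wildcards.
#' Under the default strict policy an atom with no matching entry raises an
#' error naming the pair; with `unknown = "drop"` such atoms are removed.
#'
#' @param s an (untyped or typed) [typed_structure()].
#' @param table a [typing_table()].
#' @param unknown `"error"` (default) or `"drop"`.
#' @return A typed [typed_structure()] carrying `table` and its hash.
#' @export
assign_atom_types <- function(s, table, unknown = c("error", "drop")) {
  stopifnot(inherits(s, "typed_structure"), inherits(table, "typing_table"))
  unknown <- match.arg(unknown)
  ent <- table$entries
  exact <- setNames(ent$type, paste(ent$residue, ent$atom, sep = "|"))
  type_one <- function(df) {
    res <- toupper(df$resid); atom <- toupper(df$elety)
    t <- unname(exact[paste(res, atom, sep = "|")])
    miss <- is.na(t) & df$is_h
    t[miss] <- unname(exact[paste(res[miss], "H*", sep = "|")])
    miss <- is.na(t)
    t[miss] <- unname(exact[paste("*", atom[miss], sep = "|")])
    miss <- is.na(t) & df$is_h
    t[miss] <- unname(exact["*|H*"])
    if (anyNA(t)) {
      bad <- which(is.na(t))
      if (unknown == "error")
        stop(sprintf("no atom type for (%s, %s) in table '%s'",
                     res[bad[1]], atom[bad[1]], table$name))
      df <- df[-bad, , drop = FALSE]
      t <- t[-bad]
      if (nrow(df) == 0L) stop("all atoms of one partner dropped as unknown")
    }
    df$type <- as.integer(t)
    df$heavy <- table$heavy_flags[df$type + 1L]
    df
  }
  typed_structure(type_one(s$receptor), type_one(s$ligand), table = table)
}

# Apply a rigid motion (3x3 rotation R, length-3 translation t) to one or
# both partners; coordinates are row vectors, x' = x R + t.
transform_partner <- function(s, partner, R, t) {
  xyz <- structure_coords(s, partner) %*% R
  xyz <- sweep(xyz, 2, t, "+")
  s[[partner]][, c("x", "y", "z")] <- xyz
  s
}
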