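#' Atom typing tables
#'
#' A typing table maps `(residue name, atom name)` pairs to integer atom-type
#' indices in `[0, n_types)`. Types marked `heavy` enter buried-surface-area
#' potentials and heavy-atom contact definitions; the remaining types collect
#' hydrogens. Two wildcard forms are supported in `entries`:
#' an `atom` of `"H*"` matches any hydrogen of that residue without an exact
#' entry, and a `residue` of `"*"` matches any residue (useful for toy
#' pseudo-atom tables).
#'
#' @param entries data.frame with columns `residue`, `atom`, `type`
#'   (0-based integer), `label`, `heavy` (logical or 0/1).
#' @param name short identifier for the table.
#' @return An object of class `typing_table` with fields `name`, `n_types`,
#'   `entries`, `labels` (one per type), `heavy_flags` (logical per type) and
#'   a content `hash`.
#' @examples
#' tt <- toy_typing_table(4)
#' tt$n_types
#' @export
typing_table <- function(entries, name = "custom") {
  stopifnot(is.data.frame(entries),
            all(c("residue", "atom", "type", "heavy") %in% names(entries)))
  entries$residue <- toupper(trimws(as.character(entries$residue)))
  entries$atom <- toupper(trimws(as.character(entries$atom)))
  entries$type <- as.integer(entries$type)
  entries$heavy <- as.logical(entries$heavy)
  if (is.null(entries$label)) entries$label <- paste0("T", entries$type)
  if (any(entries$type < 0L)) stop("type indices must be >= 0")
  n_types <- max(entries$type) + 1L
  present <- sort(unique(entries$type))
  if (!identical(present, 0:(n_types - 1L)))
    stop("every type index in [0, n_types) must appear in at least one entry")
  heavy_flags <- logical(n_types)
  labels <- character(n_types)
  for (t in seq_len(n_types) - 1L) {
    rows <- entries[entries$type == t, ]
    hv <- unique(rows$heavy)
    if (length(hv) != 1L)
      stop("inconsistent heavy flag for type ", t)
    heavy_flags[t + 1L] <- hv
    labels[t + 1L] <- rows$label[1L]
  }
  if (!any(heavy_flags)) stop("at least one type must be heavy")
  key <- paste(entries$residue, entries$atom, entries$type, entries$heavy,
               sep = ":", collapse = ";")
  structure(
    list(name = name, n_types = n_types, entries = entries,
         labels = labels, heavy_flags = heavy_flags,
         hash = str_hash(paste(name, n_types, key))),
    class = "typing_table")
}

#' @export
print.typing_table <- function(x, ...) {
  cat(sprintf("typing_table '%s': %d types (%d heavy), %d entries\n",
              x$name, x$n_types, sum(x$heavy_flags), nrow(x$entries)))
  invisible(x)
}

#' Read / write typing tables as TSV
#'
#' Columns: `residue_name`, `atom_name`, `type_index`, `type_label`,
#' `heavy` (0/1).
#'
#' @param path file path.
#' @param name table name (defaults to the file name).
#' @return `read_typing_table()` returns a [typing_table()];
#'   `write_typing_table()` returns `path` invisibly.
#' @export
read_typing_table <- function(path, name = basename(path)) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "", comment.char = "#")
  typing_table(data.frame(residue = df$residue_name, atom = df$atom_name,
                          type = df$type_index, label = df$type_label,
                          heavy = df$heavy != 0),
               name = name)
}

#' @rdname read_typing_table
#' @param table a [typing_table()].
#' @export
write_typing_table <- function(table, path) {
  stopifnot(inherits(table, "typing_table"))
  df <- data.frame(residue_name = table$entries$residue,
                   atom_name = table$entries$atom,
                   type_index = table$entries$type,
                   type_label = table$entries$label,
                   heavy = as.integer(table$entries$heavy))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Canonical index of an unordered atom-type pair
#'
#' Contact potentials are symmetric in the two partners, so parameters are
#' keyed by unordered type pairs. For `n_types` types the unordered pairs
#' map bijectively onto `0 .. n_types*(n_types+1)/2 - 1`, with
#' `canonical_pair_index(a, b) == canonical_pair_index(b, a)` and
#' `(0,0) -> 0`. Vectorized over `a` and `b`.
#'
#' @param a,b 0-based type indices.
#' @param n_types number of atom types.
#' @return 0-based pair index (integer vector).
#' @examples
#' canonical_pair_index(3, 5, 27) == canonical_pair_index(5, 3, 27)
#' @export
canonical_pair_index <- function(a, b, n_types) {
  a <- as.integer(a); b <- as.integer(b)
  if (any(a < 0L | a >= n_types | b < 0L | b >= n_types))
    stop("type index out of range [0, n_types)")
  i <- pmin(a, b); j <- pmax(a, b)
  as.integer(i * n_types - (i * (i - 1L)) %/% 2L + (j - i))
}

#' @rdname canonical_pair_index
#' @export
n_pair_types <- function(n_types) as.integer(n_types * (n_types + 1L) / 2L)

# ---------------------------------------------------------------------------
# Shipped grouped all-atom table (27 types, 23 heavy).
#
# The grouping follows the chemical character of five residue classes
# (non-polar, polar, aromatic, positively charged, negatively charged):
# shared backbone N/CA/C/O types plus per-class side-chain group types, and
# four grouped hydrogen types. This table is a documented reconstruction in
# that spirit, not a verbatim copy of any published supplementary table.
# ---------------------------------------------------------------------------

gaa_heavy_labels <- c(
  "BB_N", "BB_CA", "BB_C", "BB_O",            # 0-3  backbone
  "NP_CH3", "NP_CH2", "NP_CH", "NP_S",        # 4-7  non-polar side chains
  "P_CH2", "P_CH", "P_O", "P_N", "P_C",       # 8-12 polar side chains
  "AR_CH2", "AR_C", "AR_N", "AR_O",           # 13-16 aromatic side chains
  "POS_CH2", "POS_N", "POS_C",                # 17-19 positively charged
  "NEG_CH2", "NEG_C", "NEG_O")                # 20-22 negatively charged
gaa_h_labels <- c("H_BB", "H_NP", "H_P", "H_CHG") # 23-26 grouped hydrogens

# side-chain heavy-atom assignments, per residue: atom name -> type label
gaa_sidechain_map <- list(
  ALA = c(CB = "NP_CH3"),
  VAL = c(CB = "NP_CH", CG1 = "NP_CH3", CG2 = "NP_CH3"),
  LEU = c(CB = "NP_CH2", CG = "NP_CH", CD1 = "NP_CH3", CD2 = "NP_CH3"),
  ILE = c(CB = "NP_CH", CG1 = "NP_CH2", CG2 = "NP_CH3", CD1 = "NP_CH3"),
  PRO = c(CB = "NP_CH2", CG = "NP_CH2", CD = "NP_CH2"),
  MET = c(CB = "NP_CH2", CG = "NP_CH2", SD = "NP_S", CE = "NP_CH3"),
  CYS = c(CB = "NP_CH2", SG = "NP_S"),
  GLY = character(0),
  SER = c(CB = "P_CH2", OG = "P_O"),
  THR = c(CB = "P_CH", OG1 = "P_O", CG2 = "NP_CH3"),
  ASN = c(CB = "P_CH2", CG = "P_C", OD1 = "P_O", ND2 = "P_N"),
  GLN = c(CB = "P_CH2", CG = "P_CH2", CD = "P_C", OE1 = "P_O", NE2 = "P_N"),
  PHE = c(CB = "AR_CH2", CG = "AR_C", CD1 = "AR_C", CD2 = "AR_C",
          CE1 = "AR_C", CE2 = "AR_C", CZ = "AR_C"),
  TYR = c(CB = "AR_CH2", CG = "AR_C", CD1 = "AR_C", CD2 = "AR_C",
          CE1 = "AR_C", CE2 = "AR_C", CZ = "AR_C", OH = "AR_O"),
  TRP = c(CB = "AR_CH2", CG = "AR_C", CD1 = "AR_C", CD2 = "AR_C",
          NE1 = "AR_N", CE2 = "AR_C", CE3 = "AR_C", CZ2 = "AR_C",
          CZ3 = "AR_C", CH2 = "AR_C"),
  HIS = c(CB = "AR_CH2", CG = "AR_C", ND1 = "AR_N", CD2 = "AR_C",
          CE1 = "AR_C", NE2 = "AR_N"),
  LYS = c(CB = "POS_CH2", CG = "POS_CH2", CD = "POS_CH2", CE = "POS_CH2",
          NZ = "POS_N"),
  ARG = c(CB = "POS_CH2", CG = "POS_CH2", CD = "POS_CH2", NE = "POS_N",
          CZ = "POS_C", NH1 = "POS_N", NH2 = "POS_N"),
  ASP = c(CB = "NEG_CH2", CG = "NEG_C", OD1 = "NEG_O", OD2 = "NEG_O"),
  GLU = c(CB = "NEG_CH2", CG = "NEG_CH2", CD = "NEG_C",
          OE1 = "NEG_O", OE2 = "NEG_O"))

# residue class -> hydrogen type for charged/polar side-chain hydrogens
gaa_polar_h_map <- list(
  SER = c(HG = "H_P"), THR = c(HG1 = "H_P"), CYS = c(HG = "H_P"),
  TYR = c(HH = "H_P"), TRP = c(HE1 = "H_P"),
  ASN = c(HD21 = "H_P", HD22 = "H_P"),
  GLN = c(HE21 = "H_P", HE22 = "H_P"),
  HIS = c(HD1 = "H_P", HE2 = "H_P"),
  LYS = c(HZ1 = "H_CHG", HZ2 = "H_CHG", HZ3 = "H_CHG"),
  ARG = c(HE = "H_CHG", HH11 = "H_CHG", HH12 = "H_CHG",
          HH21 = "H_CHG", HH22 = "H_CHG"))

#' Default grouped all-atom typing table
#'
#' A 27-type atomistic representation of the 20 standard amino acids: 23
#' heavy-atom types (shared backbone N/CA/C/O plus side-chain chemical
#' groups per residue class: non-polar CH3/CH2/CH/S, polar CH2/CH/O/N/C,
#' aromatic CH2/ring-C/ring-N/OH, positively charged CH2/N/C, negatively
#' charged CH2/C/O) and 4 grouped hydrogen types (backbone amide, apolar,
#' polar, charged). Named polar/charged hydrogens have explicit entries;
#' all other hydrogens of a residue match its `"H*"` wildcard entry and are
#' typed apolar. This grouping reconstructs a grouped-all-atom scheme from
#' its published description; the verbatim published mapping is not
#' redistributed here.
#'
#' @return A [typing_table()] with `n_types = 27` and 23 heavy types.
#' @examples
#' tt <- default_typing_table()
#' sum(tt$heavy_flags)
#' @export
default_typing_table <- function() {
  labels <- c(gaa_heavy_labels, gaa_h_labels)
  type_of <- setNames(seq_along(labels) - 1L, labels)
  heavy_of <- setNames(c(rep(TRUE, length(gaa_heavy_labels)),
                         rep(FALSE, length(gaa_h_labels))), labels)
  rows <- list()
  add <- function(res, atom, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      residue = res, atom = atom, type = type_of[[label]],
      label = label, heavy = heavy_of[[label]])
  }
  for (res in names(gaa_sidechain_map)) {
    add(res, "N", "BB_N"); add(res, "CA", "BB_CA")
    add(res, "C", "BB_C"); add(res, "O", "BB_O"); add(res, "OXT", "BB_O")
    sc <- gaa_sidechain_map[[res]]
    for (atom in names(sc)) add(res, atom, sc[[atom]])
    # backbone amide hydrogens (incl. N-terminal H1-3)
    for (atom in c("H", "HN", "H1", "H2", "H3")) add(res, atom, "H_BB")
    ph <- gaa_polar_h_map[[res]]
    if (!is.null(ph)) for (atom in names(ph)) add(res, atom, ph[[atom]])
    add(res, "H*", "H_NP") # all remaining hydrogens are carbon-attached
  }
  typing_table(do.call(rbind, rows), name = "gaa27")
}

#' Toy pseudo-atom typing table
#'
#' Small tables for synthetic rigid-body fixtures: residue `"PSD"` with atom
#' names `X0, X1, ...`, one heavy type per atom name.
#'
#' @param n_types number of pseudo-atom types.
#' @return A [typing_table()].
#' @export
toy_typing_table <- function(n_types = 4L) {
  stopifnot(n_types >= 1L)
  typing_table(data.frame(residue = "PSD",
                          atom = paste0("X", seq_len(n_types) - 1L),
                          type = seq_len(n_types) - 1L,
                          label = paste0("X", seq_len(n_types) - 1L),
                          heavy = TRUE),
               name = sprintf("toy%d", n_types))
}
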