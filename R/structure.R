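# Internal coordinate model: a plc_structure is a list with
#   entry_id  PDB accession or fixture id
#   atoms     data.frame(serial, name, alt, resname, chain, resseq, icode,
#                        x, y, z, occupancy, element, record, is_experimental)
#   conect    integer matrix with two columns of atom serials (unordered pairs)
#   model     model number kept from the source file
# Residue identity is the triple (chain, resseq, icode), author numbering.

.standard_aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")
.standard_nuc <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT", "DU")

#' Construct a structure object
#'
#' Low-level constructor used by the PDB reader and the fixture generator.
#'
#' @param entry_id entry identifier (PDB accession or fixture id).
#' @param atoms data frame with the atom columns (see package internals).
#' @param conect two-column integer matrix of bonded atom serial pairs.
#' @param model model number.
#' @return an object of class `plc_structure`.
#' @export
plc_structure <- function(entry_id, atoms, conect = NULL, model = 1L) {
  if (is.null(conect)) conect <- matrix(integer(0), ncol = 2)
  need <- c("serial", "name", "alt", "resname", "chain", "resseq", "icode",
            "x", "y", "z", "occupancy", "element", "record",
            "is_experimental")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (nrow(conect) && !all(conect %in% atoms$serial)) {
    stop("CONECT refers to atom serial(s) absent from the structure")
  }
  structure(
    list(entry_id = entry_id, atoms = atoms,
         conect = conect, model = as.integer(model)),
    class = "plc_structure"
  )
}

#' @export
print.plc_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<plc_structure> %s: %d atoms, %d chains, %d CONECT pairs\n",
              x$entry_id, nrow(a), length(unique(a$chain)), nrow(x$conect)))
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, ]
    cat(sprintf("  chain %s: %d residues (%s)\n", ch,
                length(unique(residue_key(sub))),
                if (chain_is_polymer(x, ch)) "polymer" else "non-polymer"))
  }
  invisible(x)
}

# Residue key strings "chain|resseq|icode" for an atom table.
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$icode, sep = "|")
}

split_residue_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resseq = as.integer(vapply(parts, `[`, "", 2L)),
             icode = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
             stringsAsFactors = FALSE)
}

#' Coordinates of a structure as a matrix
#'
#' @param s a `plc_structure`.
#' @param heavy_only drop hydrogens first.
#' @return numeric matrix with columns x, y, z.
#' @export
structure_xyz <- function(s, heavy_only = FALSE) {
  a <- s$atoms
  if (heavy_only) a <- a[a$element != "H", ]
  as.matrix(a[, c("x", "y", "z")])
}

heavy_atoms <- function(atoms) atoms[atoms$element != "H", , drop = FALSE]

#' Is a chain a biopolymer?
#'
#' A chain is a polymer when it contains at least one ATOM-record residue
#' whose name is a standard amino acid or nucleotide.
#'
#' @param s a `plc_structure`.
#' @param chain_id chain identifier.
#' @return logical scalar.
#' @export
chain_is_polymer <- function(s, chain_id) {
  a <- s$atoms[s$atoms$chain == chain_id, ]
  any(a$record == "ATOM" &
        a$resname %in% c(.standard_aa3, .standard_nuc))
}

# Subset a structure to the atoms selected by a logical vector over rows of
# s$atoms; CONECT pairs with both ends retained are kept.
subset_structure <- function(s, keep) {
  atoms <- s$atoms[keep, , drop = FALSE]
  conect <- s$conect
  if (nrow(conect)) {
    ok <- conect[, 1] %in% atoms$serial & conect[, 2] %in% atoms$serial
    conect <- conect[ok, , drop = FALSE]
  }
  plc_structure(s$entry_id, atoms, conect, s$model)
}

# Order atoms by (chain, resseq, icode, serial); residue ordering invariant.
order_structure_atoms <- function(atoms) {
  atoms[order(atoms$chain, atoms$resseq, atoms$icode, atoms$serial), ,
        drop = FALSE]
}
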