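# Linear-peptide SMILES construction from one-letter sequence, used as the
# reference chemistry for short polymer ligands made of alpha-amino acids.

.aa_side_smiles <- c(
  A = "C",
  R = "CCCNC(=N)N",
  N = "CC(N)=O",
  D = "CC(O)=O",
  C = "CS",
  Q = "CCC(N)=O",
  E = "CCC(O)=O",
  H = "Cc1c[nH]cn1",
  I = "C(C)CC",
  L = "CC(C)C",
  K = "CCCCN",
  M = "CCSC",
  F = "Cc1ccccc1",
  S = "CO",
  T = "C(O)C",
  W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1",
  V = "C(C)C"
)

#' Build a reference SMILES for a linear peptide
#'
#' Chains standard alpha-amino acids with amide bonds, free (neutral)
#' N- and C-termini and L-alpha stereocenters; protonation is applied by
#' the later rule stage, not here. Cyclic peptides and disulfide-linked
#' sequences are out of scope and yield a mismatch downstream.
#'
#' @param sequence one-letter amino-acid string, length >= 2.
#' @return an object of class `plc_reference` (fields `smiles`, `source`,
#'   `net_charge`).
#' @export
peptide_smiles <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) < 2L) {
    stop("peptide reference requires at least 2 residues")
  }
  known <- c(names(.aa_side_smiles), "G", "P")
  bad <- setdiff(letters1, known)
  if (length(bad)) {
    stop("unsupported residue(s) for peptide reference: ",
         paste(bad, collapse = ", "))
  }
  unit <- vapply(letters1, function(a) {
    switch(a,
      G = "NCC(=O)",
      P = "N1CCC[C@H]1C(=O)",
      paste0("N[C@@H](", .aa_side_smiles[[a]], ")C(=O)"))
  }, "")
  smiles <- paste0(paste(unit, collapse = ""), "O")
  new_reference(smiles, "peptide-builder")
}

new_reference <- function(smiles, source) {
  smiles <- largest_organic_fragment(smiles)
  mol <- mol_from_smiles(smiles)
  structure(list(smiles = smiles, source = source,
                 net_charge = mol_net_charge(mol)),
            class = "plc_reference")
}

#' @export
print.plc_reference <- function(x, ...) {
  cat(sprintf("<plc_reference> %s (source: %s, net charge %+d)\n",
              x$smiles, x$source, x$net_charge))
  invisible(x)
}
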