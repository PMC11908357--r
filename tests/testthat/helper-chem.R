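# Shared helpers: build ligand objects from SMILES, compare molecule
# graphs chemically, rotate side chains for rotamer tests.

# Embed a SMILES in 3D, strip hydrogens (and implicitly all chemistry a
# PDB would not carry) and wrap as a crystal-style ligand object.
smiles_ligand <- function(smi, key = "L|1|") {
  m3 <- plcurate:::strip_hydrogens(mol_from_smiles(smi, coords = "3d"))
  atoms <- data.frame(
    serial = seq_len(nrow(m3$atoms)),
    name = paste0(m3$atoms$element, seq_len(nrow(m3$atoms))),
    alt = "", resname = "LIG", chain = "L", resseq = 1L, icode = "",
    x = m3$atoms$x, y = m3$atoms$y, z = m3$atoms$z, occupancy = 1,
    element = m3$atoms$element, record = "HETATM",
    is_experimental = TRUE, stringsAsFactors = FALSE)
  plcurate:::new_ligand(ligand_spec("ccd", ccd_code = "LIG"), atoms, key)
}

# Chemical graph equality: element+charge-labelled isomorphism with at
# least one mapping under which all bond orders agree.
chem_equal <- function(a, b) {
  a <- plcurate:::strip_hydrogens(a)
  b <- plcurate:::strip_hydrogens(b)
  if (nrow(a$atoms) != nrow(b$atoms)) return(FALSE)
  ga <- mol_to_igraph(a, heavy_only = FALSE)
  gb <- mol_to_igraph(b, heavy_only = FALSE)
  lv <- unique(c(paste(a$atoms$element, a$atoms$charge),
                 paste(b$atoms$element, b$atoms$charge)))
  ca <- as.integer(factor(paste(a$atoms$element, a$atoms$charge), lv))
  cb <- as.integer(factor(paste(b$atoms$element, b$atoms$charge), lv))
  maps <- tryCatch(
    igraph::graph.get.isomorphisms.vf2(ga, gb, vertex.color1 = ca,
                                       vertex.color2 = cb),
    error = function(e) list())
  for (mp in maps) {
    mp <- as.integer(mp)
    ok <- TRUE
    for (k in seq_len(nrow(a$bonds))) {
      if (plcurate:::bond_order_between(b, mp[a$bonds$i[k]],
                                        mp[a$bonds$j[k]]) !=
          a$bonds$order[k]) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Rotate the side-chain atoms of one residue about its CA-CB axis.
rotate_side_chain <- function(atoms, resseq, angle_deg) {
  sel <- atoms$resseq == resseq
  res <- atoms[sel, ]
  ca <- unlist(res[res$name == "CA", c("x", "y", "z")])
  cb <- unlist(res[res$name == "CB", c("x", "y", "z")])
  axis <- (cb - ca) / sqrt(sum((cb - ca)^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  move <- sel & !atoms$name %in% c("N", "CA", "C", "O", "CB")
  xyz <- as.matrix(atoms[move, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, cb) %*% t(R), 2, cb, "+")
  atoms[move, c("x", "y", "z")] <- xyz
  atoms
}

# 50-molecule drug-like panel for the ligand round-trip property
# (shipped with the package so the acceptance script shares it).
drug_panel <- readLines(system.file("extdata", "drug_panel.smi",
                                    package = "plcurate"))

# One full embed -> strip -> fix cycle; TRUE when the fixed molecule is
# chemically identical to the protonated reference.
ligand_roundtrip_ok <- function(smi) {
  lig <- smiles_ligand(smi)
  out <- fix_ligand(lig, reference = smi)
  if (out$status != "fixed") return(FALSE)
  ref <- assign_protonation(mol_from_smiles(smi))
  chem_equal(out$mol, ref)
}
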