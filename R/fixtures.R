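# Deterministic synthetic-complex generator: an ideal-geometry polyalanine
# helix receptor (with optional named side-chain substitutions), a
# co-crystallized small-molecule ligand with hydrogens stripped and bond
# orders absent (as in deposited PDB files), and injectable defects so
# every filter and fixer stage can be triggered on demand. Generation is a
# pure function of (spec, seed).

#' Specification for a synthetic protein-ligand fixture
#'
#' @param seed integer seed controlling ligand placement jitter.
#' @param n_res receptor helix length in residues.
#' @param substitutions named list mapping residue position (as character
#'   or integer) to a residue name, e.g. `list("5" = "LYS")`. The default
#'   places one LYS, ASP, HIS and CYS on the polyalanine helix.
#' @param ligand_smiles SMILES of the co-crystallized ligand (default a
#'   benzamidine-like aromatic amidine).
#' @param placement target minimum ligand-protein heavy-atom distance in
#'   angstroms.
#' @param defects character vector of defect tags from:
#'   `delete_ligand_atom`, `delete_side_chain_atom`,
#'   `delete_internal_segment`, `delete_terminal_segment`,
#'   `add_covalent_conect`, `swap_element_to`, `create_clash`,
#'   `tiny_ligand`, `corrupt_reference_all_single`.
#' @param segment_length length for the segment-deletion defects.
#' @param swap_element element for `swap_element_to`.
#' @param clash_distance distance for `create_clash` (A).
#' @param entry_id synthetic accession written into the files.
#' @return an object of class `plc_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_res = 20L,
                         substitutions = list("5" = "LYS", "8" = "ASP",
                                              "12" = "HIS", "15" = "CYS"),
                         ligand_smiles = "NC(=N)c1ccccc1",
                         placement = 3.5,
                         defects = character(0),
                         segment_length = 4L,
                         swap_element = "Se",
                         clash_distance = 1.5,
                         entry_id = "9XYZ") {
  known <- c("delete_ligand_atom", "delete_side_chain_atom",
             "delete_internal_segment", "delete_terminal_segment",
             "add_covalent_conect", "swap_element_to", "create_clash",
             "tiny_ligand", "corrupt_reference_all_single")
  bad <- setdiff(defects, known)
  if (length(bad)) {
    stop("unknown defect tag(s): ", paste(bad, collapse = ", "))
  }
  if ("tiny_ligand" %in% defects && "delete_ligand_atom" %in% defects) {
    stop("fixture spec error: tiny_ligand cannot be combined with ",
         "delete_ligand_atom")
  }
  if (n_res < 6L) stop("receptor must have at least 6 residues")
  structure(list(seed = as.integer(seed), n_res = as.integer(n_res),
                 substitutions = substitutions,
                 ligand_smiles = ligand_smiles, placement = placement,
                 defects = defects,
                 segment_length = as.integer(segment_length),
                 swap_element = swap_element,
                 clash_distance = clash_distance, entry_id = entry_id),
            class = "plc_fixture_spec")
}

#' Generate a synthetic fixture
#'
#' Builds the receptor helix and ligand, applies the requested defects,
#' and returns the file contents a deposited entry would provide: PDB
#' text (ligand as HETATM residue `LIG` with intra-ligand CONECT),
#' mmCIF-style header declaring the full receptor sequence (including any
#' deleted segments), the reference SMILES (corrupted if so requested),
#' and a machine-readable manifest of the stage outcomes the defects must
#' trigger.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `plc_fixture` with elements `pdb` (lines),
#'   `cif` (lines), `reference_smiles`, `manifest`, `spec`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  lig_smiles <- if ("tiny_ligand" %in% spec$defects) "O=C=O"
                else spec$ligand_smiles

  prot <- build_helix(spec$n_res, spec$substitutions)
  lig <- build_ligand_atoms(lig_smiles, prot, spec$placement,
                            serial_start = max(prot$atoms$serial) + 1L)
  lig_atoms <- lig$atoms
  lig_bonds <- lig$bonds
  removed_res <- integer(0)
  manifest <- list(expect = "fixed", filter_failures = character(0),
                   repairs = list())

  for (defect in spec$defects) {
    if (defect == "delete_ligand_atom") {
      # remove a terminal heavy atom so connectivity no longer matches
      deg <- tabulate(c(lig_bonds$i, lig_bonds$j), nbins = nrow(lig_atoms))
      drop <- max(which(deg == 1L))
      keep <- setdiff(seq_len(nrow(lig_atoms)), drop)
      remap <- match(seq_len(nrow(lig_atoms)), keep)
      lig_bonds <- lig_bonds[lig_bonds$i != drop & lig_bonds$j != drop, ]
      lig_bonds$i <- remap[lig_bonds$i]
      lig_bonds$j <- remap[lig_bonds$j]
      lig_atoms <- lig_atoms[keep, , drop = FALSE]
      manifest$expect <- "fix-failed"
      manifest$ligand_status <- "mismatch"
    } else if (defect == "delete_side_chain_atom") {
      target <- find_side_chain_target(prot$atoms, spec$substitutions)
      prot$atoms <- prot$atoms[!(prot$atoms$resseq == target$resseq &
                                   prot$atoms$name == target$atom), ]
      manifest$repairs$missing_atom <-
        list(resseq = target$resseq, atom = target$atom)
    } else if (defect == "delete_internal_segment") {
      mid <- floor(spec$n_res / 2)
      removed <- seq(mid, mid + spec$segment_length - 1L)
      prot$atoms <- prot$atoms[!prot$atoms$resseq %in% removed, ]
      removed_res <- c(removed_res, removed)
      manifest$repairs$internal_segment <- list(
        resseq = removed,
        rebuilt = spec$segment_length <= 10L)
    } else if (defect == "delete_terminal_segment") {
      removed <- seq(spec$n_res - spec$segment_length + 1L, spec$n_res)
      prot$atoms <- prot$atoms[!prot$atoms$resseq %in% removed, ]
      removed_res <- c(removed_res, removed)
      manifest$repairs$terminal_segment <- list(resseq = removed,
                                                rebuilt = FALSE)
    } else if (defect == "add_covalent_conect") {
      d <- min_pair_distance(
        as.matrix(lig_atoms[, c("x", "y", "z")]),
        as.matrix(prot$atoms[prot$atoms$element != "H", c("x", "y", "z")]))
      prot_heavy <- prot$atoms[prot$atoms$element != "H", ]
      manifest$conect_extra <- c(lig_atoms$serial[d$i],
                                 prot_heavy$serial[d$j])
      manifest$expect <- "filter-rejected"
      manifest$filter_failures <- union(manifest$filter_failures, "covalent")
    } else if (defect == "swap_element_to") {
      carbon <- which(lig_atoms$element == "C")[1L]
      lig_atoms$element[carbon] <- spec$swap_element
      lig_atoms$name[carbon] <- paste0(toupper(spec$swap_element), "1")
      manifest$expect <- "filter-rejected"
      manifest$filter_failures <- union(manifest$filter_failures,
                                        "rare_element")
    } else if (defect == "create_clash") {
      d <- min_pair_distance(
        as.matrix(lig_atoms[, c("x", "y", "z")]),
        as.matrix(prot$atoms[prot$atoms$element != "H", c("x", "y", "z")]))
      prot_heavy <- prot$atoms[prot$atoms$element != "H", ]
      pv <- unlist(prot_heavy[d$j, c("x", "y", "z")])
      lv <- unlist(lig_atoms[d$i, c("x", "y", "z")])
      shift <- unit(pv - lv) * (d$min - spec$clash_distance)
      lig_atoms$x <- lig_atoms$x + shift[1]
      lig_atoms$y <- lig_atoms$y + shift[2]
      lig_atoms$z <- lig_atoms$z + shift[3]
      manifest$expect <- "filter-rejected"
      manifest$filter_failures <- union(manifest$filter_failures, "clash")
      manifest$clash_distance <- spec$clash_distance
    } else if (defect == "tiny_ligand") {
      manifest$expect <- "filter-rejected"
      manifest$filter_failures <- union(manifest$filter_failures,
                                        "small_ligand")
    } else if (defect == "corrupt_reference_all_single") {
      manifest$expect <- "fix-failed"
      manifest$ligand_status <- "bad-reference"
    }
  }

  all_atoms <- rbind(prot$atoms, lig_atoms)
  conect <- cbind(lig_atoms$serial[lig_bonds$i], lig_atoms$serial[lig_bonds$j])
  if (!is.null(manifest$conect_extra)) {
    conect <- rbind(conect, manifest$conect_extra)
  }
  s <- plc_structure(spec$entry_id, order_structure_atoms(all_atoms),
                     conect)
  pdb <- write_pdb(s)

  sequences <- list(A = list(
    seq3 = prot$seq3,
    resseq = seq_len(spec$n_res),
    modeled = !(seq_len(spec$n_res) %in% removed_res)))
  cif <- write_mmcif_header(spec$entry_id, sequences)

  reference <- if ("corrupt_reference_all_single" %in% spec$defects) {
    saturate_smiles(lig_smiles)
  } else {
    lig_smiles
  }
  structure(list(pdb = pdb, cif = cif, reference_smiles = reference,
                 manifest = manifest, spec = spec),
            class = "plc_fixture")
}

#' Write a fixture to disk
#'
#' @param fixture a `plc_fixture`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths (`pdb`, `cif`, `smiles`,
#'   `manifest`).
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- tolower(fixture$spec$entry_id)
  paths <- c(pdb = file.path(dir, paste0(id, ".pdb")),
             cif = file.path(dir, paste0(id, ".cif")),
             smiles = file.path(dir, paste0(id, ".smi")),
             manifest = file.path(dir, paste0(id, "_manifest.json")))
  writeLines(fixture$pdb, paths["pdb"])
  writeLines(fixture$cif, paths["cif"])
  writeLines(fixture$reference_smiles, paths["smiles"])
  jsonlite::write_json(fixture$manifest, paths["manifest"],
                       auto_unbox = TRUE, pretty = TRUE)
  paths
}

# ---- receptor construction ------------------------------------------------

# NeRF placement: position of atom d given bonded chain a-b-c, the c-d
# bond length, b-c-d angle and a-b-c-d torsion (degrees).
place_atom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c_ - b)
  n <- unit(c(
    (b - a)[2] * bc[3] - (b - a)[3] * bc[2],
    (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
    (b - a)[1] * bc[2] - (b - a)[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal alpha-helix backbone (phi -57, psi -47, omega 180) with standard
# bond geometry; side chains grown from the CB direction via templates.
build_helix <- function(n_res, substitutions) {
  subs <- stats::setNames(
    toupper(unlist(substitutions)),
    as.integer(names(substitutions)))
  seq3 <- rep("ALA", n_res)
  if (length(subs)) seq3[as.integer(names(subs))] <- subs

  phi <- -57; psi <- -47; omega <- 180
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7

  rows <- list()
  serial <- 0L
  add_atom <- function(name, element, pos, resseq, resname) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, alt = "", resname = resname,
      chain = "A", resseq = resseq, icode = "", x = pos[1], y = pos[2],
      z = pos[3], occupancy = 1, element = element, record = "ATOM",
      is_experimental = TRUE, stringsAsFactors = FALSE)
  }

  # first residue laid out explicitly
  n_pos <- c(0, 0, 0)
  ca_pos <- c(b_nca, 0, 0)
  c_pos <- place_atom(c(-1, 0.5, 0), n_pos, ca_pos, b_cac, a_ncac, psi + 120)
  prev <- list(N = n_pos, CA = ca_pos, C = c_pos)
  backbone <- list(prev)
  for (i in 2:n_res) {
    n_i <- place_atom(backbone[[i - 1]]$N, backbone[[i - 1]]$CA,
                      backbone[[i - 1]]$C, b_cn, a_cacn, psi)
    ca_i <- place_atom(backbone[[i - 1]]$CA, backbone[[i - 1]]$C, n_i,
                       b_nca, a_cnca, omega)
    c_i <- place_atom(backbone[[i - 1]]$C, n_i, ca_i, b_cac, a_ncac, phi)
    backbone[[i]] <- list(N = n_i, CA = ca_i, C = c_i)
  }
  for (i in seq_len(n_res)) {
    bb <- backbone[[i]]
    add_atom("N", "N", bb$N, i, seq3[i])
    add_atom("CA", "C", bb$CA, i, seq3[i])
    add_atom("C", "C", bb$C, i, seq3[i])
    # carbonyl O from the next N (or ideal psi+180 for the last residue)
    o_pos <- if (i < n_res) {
      place_atom(backbone[[i + 1]]$N, bb$CA, bb$C, b_co, 120.5, 180)
    } else {
      place_atom(bb$N, bb$CA, bb$C, b_co, 120.5, psi + 180)
    }
    add_atom("O", "O", o_pos, i, seq3[i])
    if (seq3[i] != "GLY") {
      cb <- place_atom(bb$C, bb$N, bb$CA, 1.521, 110.4, 122.6)
      add_atom("CB", "C", cb, i, seq3[i])
    }
  }
  atoms <- do.call(rbind, rows)

  # grow substituted side chains from templates fit on N/CA/C/CB
  for (i in names(subs)) {
    resseq <- as.integer(i)
    sel <- atoms$resseq == resseq
    res <- atoms[sel, ]
    t <- fit_template(res, subs[[i]])
    extra <- t[t$element != "H" &
                 !t$atom %in% c(res$name, "OXT"), , drop = FALSE]
    if (!nrow(extra)) next
    newa <- data.frame(
      serial = max(atoms$serial) + seq_len(nrow(extra)),
      name = extra$atom, alt = "", resname = subs[[i]], chain = "A",
      resseq = resseq, icode = "", x = extra$x, y = extra$y, z = extra$z,
      occupancy = 1, element = extra$element, record = "ATOM",
      is_experimental = TRUE, stringsAsFactors = FALSE)
    atoms <- rbind(atoms, newa)
  }
  list(atoms = order_structure_atoms(renumber_serials(atoms)), seq3 = seq3)
}

renumber_serials <- function(atoms) {
  atoms <- atoms[order(atoms$resseq, atoms$serial), ]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  atoms
}

# Embed the ligand SMILES in 3D, strip hydrogens and bond orders are kept
# only as CONECT connectivity; place it at the requested minimum distance
# from the receptor with a seeded direction jitter.
build_ligand_atoms <- function(smiles, prot, placement, serial_start) {
  mol <- mol_from_smiles(smiles, coords = "3d")
  mol <- strip_hydrogens(mol)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))

  pxyz <- as.matrix(prot$atoms[, c("x", "y", "z")])
  ca <- prot$atoms[prot$atoms$name == "CA", ]
  axis <- unit(unlist(ca[nrow(ca), c("x", "y", "z")]) -
                 unlist(ca[1, c("x", "y", "z")]))
  center <- colMeans(pxyz)
  # perpendicular direction with seeded jitter
  ref <- c(axis[2], -axis[1], 0)
  if (vnorm(ref) < 1e-6) ref <- c(1, 0, 0)
  perp1 <- unit(ref - sum(ref * axis) * axis)
  perp2 <- c(axis[2] * perp1[3] - axis[3] * perp1[2],
             axis[3] * perp1[1] - axis[1] * perp1[3],
             axis[1] * perp1[2] - axis[2] * perp1[1])
  theta <- stats::runif(1, 0, 2 * pi)
  dir <- cos(theta) * perp1 + sin(theta) * perp2

  # start far out and pull in to the requested minimum distance; the
  # nearest pair changes as the ligand moves, so iterate to convergence
  pos <- center + dir * 30
  cand <- sweep(xyz, 2, pos, "+")
  for (pass in 1:25) {
    d <- min_pair_distance(cand, pxyz)
    if (abs(d$min - placement) < 0.02) break
    cand <- sweep(cand, 2, dir * (d$min - placement))
  }

  atoms <- data.frame(
    serial = serial_start + seq_len(nrow(cand)) - 1L,
    name = make.unique(paste0(mol$atoms$element,
                              seq_len(nrow(cand))), sep = ""),
    alt = "", resname = "LIG", chain = "L", resseq = 1L, icode = "",
    x = cand[, 1], y = cand[, 2], z = cand[, 3], occupancy = 1,
    element = mol$atoms$element, record = "HETATM",
    is_experimental = TRUE, stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = mol$bonds)
}

find_side_chain_target <- function(atoms, substitutions) {
  # prefer the terminal side-chain atom of a substituted residue
  tip <- c(LYS = "NZ", ASP = "OD2", HIS = "NE2", CYS = "SG", SER = "OG",
           GLU = "OE2", ARG = "NH2")
  for (pos in names(substitutions)) {
    rn <- toupper(substitutions[[pos]])
    if (rn %in% names(tip)) {
      sel <- atoms$resseq == as.integer(pos) & atoms$name == tip[[rn]]
      if (any(sel)) {
        return(list(resseq = as.integer(pos), atom = tip[[rn]]))
      }
    }
  }
  # fall back to a CB on the polyalanine body
  cb <- atoms[atoms$name == "CB", ]
  list(resseq = cb$resseq[1L], atom = "CB")
}

# all-single-bond, aromaticity-free version of a SMILES (the classic
# corrupt deposited reference)
saturate_smiles <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  mol <- strip_hydrogens(mol)
  mol$bonds$order <- 1L
  mol$bonds$aromatic <- FALSE
  mol$atoms$aromatic <- FALSE
  mol$atoms$charge <- 0L
  mol$atoms$hyb <- "sp3"
  mol_to_smiles(mol)
}
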