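# Dataset characterization: side-chain rotamer changes between identical
# chains, superposed RMSD, and ligand drug-likeness profiles.

# Standard side-chain torsion definitions (chi1-chi4). ARG chi5 is excluded
# entirely; terminal torsions with two equivalent atoms are flagged
# symmetric and folded by 180 degrees when compared.
.chi_defs <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

# torsions whose terminal atom pair is chemically equivalent: differences
# are compared modulo 180 degrees
.chi_symmetric <- list(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)

#' Side-chain chi angles of one residue
#'
#' @param res atom table of a single residue.
#' @return numeric vector of defined chi angles in degrees, `(-180, 180]`
#'   (`NA` where atoms are missing); zero-length for residues without
#'   side-chain torsions (GLY/ALA).
#' @export
chi_angles <- function(res) {
  defs <- .chi_defs[[res$resname[1L]]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(quad) {
    idx <- match(quad, res$name)
    if (anyNA(idx)) return(NA_real_)
    xyz <- as.matrix(res[idx, c("x", "y", "z")])
    dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  }, 1.0)
}

# periodic chi difference honoring terminal-atom symmetry
chi_difference <- function(a, b, resname, which_chi) {
  d <- angle_diff_periodic(a, b)
  sym <- .chi_symmetric[[resname]]
  if (!is.null(sym) && which_chi == sym) d <- pmin(d, 180 - d)
  d
}

#' Compare side-chain rotamer states between two identical chains
#'
#' Residues are paired by residue number across the two chains (the
#' chains must be sequence-identical over the paired span). A residue is
#' near the binding site when any heavy atom lies within `site_cutoff` of
#' a ligand heavy atom in either chain's frame. A rotamer change is any
#' defined chi angle differing by more than `rotamer_angle_cutoff` under
#' the periodic difference; GLY/ALA carry no chi and are excluded from
#' the counts. Swapping the chains leaves flags and counts unchanged.
#'
#' @param chain_a,chain_b atom tables (e.g. `s$atoms` subset to one chain
#'   each).
#' @param ligand a `plc_ligand` (or atom table) giving the binding-site
#'   frame.
#' @param site_cutoff near-site distance in angstroms; defaults to the
#'   protein-association cutoff.
#' @param cfg a [plc_config()].
#' @return an object of class `plc_rotamer_comparison`: list with
#'   `residues` (per-residue data frame: resseq, resname, near_site,
#'   max_chi_diff, changed) and counts `n_near_site`, `n_changed`.
#' @export
compare_rotamers <- function(chain_a, chain_b, ligand,
                             site_cutoff = NULL, cfg = plc_config()) {
  if (is.null(site_cutoff)) site_cutoff <- cfg$protein_assoc_cutoff
  lig_atoms <- if (inherits(ligand, "plc_ligand")) ligand$atoms else ligand
  lig_xyz <- as.matrix(heavy_atoms(lig_atoms)[, c("x", "y", "z")])

  ka <- paste(chain_a$resseq, chain_a$icode)
  kb <- paste(chain_b$resseq, chain_b$icode)
  shared <- intersect(unique(ka), unique(kb))
  rows <- list()
  for (key in shared) {
    ra <- chain_a[ka == key, , drop = FALSE]
    rb <- chain_b[kb == key, , drop = FALSE]
    if (ra$resname[1L] != rb$resname[1L]) {
      stop("pairing error: residue ", key, " is ", ra$resname[1L],
           " in one chain and ", rb$resname[1L], " in the other")
    }
    resname <- ra$resname[1L]
    near <- residue_near_site(ra, lig_xyz, site_cutoff) ||
      residue_near_site(rb, lig_xyz, site_cutoff)
    chis_a <- chi_angles(ra)
    chis_b <- chi_angles(rb)
    has_chi <- length(chis_a) > 0L
    maxd <- NA_real_
    changed <- NA
    if (has_chi) {
      diffs <- vapply(seq_along(chis_a), function(k) {
        if (is.na(chis_a[k]) || is.na(chis_b[k])) return(NA_real_)
        chi_difference(chis_a[k], chis_b[k], resname, k)
      }, 1.0)
      if (any(!is.na(diffs))) {
        maxd <- max(diffs, na.rm = TRUE)
        changed <- any(diffs > cfg$rotamer_angle_cutoff, na.rm = TRUE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      resseq = ra$resseq[1L], icode = ra$icode[1L], resname = resname,
      near_site = near, has_chi = has_chi, max_chi_diff = maxd,
      changed = changed, stringsAsFactors = FALSE)
  }
  residues <- do.call(rbind, rows)
  countable <- residues$near_site & residues$has_chi & !is.na(residues$changed)
  structure(list(
    residues = residues,
    n_near_site = sum(countable),
    n_changed = sum(residues$changed[countable])
  ), class = "plc_rotamer_comparison")
}

residue_near_site <- function(res, lig_xyz, cutoff) {
  ra <- heavy_atoms(res)
  if (!nrow(ra)) return(FALSE)
  min_pair_distance(as.matrix(ra[, c("x", "y", "z")]), lig_xyz)$min < cutoff
}

#' @export
print.plc_rotamer_comparison <- function(x, ...) {
  cat(sprintf(
    "<plc_rotamer_comparison> %d/%d near-site residues change rotamer state\n",
    x$n_changed, x$n_near_site))
  invisible(x)
}

#' Root-mean-square deviation after optimal superposition
#'
#' Least-squares rigid-body superposition (rotation + translation) of two
#' matched coordinate sets, then RMSD. Invariant under any rigid
#' transform of either input.
#'
#' @param a,b n x 3 coordinate matrices with one-to-one row
#'   correspondence.
#' @param fit superpose before measuring (default `TRUE`).
#' @return RMSD in angstroms.
#' @export
compute_rmsd <- function(a, b, fit = TRUE) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop("correspondence error: coordinate sets differ in size (",
         nrow(a), " vs ", nrow(b), " points)")
  }
  if (fit && nrow(a) >= 3L) {
    k <- kabsch(a, b)
    a <- apply_kabsch(a, k)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

# ---- drug-likeness profile ------------------------------------------------

#' Drug-likeness property profile of a ligand
#'
#' Computes the eight standard descriptors: molecular weight, computed
#' logP and topological polar surface area (both via OpenBabel's
#' implementations of the published fragment-contribution methods),
#' rotatable-bond count (non-ring single bonds between non-terminal heavy
#' atoms, amides excluded), heavy-atom count, hydrogen-bond donors (N/O/S
#' with attached H) and acceptors (N/O), and the QED desirability
#' composite in [0, 1] built from the published desirability-function
#' parameters.
#'
#' @param mol a `plc_mol` with fixed chemistry (orders, charges, explicit
#'   hydrogens).
#' @return an object of class `plc_property_profile` (named list of the
#'   eight descriptors).
#' @export
ligand_properties <- function(mol) {
  a <- mol$atoms
  n_heavy <- sum(a$element != "H")
  mw <- sum(atomic_mass(a$element))
  hbd <- count_hb_donors(mol)
  hba <- sum(a$element %in% c("N", "O"))
  rotb <- count_rotatable_bonds(mol)
  arom <- length(aromatic_rings(mol))
  obp <- ob_properties(mol)
  qed <- qed_score(mw = mw, alogp = obp$logP, hba = hba, hbd = hbd,
                   psa = obp$TPSA, rotb = rotb, arom = arom, alerts = 0L)
  structure(list(
    molecular_weight = mw, clogp = obp$logP, tpsa = obp$TPSA,
    n_rotatable_bonds = rotb, n_heavy_atoms = n_heavy, n_hbd = hbd,
    n_hba = hba, qed = qed
  ), class = "plc_property_profile")
}

#' @export
print.plc_property_profile <- function(x, ...) {
  cat(sprintf(
    "<plc_property_profile> MW %.2f Da, clogP %.2f, TPSA %.1f A^2, %d rotatable, %d heavy, HBD %d, HBA %d, QED %.3f\n",
    x$molecular_weight, x$clogp, x$tpsa, x$n_rotatable_bonds,
    x$n_heavy_atoms, x$n_hbd, x$n_hba, x$qed))
  invisible(x)
}

ob_properties <- function(mol) {
  sdf <- write_sdf(mol)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(strsplit(sdf, "\n")[[1]], tmp)
  sdfset <- ChemmineR::read.SDFset(tmp)
  p <- ChemmineR::propOB(sdfset[1])
  list(logP = p$logP[1], TPSA = p$TPSA[1])
}

count_hb_donors <- function(mol) {
  el <- mol$atoms$element
  n <- 0L
  for (k in which(el %in% c("N", "O", "S"))) {
    nb <- mol_neighbors(mol, k)
    if (any(el[nb] == "H")) n <- n + 1L
  }
  n
}

count_rotatable_bonds <- function(mol) {
  ring_edges <- ring_edge_keys(mol)
  el <- mol$atoms$element
  n <- 0L
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]
    j <- mol$bonds$j[b]
    if (el[i] == "H" || el[j] == "H") next
    if (mol$bonds$order[b] != 1L || mol$bonds$aromatic[b]) next
    if (paste(min(i, j), max(i, j)) %in% ring_edges) next
    if (heavy_degree(mol, i) < 2L || heavy_degree(mol, j) < 2L) next
    # amide C-N bonds are not rotatable
    amide <- (el[i] == "C" && el[j] == "N" &&
                has_neighbor(mol, i, "O", order = 2L)) ||
      (el[j] == "C" && el[i] == "N" &&
         has_neighbor(mol, j, "O", order = 2L))
    if (amide) next
    n <- n + 1L
  }
  n
}

ring_edge_keys <- function(mol) {
  rings <- find_rings(strip_hydrogens(mol), max_size = 8L)
  hmap <- which(mol$atoms$element != "H")
  keys <- character(0)
  for (r in rings) {
    rr <- hmap[r]
    k <- length(rr)
    for (idx in seq_len(k)) {
      a <- rr[idx]
      b <- rr[if (idx == k) 1L else idx + 1L]
      keys <- c(keys, paste(min(a, b), max(a, b)))
    }
  }
  unique(keys)
}

aromatic_rings <- function(mol) {
  m <- strip_hydrogens(mol)
  rings <- find_rings(m, max_size = 6L)
  Filter(function(r) all(m$atoms$aromatic[r]), rings)
}

# QED: published asymmetric-double-sigmoid desirability parameters
# (a, b, c, d, e, f, dmax per descriptor) and mean weights.
.qed_ads <- list(
  MW = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677,
         65.37051707, 104.9805561),
  ALOGP = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
            0.822739154, 0.576295591, 131.3186604),
  HBA = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953,
          1.300669958, 148.7763046),
  HBD = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843,
          0.920922555, 258.1632616),
  PSA = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824,
          28.51324732, 104.5686167),
  ROTB = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166,
           2.758063707, 105.4420403),
  AROM = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384,
           0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001,
             0.185904477, 0.875193782, 417.7253140)
)
.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  v <- p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  max(v / p[7], 1e-10)
}

#' QED drug-likeness score from its eight descriptors
#'
#' Weighted geometric mean of the desirability functions over molecular
#' weight, computed logP, acceptor and donor counts, polar surface area,
#' rotatable bonds, aromatic rings and structural alerts.
#'
#' @param mw,alogp,hba,hbd,psa,rotb,arom,alerts descriptor values.
#' @return QED in [0, 1].
#' @export
qed_score <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts = 0) {
  x <- c(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd, PSA = psa,
         ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(names(.qed_ads),
              function(k) qed_ads(x[[k]], .qed_ads[[k]]), 1.0)
  w <- .qed_weights[names(.qed_ads)]
  exp(sum(w * log(d)) / sum(w))
}
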