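# Splitting deposited structures into ligand / protein / additive roles.

#' Describe a ligand to look for
#'
#' A ligand spec names either a small-molecule residue by its Chemical
#' Component Dictionary (CCD) code, or a short polymer ligand (peptide,
#' oligosaccharide, oligonucleotide) by its chain (and optionally a
#' residue span).
#'
#' @param kind `"ccd"` or `"polymer"`.
#' @param ccd_code CCD code (kind = `"ccd"`).
#' @param chain_id chain identifier (kind = `"polymer"`).
#' @param res_start,res_end optional residue span bounds (kind =
#'   `"polymer"`); default is the whole chain.
#' @param source free-text provenance (which reference dataset row named
#'   this ligand).
#' @return an object of class `plc_ligand_spec`.
#' @export
ligand_spec <- function(kind = c("ccd", "polymer"), ccd_code = NULL,
                        chain_id = NULL, res_start = NULL, res_end = NULL,
                        source = "user") {
  kind <- match.arg(kind)
  if (kind == "ccd" && is.null(ccd_code)) {
    stop("ccd ligand spec requires ccd_code")
  }
  if (kind == "polymer" && is.null(chain_id)) {
    stop("polymer ligand spec requires chain_id")
  }
  structure(list(kind = kind, ccd_code = ccd_code, chain_id = chain_id,
                 res_start = res_start, res_end = res_end, source = source),
            class = "plc_ligand_spec")
}

format_spec <- function(spec) {
  if (spec$kind == "ccd") paste0("ccd:", spec$ccd_code)
  else paste0("polymer:", spec$chain_id,
              if (!is.null(spec$res_start)) {
                paste0(":", spec$res_start, "-", spec$res_end)
              } else "")
}

#' Identify ligand instances in a structure
#'
#' Every residue matching a CCD spec yields one instance per copy (copies
#' across chains are distinct instances); every chain matching a polymer
#' spec yields one instance covering the whole chain (or span). Instances
#' carry heavy atoms only and are ordered by chain then residue key.
#'
#' @param s a [plc_structure()].
#' @param specs list of [ligand_spec()] objects (a single spec is
#'   accepted).
#' @param cfg a [plc_config()].
#' @return list of `plc_ligand` objects, each with fields `spec`, `atoms`
#'   (heavy-atom table), `residue_names`, `n_residues`, `key`.
#' @export
identify_ligands <- function(s, specs, cfg = plc_config()) {
  if (inherits(specs, "plc_ligand_spec")) specs <- list(specs)
  out <- list()
  for (spec in specs) {
    if (spec$kind == "ccd") {
      hits <- s$atoms[s$atoms$resname == spec$ccd_code, , drop = FALSE]
      if (!nrow(hits)) {
        stop("ligand spec matches nothing in ", s$entry_id, ": ",
             format_spec(spec))
      }
      for (key in unique(residue_key(hits))) {
        atoms <- heavy_atoms(hits[residue_key(hits) == key, , drop = FALSE])
        out[[length(out) + 1L]] <- new_ligand(spec, atoms, key)
      }
    } else {
      ca <- s$atoms[s$atoms$chain == spec$chain_id, , drop = FALSE]
      if (!nrow(ca)) {
        stop("ligand spec matches nothing in ", s$entry_id, ": ",
             format_spec(spec))
      }
      if (!is.null(spec$res_start)) {
        ca <- ca[ca$resseq >= spec$res_start & ca$resseq <= spec$res_end, ,
                 drop = FALSE]
      }
      nres <- length(unique(residue_key(ca)))
      if (nres >= cfg$polymer_ligand_max_residues) {
        stop("polymer ligand class violation: chain ", spec$chain_id,
             " has ", nres, " residues (limit is < ",
             cfg$polymer_ligand_max_residues, ")")
      }
      if (nres < cfg$polymer_ligand_min_residues) {
        stop("polymer ligand class violation: chain ", spec$chain_id,
             " has ", nres, " residues (need >= ",
             cfg$polymer_ligand_min_residues, ")")
      }
      atoms <- heavy_atoms(ca)
      out[[length(out) + 1L]] <-
        new_ligand(spec, atoms, residue_key(atoms)[1L])
    }
  }
  keys <- vapply(out, function(l) l$key, "")
  out[order(keys)]
}

new_ligand <- function(spec, atoms, key) {
  structure(list(
    spec = spec,
    atoms = atoms,
    residue_names = unique(atoms$resname),
    n_residues = length(unique(residue_key(atoms))),
    key = key
  ), class = "plc_ligand")
}

#' @export
print.plc_ligand <- function(x, ...) {
  cat(sprintf("<plc_ligand> %s [%s]: %d heavy atoms, %d residue(s)\n",
              x$key, format_spec(x$spec), nrow(x$atoms), x$n_residues))
  invisible(x)
}

#' Extract the curated complex around one ligand
#'
#' Labels every biopolymer chain with a heavy atom closer than
#' `protein_assoc_cutoff` to any ligand heavy atom as the associated
#' protein (chains are kept whole, never trimmed to the shell), and every
#' HETATM residue within `additive_cutoff` of that protein as an additive.
#' The ligand's own residues, and residues serving as the ligand of
#' another bundle (via `other_ligand_keys`), are excluded from additives;
#' roles within a bundle are disjoint.
#'
#' @param s the parent [plc_structure()].
#' @param ligand a `plc_ligand` from [identify_ligands()].
#' @param cfg a [plc_config()].
#' @param drop_waters drop HOH/WAT/DOD residues from the additive shell.
#' @param other_ligand_keys residue keys of ligands in other bundles of
#'   this entry, excluded from additives.
#' @return an object of class `plc_bundle` with fields `ligand`, `protein`
#'   (a `plc_structure` of whole associated chains), `additives` (atom
#'   table), `entry_id`, `log`.
#' @export
extract_complex <- function(s, ligand, cfg = plc_config(),
                            drop_waters = FALSE,
                            other_ligand_keys = character(0)) {
  lig_keys <- unique(residue_key(ligand$atoms))
  lig_xyz <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  all_atoms <- s$atoms
  in_ligand <- residue_key(all_atoms) %in% lig_keys

  log <- character(0)
  assoc <- character(0)
  for (ch in unique(all_atoms$chain)) {
    if (!chain_is_polymer(s, ch)) next
    ca <- heavy_atoms(all_atoms[all_atoms$chain == ch & !in_ligand, ,
                                drop = FALSE])
    if (!nrow(ca)) next
    d <- min_pair_distance(as.matrix(ca[, c("x", "y", "z")]), lig_xyz)
    if (d$min < cfg$protein_assoc_cutoff) {
      assoc <- c(assoc, ch)
      log <- c(log, sprintf("chain %s associated (min distance %.2f A)",
                            ch, d$min))
    }
  }
  if (!length(assoc)) {
    stop("orphan ligand ", ligand$key, ": no biopolymer chain within ",
         cfg$protein_assoc_cutoff, " A")
  }

  prot_keep <- all_atoms$chain %in% assoc & !in_ligand &
    all_atoms$record == "ATOM"
  protein <- subset_structure(s, prot_keep)
  prot_xyz <- structure_xyz(protein, heavy_only = TRUE)

  het <- all_atoms[all_atoms$record == "HETATM" & !in_ligand &
                     !(all_atoms$chain %in% assoc &
                         all_atoms$record == "ATOM"), , drop = FALSE]
  if (drop_waters) {
    het <- het[!het$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  }
  het <- het[!(residue_key(het) %in% other_ligand_keys), , drop = FALSE]
  additives <- het[0, ]
  for (key in unique(residue_key(het))) {
    ra <- heavy_atoms(het[residue_key(het) == key, , drop = FALSE])
    if (!nrow(ra)) next
    d <- min_pair_distance(as.matrix(ra[, c("x", "y", "z")]), prot_xyz)
    if (d$min < cfg$additive_cutoff) {
      additives <- rbind(additives,
                         het[residue_key(het) == key, , drop = FALSE])
      log <- c(log, sprintf("additive %s (%s) at %.2f A", key,
                            ra$resname[1L], d$min))
    }
  }

  structure(list(
    ligand = ligand,
    protein = protein,
    additives = additives,
    entry_id = s$entry_id,
    conect = s$conect,
    log = log
  ), class = "plc_bundle")
}

#' @export
print.plc_bundle <- function(x, ...) {
  cat(sprintf(
    "<plc_bundle> %s / %s: protein %d atoms (%d chains), %d additive atoms\n",
    x$entry_id, x$ligand$key, nrow(x$protein$atoms),
    length(unique(x$protein$atoms$chain)), nrow(x$additives)))
  invisible(x)
}

#' Write the additive shell of a bundle as PDB
#'
#' @param bundle a `plc_bundle`.
#' @param path optional output file.
#' @return PDB lines, invisibly.
#' @export
write_additives_pdb <- function(bundle, path = NULL) {
  s <- plc_structure(bundle$entry_id, bundle$additives)
  write_pdb(s, path = path)
}
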