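# Ligand repair: perceive a graph from crystal geometry, resolve a
# reference chemistry, check the reference against the geometry, transfer
# bond orders through element-labelled graph isomorphism, and protonate.

#' Perceive a molecular graph from crystal geometry
#'
#' Bonds are inferred from interatomic distances: two heavy atoms are
#' bonded when their distance is below the sum of covalent radii times
#' `cfg$bond_tolerance`. All provisional orders are single — correcting
#' them is the job of [transfer_bond_orders()]. Atoms with no neighbor
#' within bonding distance leave the graph flagged multi-fragment.
#'
#' @param ligand a `plc_ligand` (heavy atoms with 3D coordinates).
#' @param cfg a [plc_config()].
#' @return a `plc_mol` (heavy atoms only) with attribute
#'   `"n_fragments"`.
#' @export
perceive_from_geometry <- function(ligand, cfg = plc_config()) {
  a <- heavy_atoms(ligand$atoms)
  if (nrow(a) < 1L) stop("ligand has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- covalent_radius(a$element)
  n <- nrow(a)
  bonds <- list()
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    thr <- outer(r, r, "+") * cfg$bond_tolerance
    hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
      bonds[[1L]] <- data.frame(i = hit[, 1], j = hit[, 2], order = 1L,
                                aromatic = FALSE)
    }
  }
  atoms <- data.frame(
    element = a$element, charge = 0L, hyb = "other", aromatic = FALSE,
    x = a$x, y = a$y, z = a$z, name = a$name, serial = a$serial,
    stringsAsFactors = FALSE
  )
  mol <- plc_mol(atoms, if (length(bonds)) bonds[[1L]] else
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0)))
  g <- mol_to_igraph(mol, heavy_only = FALSE)
  nfrag <- igraph::components(g)$no
  if (nfrag > 1L) {
    warning("ligand ", ligand$key, " perceives as ", nfrag,
            " disconnected fragment(s)")
  }
  attr(mol, "n_fragments") <- nfrag
  mol
}

#' Resolve the reference chemistry for a ligand
#'
#' Precedence: user override table, then CCD/BIRD lookup through the
#' supplied fetcher, then the peptide builder for polymer ligands made of
#' standard alpha-amino acids. The source is recorded on the result.
#'
#' @param ligand a `plc_ligand`.
#' @param overrides optional data frame with columns `code`, `smiles`
#'   (manually corrected reference SMILES).
#' @param fetcher optional function `code -> SMILES or NULL` (e.g. a
#'   cached chemical-component-dictionary lookup); offline table-backed
#'   implementations are interchangeable with network ones.
#' @return a `plc_reference`.
#' @export
resolve_reference <- function(ligand, overrides = NULL, fetcher = NULL) {
  code <- if (ligand$spec$kind == "ccd") ligand$spec$ccd_code else NULL
  if (!is.null(code) && !is.null(overrides) && nrow(overrides)) {
    hit <- match(code, overrides$code)
    if (!is.na(hit)) {
      return(new_reference(overrides$smiles[hit], "override-table"))
    }
  }
  if (!is.null(code) && !is.null(fetcher)) {
    smi <- fetcher(code)
    if (!is.null(smi) && nzchar(smi)) {
      return(new_reference(smi, "ccd-lookup"))
    }
  }
  if (ligand$spec$kind == "polymer") {
    res3 <- residue_sequence(ligand$atoms)
    one <- aa3_to_1(res3)
    if (any(one == "X")) {
      stop("unresolvable reference for ", ligand$key,
           ": polymer contains non-standard residue(s) ",
           paste(unique(res3[one == "X"]), collapse = ", "))
    }
    ref <- peptide_smiles(paste(one, collapse = ""))
    return(ref)
  }
  stop("unresolvable reference for ligand ", ligand$key,
       ": no override, lookup, or peptide route available")
}

residue_sequence <- function(atoms) {
  keys <- residue_key(atoms)
  atoms$resname[!duplicated(keys)]
}

#' Check a reference chemistry against crystal geometry
#'
#' Catches corrupt references (typically all-single-bond SMILES) by
#' comparing carbon planarity in the crystal geometry with the
#' unsaturation the reference declares: a planar 5/6-ring or a planar
#' three-substituent carbon in the geometry must be matched by an
#' unsaturated ring or an sp2 carbon in the reference, and vice versa for
#' pyramidal centers declared sp2.
#'
#' @param reference a `plc_reference`.
#' @param inferred the geometry-perceived `plc_mol`.
#' @param cfg a [plc_config()] (`planarity_tol_deg` is the improper
#'   dihedral tolerance).
#' @return list with `ok` (logical) and `diagnostic` (string naming the
#'   offending atoms when `ok` is `FALSE`).
#' @export
validate_reference_geometry <- function(reference, inferred,
                                        cfg = plc_config()) {
  ref <- mol_from_smiles(reference$smiles)

  # ring test: planar rings in geometry need unsaturation in the reference
  inf_rings <- find_rings(inferred, max_size = 6L)
  planar_rings <- Filter(function(r) ring_is_planar(inferred, r), inf_rings)
  ref_rings <- find_rings(ref, max_size = 6L)
  unsat <- Filter(function(r) ring_is_unsaturated(ref, r), ref_rings)
  if (length(planar_rings) > length(unsat)) {
    ats <- paste(unique(unlist(lapply(planar_rings, function(r) {
      inferred$atoms$name[r]
    }))), collapse = ",")
    return(list(ok = FALSE, diagnostic = paste0(
      "geometry has ", length(planar_rings), " planar ring(s) [", ats,
      "] but reference declares only ", length(unsat),
      " unsaturated ring(s)")))
  }

  # three-substituent carbon test
  tol <- cfg$planarity_tol_deg
  cls <- carbon3_classes(inferred, tol)
  ref3 <- ref_carbon3_hyb(ref)
  if (length(cls$planar) > ref3$sp2) {
    return(list(ok = FALSE, diagnostic = paste0(
      "carbons ", paste(inferred$atoms$name[cls$planar], collapse = ","),
      " are planar in the crystal but the reference has only ", ref3$sp2,
      " three-connected sp2 carbon(s)")))
  }
  if (length(cls$pyramidal) > ref3$sp3) {
    return(list(ok = FALSE, diagnostic = paste0(
      "carbons ", paste(inferred$atoms$name[cls$pyramidal], collapse = ","),
      " are pyramidal in the crystal but the reference has only ",
      ref3$sp3, " three-connected sp3 carbon(s)")))
  }
  list(ok = TRUE, diagnostic = "")
}

# Enumerate simple cycles up to max_size by DFS (ligand-sized graphs only).
find_rings <- function(mol, max_size = 6L) {
  n <- nrow(mol$atoms)
  adj <- lapply(seq_len(n), function(k) mol_neighbors(mol, k))
  rings <- list()
  seen <- character(0)
  dfs <- function(path) {
    tail_v <- path[length(path)]
    for (nb in adj[[tail_v]]) {
      if (nb == path[1L] && length(path) >= 3L) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < max_size) {
        dfs(c(path, nb))
      }
    }
  }
  for (v in seq_len(n)) dfs(v)
  # drop rings that are unions of smaller rings (keep minimal by size, then
  # discard any ring fully covered by smaller rings' edges)
  rings[order(vapply(rings, length, 1L))]
}

ring_is_planar <- function(mol, ring, rms_tol = 0.1) {
  xyz <- as.matrix(mol$atoms[ring, c("x", "y", "z")])
  c0 <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(c0)
  # distance of atoms to the best-fit plane = projection on third axis
  sqrt(mean((c0 %*% sv$v[, 3])^2)) < rms_tol
}

ring_is_unsaturated <- function(mol, ring) {
  k <- length(ring)
  for (idx in seq_len(k)) {
    a <- ring[idx]
    b <- ring[if (idx == k) 1L else idx + 1L]
    hit <- (mol$bonds$i == a & mol$bonds$j == b) |
      (mol$bonds$i == b & mol$bonds$j == a)
    if (any(hit) && (mol$bonds$order[which(hit)[1L]] >= 2L ||
                     mol$bonds$aromatic[which(hit)[1L]])) {
      return(TRUE)
    }
  }
  FALSE
}

# Classify carbons with exactly three heavy neighbors as planar or
# pyramidal from the improper dihedral between the C and its substituents.
carbon3_classes <- function(mol, tol_deg, pyramidal_min = 25) {
  planar <- integer(0)
  pyramidal <- integer(0)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  for (k in which(mol$atoms$element == "C")) {
    nb <- mol_neighbors(mol, k)
    nb <- nb[mol$atoms$element[nb] != "H"]
    if (length(nb) != 3L) next
    imp <- abs(dihedral(xyz[nb[1L], ], xyz[nb[2L], ], xyz[k, ],
                        xyz[nb[3L], ]))
    dev <- abs(180 - imp)
    if (dev < tol_deg) planar <- c(planar, k)
    else if (dev > pyramidal_min) pyramidal <- c(pyramidal, k)
  }
  list(planar = planar, pyramidal = pyramidal)
}

ref_carbon3_hyb <- function(ref) {
  sp2 <- 0L
  sp3 <- 0L
  for (k in which(ref$atoms$element == "C")) {
    nb <- mol_neighbors(ref, k)
    nb <- nb[ref$atoms$element[nb] != "H"]
    if (length(nb) != 3L) next
    if (ref$atoms$hyb[k] == "sp2" || ref$atoms$aromatic[k]) sp2 <- sp2 + 1L
    else sp3 <- sp3 + 1L
  }
  list(sp2 = sp2, sp3 = sp3)
}

#' Transfer bond orders from a reference onto crystal coordinates
#'
#' Matches the geometry-perceived heavy-atom graph against the reference
#' graph by element-labelled (order-blind) isomorphism. When a one-to-one
#' mapping exists, bond orders, aromaticity, hybridization and formal
#' charges are copied through the mapping onto the crystal coordinates;
#' any automorphic mapping is chemically equivalent, so the first is
#' taken. A missing atom or differing connectivity yields a mismatch
#' outcome naming the difference.
#'
#' @param inferred `plc_mol` from [perceive_from_geometry()].
#' @param reference a `plc_reference` (or a `plc_mol` used directly).
#' @param time_limit seconds allowed for the isomorphism search.
#' @return a `plc_fix_outcome`: list with `status`
#'   (`"fixed"`/`"mismatch"`), `mol` (when fixed), `diagnostic`.
#' @export
transfer_bond_orders <- function(inferred, reference, time_limit = 20) {
  ref <- if (inherits(reference, "plc_mol")) reference
         else mol_from_smiles(reference$smiles)
  gi <- mol_to_igraph(inferred, heavy_only = TRUE)
  gr <- mol_to_igraph(ref, heavy_only = TRUE)

  if (igraph::vcount(gi) != igraph::vcount(gr)) {
    return(fix_outcome("mismatch", diagnostic = sprintf(
      "atom count differs: crystal has %d heavy atoms, reference %d",
      igraph::vcount(gi), igraph::vcount(gr))))
  }
  ci <- sort(table(inferred$atoms$element[inferred$atoms$element != "H"]))
  cr <- sort(table(ref$atoms$element[ref$atoms$element != "H"]))
  if (!identical(ci, cr)) {
    return(fix_outcome("mismatch", diagnostic = paste0(
      "element composition differs: crystal ",
      paste(names(ci), ci, sep = ":", collapse = " "), " vs reference ",
      paste(names(cr), cr, sep = ":", collapse = " "))))
  }

  maps <- tryCatch({
    on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
    setTimeLimit(elapsed = time_limit, transient = TRUE)
    igraph::graph.get.isomorphisms.vf2(
      gi, gr,
      vertex.color1 = element_colors(gi),
      vertex.color2 = element_colors(gr))
  }, error = function(e) e)
  setTimeLimit(elapsed = Inf)
  if (inherits(maps, "error")) {
    return(fix_outcome("mismatch", diagnostic = paste(
      "isomorphism search did not finish:", conditionMessage(maps))))
  }
  if (!length(maps)) {
    return(fix_outcome("mismatch",
                       diagnostic = "connectivity differs from reference"))
  }
  m <- as.integer(maps[[1L]])  # inferred vertex k corresponds to ref m[k]

  heavy_idx <- which(inferred$atoms$element != "H")
  ref_heavy <- which(ref$atoms$element != "H")
  out <- inferred
  out$atoms$charge[heavy_idx] <- ref$atoms$charge[ref_heavy][m]
  out$atoms$hyb[heavy_idx] <- ref$atoms$hyb[ref_heavy][m]
  out$atoms$aromatic[heavy_idx] <- ref$atoms$aromatic[ref_heavy][m]
  ref_map <- ref_heavy[m]
  for (b in seq_len(nrow(out$bonds))) {
    ri <- ref_map[out$bonds$i[b]]
    rj <- ref_map[out$bonds$j[b]]
    hit <- (ref$bonds$i == ri & ref$bonds$j == rj) |
      (ref$bonds$i == rj & ref$bonds$j == ri)
    out$bonds$order[b] <- ref$bonds$order[which(hit)[1L]]
    out$bonds$aromatic[b] <- ref$bonds$aromatic[which(hit)[1L]]
  }
  fix_outcome("fixed", mol = out)
}

fix_outcome <- function(status, mol = NULL, diagnostic = "") {
  structure(list(status = status, mol = mol, diagnostic = diagnostic),
            class = "plc_fix_outcome")
}

#' @export
print.plc_fix_outcome <- function(x, ...) {
  cat(sprintf("<plc_fix_outcome> %s%s\n", x$status,
              if (nzchar(x$diagnostic)) paste0(": ", x$diagnostic) else ""))
  invisible(x)
}

#' Fix a ligand end to end
#'
#' Composition of [perceive_from_geometry()], [resolve_reference()],
#' [validate_reference_geometry()], [transfer_bond_orders()] and
#' [assign_protonation()]. Heavy-atom coordinates are preserved exactly;
#' hydrogens are placed at standard geometry. Any stage failure yields a
#' non-`fixed` outcome tagged with the stage.
#'
#' @param ligand a `plc_ligand` that passed the filters.
#' @param reference optional `plc_reference` (or SMILES string) to use
#'   directly; when `NULL` it is resolved via `overrides`/`fetcher`.
#' @param overrides,fetcher passed to [resolve_reference()].
#' @param cfg a [plc_config()].
#' @return a `plc_fix_outcome`; on success `mol` is the protonated,
#'   hydrogen-complete molecule on crystal coordinates and the outcome
#'   carries a `"reference"` attribute.
#' @export
fix_ligand <- function(ligand, reference = NULL, overrides = NULL,
                       fetcher = NULL, cfg = plc_config()) {
  inferred <- tryCatch(withCallingHandlers(
    perceive_from_geometry(ligand, cfg),
    warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
  if (inherits(inferred, "error")) {
    return(fix_outcome("bad-reference", diagnostic = paste(
      "perceive:", conditionMessage(inferred))))
  }
  if (is.null(reference)) {
    reference <- tryCatch(resolve_reference(ligand, overrides, fetcher),
                          error = function(e) e)
    if (inherits(reference, "error")) {
      return(fix_outcome("bad-reference", diagnostic = paste(
        "resolve:", conditionMessage(reference))))
    }
  } else if (is.character(reference)) {
    reference <- new_reference(reference, "user")
  }
  chk <- validate_reference_geometry(reference, inferred, cfg)
  if (!chk$ok) {
    return(fix_outcome("bad-reference",
                       diagnostic = paste("validate:", chk$diagnostic)))
  }
  res <- transfer_bond_orders(inferred, reference)
  if (res$status != "fixed") return(res)
  mol <- tryCatch(assign_protonation(res$mol), error = function(e) e)
  if (inherits(mol, "error")) {
    return(fix_outcome("bad-reference", diagnostic = paste(
      "protonate:", conditionMessage(mol))))
  }
  out <- fix_outcome("fixed", mol = mol)
  attr(out, "reference") <- reference
  out
}
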