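# Rule-based protonation at physiological pH, expressed as molecular-graph
# predicates applied in a fixed order:
#   1. deprotonate acids (carboxylic/sulfonic/phosphonic), nitro OH,
#      thiophenols, azides, N-oxides
#   2. deprotonate enols in the O=C-C=C-OH motif
#   3. protonate aliphatic amines and guanidine/imine nitrogens, except
#      anilines and amines whose N touches any non-{H,C} atom
#   4. on diamines/piperazines, protonate exactly one nitrogen
# Explicit hydrogens for the final states are added afterwards at standard
# geometry. The rules only touch atoms with zero formal charge, which makes
# the whole assignment idempotent.

#' Assign protonation states to a fixed ligand
#'
#' Applies the fixed-order rule set described in the package vignette and
#' adds explicit hydrogens for the resulting charge states. Heavy-atom
#' coordinates are untouched; applying the function twice equals applying
#' it once.
#'
#' @param mol a `plc_mol` with correct bond orders (typically the output
#'   of [transfer_bond_orders()]).
#' @return a protonated `plc_mol` with explicit hydrogens.
#' @export
assign_protonation <- function(mol) {
  heavy <- mol$atoms$element != "H"
  # work on the heavy-atom graph; H counts are implied by charge + valence
  m <- strip_hydrogens(mol)
  m <- deprotonate_acidic(m)
  m <- deprotonate_enols(m)
  m <- protonate_basic_nitrogens(m)
  mol_add_hydrogens(m)
}

strip_hydrogens <- function(mol) {
  keep <- which(mol$atoms$element != "H")
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  b <- mol$bonds
  ok <- b$i %in% keep & b$j %in% keep
  b <- b[ok, , drop = FALSE]
  b$i <- remap[b$i]
  b$j <- remap[b$j]
  rownames(atoms) <- NULL
  plc_mol(atoms, b)
}

heavy_degree <- function(mol, k) {
  nb <- mol_neighbors(mol, k)
  sum(mol$atoms$element[nb] != "H")
}

# does atom k have a neighbor of given element joined by given order?
has_neighbor <- function(mol, k, element, order = NULL, exclude = integer(0)) {
  nb <- setdiff(mol_neighbors(mol, k), exclude)
  for (n in nb) {
    if (mol$atoms$element[n] %in% element) {
      if (is.null(order) || bond_order_between(mol, k, n) %in% order) {
        return(TRUE)
      }
    }
  }
  FALSE
}

deprotonate_acidic <- function(mol) {
  el <- mol$atoms$element
  for (k in seq_len(nrow(mol$atoms))) {
    if (mol$atoms$charge[k] != 0L) next

    # terminal hydroxyl-type O on C/S/P centers that carry a doubly bonded
    # O: carboxylic, sulfonic, phosphonic acids and the nitro OH form
    if (el[k] == "O" && heavy_degree(mol, k) == 1L) {
      c0 <- mol_neighbors(mol, k)
      c0 <- c0[el[c0] != "H"][1L]
      if (!is.na(c0) && bond_order_between(mol, k, c0) == 1L &&
          el[c0] %in% c("C", "S", "P", "N") &&
          has_neighbor(mol, c0, "O", order = 2L, exclude = k)) {
        mol$atoms$charge[k] <- -1L
        if (el[c0] == "N" && mol$atoms$charge[c0] == 0L &&
            total_bond_order(mol, c0) >= 4L) {
          mol$atoms$charge[c0] <- 1L  # nitro written as N(=O)OH
        }
        next
      }
    }

    # thiophenol: terminal S on an aromatic carbon
    if (el[k] == "S" && heavy_degree(mol, k) == 1L) {
      c0 <- mol_neighbors(mol, k)
      c0 <- c0[el[c0] != "H"][1L]
      if (!is.na(c0) && el[c0] == "C" && mol$atoms$aromatic[c0] &&
          bond_order_between(mol, k, c0) == 1L) {
        mol$atoms$charge[k] <- -1L
        next
      }
    }

    # azide written neutrally (R-N=N=N or HN3): terminal N gets the charge
    if (el[k] == "N" && heavy_degree(mol, k) == 1L) {
      n2 <- mol_neighbors(mol, k)
      n2 <- n2[el[n2] == "N"]
      if (length(n2) == 1L && bond_order_between(mol, k, n2) == 2L &&
          mol$atoms$charge[n2] == 0L &&
          has_neighbor(mol, n2, "N", order = 2L, exclude = k)) {
        mol$atoms$charge[k] <- -1L
        mol$atoms$charge[n2] <- 1L
        next
      }
    }

    # N-oxide written neutrally: terminal O on an N with no other oxygens
    if (el[k] == "O" && heavy_degree(mol, k) == 1L) {
      n0 <- mol_neighbors(mol, k)
      n0 <- n0[el[n0] == "N"]
      if (length(n0) == 1L && mol$atoms$charge[n0] == 0L &&
          !has_neighbor(mol, n0, "O", exclude = k) &&
          heavy_degree(mol, n0) >= 3L) {
        ord <- bond_order_between(mol, k, n0)
        mol$atoms$charge[k] <- -1L
        mol$atoms$charge[n0] <- 1L
        if (ord == 2L) set_bond_order(mol, k, n0) -> mol
        next
      }
    }
  }
  mol
}

total_bond_order <- function(mol, k) {
  b <- mol$bonds
  sum(b$order[b$i == k | b$j == k])
}

set_bond_order <- function(mol, a, b, order = 1L) {
  hit <- (mol$bonds$i == a & mol$bonds$j == b) |
    (mol$bonds$i == b & mol$bonds$j == a)
  mol$bonds$order[hit] <- order
  mol
}

# enol O in the O=C-C=C-OH motif
deprotonate_enols <- function(mol) {
  el <- mol$atoms$element
  for (k in seq_len(nrow(mol$atoms))) {
    if (el[k] != "O" || mol$atoms$charge[k] != 0L) next
    if (heavy_degree(mol, k) != 1L) next
    c3 <- mol_neighbors(mol, k)
    c3 <- c3[el[c3] == "C"]
    if (!length(c3) || bond_order_between(mol, k, c3[1L]) != 1L) next
    c3 <- c3[1L]
    for (c2 in setdiff(mol_neighbors(mol, c3), k)) {
      if (el[c2] != "C" || bond_order_between(mol, c3, c2) != 2L) next
      for (c1 in setdiff(mol_neighbors(mol, c2), c3)) {
        if (el[c1] != "C" || bond_order_between(mol, c2, c1) != 1L) next
        if (has_neighbor(mol, c1, "O", order = 2L)) {
          mol$atoms$charge[k] <- -1L
          return(deprotonate_enols(mol))
        }
      }
    }
  }
  mol
}

protonate_basic_nitrogens <- function(mol) {
  el <- mol$atoms$element
  candidates <- integer(0)
  for (k in which(el == "N")) {
    if (mol$atoms$charge[k] != 0L || mol$atoms$aromatic[k]) next
    nb <- mol_neighbors(mol, k)
    nb_heavy <- nb[el[nb] != "H"]
    # bonded only to C or H
    if (any(!el[nb] %in% c("C", "H"))) next
    # aniline: N on an aromatic carbon stays neutral
    if (any(mol$atoms$aromatic[nb_heavy] & el[nb_heavy] == "C")) next
    orders <- vapply(nb_heavy, function(n) bond_order_between(mol, k, n), 1L)
    if (any(orders >= 3L)) next  # nitriles are not basic
    if (all(orders == 1L)) {
      # aliphatic amine -- but not an amide/sulfonamide-type N: exclude N
      # bonded to a carbon that carries a double bond to O or S
      acylated <- any(vapply(nb_heavy, function(n) {
        el[n] == "C" && has_neighbor(mol, n, c("O", "S"), order = 2L)
      }, TRUE))
      if (acylated) next
      if (length(nb_heavy) > 3L) next
      candidates <- c(candidates, k)
    } else if (sum(orders == 2L) == 1L) {
      # imine / guanidine / amidine nitrogen: protonate the =N
      candidates <- c(candidates, k)
    }
  }
  if (!length(candidates)) return(mol)

  # diamine / piperazine rule: within any group of candidate nitrogens
  # closer than 4 bonds, exactly one is protonated -- the nitrogen with
  # fewer heavy substituents (ties: lowest atom index). Nitrogens already
  # cationic claim their neighborhood too, which keeps the whole
  # assignment idempotent.
  g <- mol_to_igraph(mol, heavy_only = FALSE)
  cationic <- which(mol$atoms$element == "N" & mol$atoms$charge == 1L)
  if (length(cationic)) {
    dcat <- igraph::distances(g, v = candidates, to = cationic)
    candidates <- candidates[apply(dcat > 3, 1L, all)]
    if (!length(candidates)) return(mol)
  }
  dmat <- igraph::distances(g, v = candidates, to = candidates)
  prox <- dmat <= 3
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(prox, mode = "undirected"))$membership
  chosen <- integer(0)
  for (grp in split(seq_along(candidates), comp)) {
    idx <- candidates[grp]
    deg <- vapply(idx, function(k) heavy_degree(mol, k), 1L)
    chosen <- c(chosen, idx[order(deg, idx)][1L])
  }
  mol$atoms$charge[chosen] <- 1L
  mol
}
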