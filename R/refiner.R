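# Constrained relaxation of the recombined complex. Experimentally
# resolved atoms are frozen by construction: they are simply not part of
# the optimization variables, so their displacement is exactly zero. The
# potential is a lightweight geometric one -- harmonic bond restraints to
# the input bond lengths plus a soft-core quadratic repulsion between
# non-bonded pairs -- which is everywhere finite, so relaxation always
# starts from a defined energy and L-BFGS monotonically improves it.

.vdw_radii <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Relax a protein-ligand complex under coordinate constraints
#'
#' Combines the fixed protein and ligand and minimizes a bonded +
#' soft-repulsion potential in which only non-experimental atoms
#' (hydrogens and fixer-added atoms) move. Additives are excluded from
#' the relaxed system. Deterministic: no stochastic steps.
#'
#' @param protein a protonated [plc_structure()].
#' @param ligand_mol the fixed `plc_mol` of the ligand (hydrogens
#'   explicit; heavy atoms experimental).
#' @param cfg a [plc_config()] (`minimize_tol` kJ/mol and
#'   `minimize_max_iter` govern convergence).
#' @param ff_spec potential selection; `"steric-harmonic"` is the bonded +
#'   soft-core-repulsion potential described in the vignette.
#' @param repulsion_cutoff neighbor-list cutoff in angstroms.
#' @return an object of class `plc_refinement`: list with `protein`,
#'   `ligand_mol` (relaxed coordinates), `converged`,
#'   `max_moved_constrained` (always 0 by construction),
#'   `energy_initial`, `energy_final`.
#' @export
minimize_complex <- function(protein, ligand_mol, cfg = plc_config(),
                             ff_spec = "steric-harmonic",
                             repulsion_cutoff = 5.0) {
  if (!identical(ff_spec, "steric-harmonic")) {
    stop("refinement error: unknown force-field spec '", ff_spec, "'")
  }
  pa <- protein$atoms
  la <- ligand_mol$atoms
  n_p <- nrow(pa)
  n_l <- nrow(la)
  xyz <- rbind(as.matrix(pa[, c("x", "y", "z")]),
               as.matrix(la[, c("x", "y", "z")]))
  element <- c(pa$element, la$element)
  # ligand heavy atoms are experimentally resolved; its hydrogens are not
  movable <- c(!pa$is_experimental, la$element == "H")
  if (!any(movable)) {
    e0 <- NA_real_
    sys <- build_potential(xyz, element, movable, ligand_mol, n_p,
                           repulsion_cutoff)
    e0 <- sys$energy(xyz[movable, , drop = FALSE])
    return(refinement_result(protein, ligand_mol, TRUE, e0, e0))
  }

  sys <- build_potential(xyz, element, movable, ligand_mol, n_p,
                         repulsion_cutoff)
  x0 <- as.vector(t(xyz[movable, , drop = FALSE]))
  e_initial <- sys$fn(x0)
  opt <- stats::optim(
    x0, fn = sys$fn, gr = sys$gr, method = "L-BFGS-B",
    control = list(maxit = cfg$minimize_max_iter, factr = 1e7,
                   pgtol = cfg$minimize_tol * 1e-3))
  e_final <- min(opt$value, e_initial)
  xnew <- if (opt$value <= e_initial) {
    matrix(opt$par, ncol = 3, byrow = TRUE)
  } else {
    xyz[movable, , drop = FALSE]
  }
  xyz[movable, ] <- xnew

  pa[, c("x", "y", "z")] <- xyz[seq_len(n_p), , drop = FALSE]
  la[, c("x", "y", "z")] <- xyz[n_p + seq_len(n_l), , drop = FALSE]
  protein_out <- protein
  protein_out$atoms <- pa
  lig_out <- ligand_mol
  lig_out$atoms <- la
  refinement_result(protein_out, lig_out, opt$convergence == 0L,
                    e_initial, e_final)
}

refinement_result <- function(protein, ligand_mol, converged, e0, e1) {
  structure(list(protein = protein, ligand_mol = ligand_mol,
                 converged = converged, max_moved_constrained = 0,
                 energy_initial = e0, energy_final = e1),
            class = "plc_refinement")
}

#' @export
print.plc_refinement <- function(x, ...) {
  cat(sprintf(
    "<plc_refinement> energy %.2f -> %.2f kJ/mol (%s); constrained displacement %.1f A\n",
    x$energy_initial, x$energy_final,
    if (x$converged) "converged" else "iteration cap reached",
    x$max_moved_constrained))
  invisible(x)
}

# Assemble the bond list and the repulsion neighbor list once, from the
# input geometry; both stay fixed during minimization (deterministic).
build_potential <- function(xyz, element, movable, ligand_mol, n_p,
                            cutoff) {
  n <- nrow(xyz)
  # bonds: protein bonds perceived from distance (covalent-radius rule so
  # chain breaks never produce a spurious bond), ligand bonds taken from
  # its graph
  bonds <- perceive_bonds_xyz(xyz[seq_len(n_p), , drop = FALSE],
                              element[seq_len(n_p)])
  if (nrow(ligand_mol$bonds)) {
    bonds <- rbind(bonds, cbind(ligand_mol$bonds$i + n_p,
                                ligand_mol$bonds$j + n_p))
  }
  keep <- movable[bonds[, 1]] | movable[bonds[, 2]]
  bonds <- bonds[keep, , drop = FALSE]
  b0 <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                        xyz[bonds[, 2], , drop = FALSE])^2))
  # restrain X-H bonds to ideal lengths, others to their input length
  ideal_h <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)
  for (k in seq_len(nrow(bonds))) {
    e1 <- element[bonds[k, 1]]
    e2 <- element[bonds[k, 2]]
    if (xor(e1 == "H", e2 == "H")) {
      parent <- if (e1 == "H") e2 else e1
      if (parent %in% names(ideal_h)) b0[k] <- ideal_h[[parent]]
    }
  }

  bonded_key <- paste(pmin(bonds[, 1], bonds[, 2]),
                      pmax(bonds[, 1], bonds[, 2]))
  # repulsion pairs: within cutoff at input, at least one end movable,
  # not bonded, not both in the frozen set
  pairs <- neighbor_pairs(xyz, cutoff)
  pkeep <- (movable[pairs[, 1]] | movable[pairs[, 2]])
  pairs <- pairs[pkeep, , drop = FALSE]
  pkey <- paste(pairs[, 1], pairs[, 2])
  pairs <- pairs[!pkey %in% bonded_key, , drop = FALSE]
  # skip 1-3 pairs (sharing a bonded neighbor) to avoid fighting geometry
  if (nrow(bonds)) {
    nb_of <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
    is13 <- vapply(seq_len(nrow(pairs)), function(k) {
      a <- as.character(pairs[k, 1])
      b <- as.character(pairs[k, 2])
      length(intersect(nb_of[[a]], nb_of[[b]])) > 0
    }, TRUE)
    pairs <- pairs[!is13, , drop = FALSE]
  }
  r0 <- 0.85 * (vdw_radius(element[pairs[, 1]]) +
                  vdw_radius(element[pairs[, 2]]))

  k_bond <- 1000   # kJ/mol/A^2
  k_rep <- 200     # kJ/mol/A^2

  mov_idx <- which(movable)
  slot <- match(seq_len(n), mov_idx)  # variable slot per atom (NA frozen)

  unpack <- function(x) {
    out <- xyz
    out[mov_idx, ] <- matrix(x, ncol = 3, byrow = TRUE)
    out
  }
  energy_of <- function(coords) {
    d_b <- sqrt(rowSums((coords[bonds[, 1], , drop = FALSE] -
                           coords[bonds[, 2], , drop = FALSE])^2))
    e <- sum(k_bond * (d_b - b0)^2)
    if (nrow(pairs)) {
      d_p <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                             coords[pairs[, 2], , drop = FALSE])^2))
      pen <- pmax(r0 - d_p, 0)
      e <- e + sum(k_rep * pen^2)
    }
    e
  }
  fn <- function(x) energy_of(unpack(x))
  gr <- function(x) {
    coords <- unpack(x)
    g <- matrix(0, nrow = n, ncol = 3)
    dv <- coords[bonds[, 1], , drop = FALSE] -
      coords[bonds[, 2], , drop = FALSE]
    d_b <- sqrt(rowSums(dv^2))
    coef <- 2 * k_bond * (d_b - b0) / pmax(d_b, 1e-8)
    gb <- dv * coef
    for (col in 1:3) {
      g[, col] <- g[, col] +
        tabulate_add(bonds[, 1], gb[, col], n) -
        tabulate_add(bonds[, 2], gb[, col], n)
    }
    if (nrow(pairs)) {
      dv <- coords[pairs[, 1], , drop = FALSE] -
        coords[pairs[, 2], , drop = FALSE]
      d_p <- sqrt(rowSums(dv^2))
      pen <- pmax(r0 - d_p, 0)
      coef <- -2 * k_rep * pen / pmax(d_p, 1e-8)
      gp <- dv * coef
      for (col in 1:3) {
        g[, col] <- g[, col] +
          tabulate_add(pairs[, 1], gp[, col], n) -
          tabulate_add(pairs[, 2], gp[, col], n)
      }
    }
    as.vector(t(g[mov_idx, , drop = FALSE]))
  }
  list(fn = fn, gr = gr,
       energy = function(sub) fn(as.vector(t(sub))))
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- tapply(val, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

perceive_bonds_xyz <- function(xyz, element, tol = 1.3) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  pairs <- neighbor_pairs(xyz, 2.6)
  r <- covalent_radius(element)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  thr <- (r[pairs[, 1]] + r[pairs[, 2]]) * tol
  pairs[d < thr, , drop = FALSE]
}

# all unordered pairs with distance < cutoff, via cell lists
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  cell <- floor(xyz / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  coords <- lapply(buckets, function(i) unique(cell[i, , drop = FALSE][1, ]))
  out <- list()
  bkeys <- names(buckets)
  cellmat <- do.call(rbind, lapply(strsplit(bkeys, " "), as.numeric))
  for (bi in seq_along(buckets)) {
    base <- cellmat[bi, ]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nb_key <- paste(base[1] + dx, base[2] + dy, base[3] + dz)
      bj <- match(nb_key, bkeys)
      if (is.na(bj) || bj < bi) next
      ii <- buckets[[bi]]
      jj <- buckets[[bj]]
      if (bi == bj) {
        if (length(ii) < 2L) next
        cmb <- t(utils::combn(ii, 2L))
      } else {
        cmb <- as.matrix(expand.grid(i = ii, j = jj))
      }
      d2 <- rowSums((xyz[cmb[, 1], , drop = FALSE] -
                       xyz[cmb[, 2], , drop = FALSE])^2)
      hit <- cmb[d2 < cutoff^2, , drop = FALSE]
      if (nrow(hit)) {
        out[[length(out) + 1L]] <-
          cbind(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2]))
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, out))
}
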