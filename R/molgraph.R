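# Chemistry-complete ligand representation: a plc_mol is a list with
#   atoms  data.frame(element, charge, hyb, aromatic, x, y, z, name, serial)
#          `serial` maps back to the source AtomRecord (NA for added H)
#   bonds  data.frame(i, j, order, aromatic) with Kekule integer orders
# Aromaticity is carried as flags next to Kekule orders so SDF output never
# needs query bond types.

#' Construct a molecule graph
#'
#' @param atoms data frame with columns `element`, `charge`, `hyb`,
#'   `aromatic`, `x`, `y`, `z` and optionally `name`, `serial`.
#' @param bonds data frame with columns `i`, `j`, `order` (1/2/3) and
#'   optionally `aromatic`.
#' @return an object of class `plc_mol`.
#' @export
plc_mol <- function(atoms, bonds) {
  if (is.null(atoms$name)) atoms$name <- atoms$element
  if (is.null(atoms$serial)) atoms$serial <- NA_integer_
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$hyb)) atoms$hyb <- "other"
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (nrow(bonds)) {
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    stopifnot(all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)))
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0))
  }
  if (!all(is_known_element(atoms$element))) {
    stop("unknown element symbol(s): ",
         paste(unique(atoms$element[!is_known_element(atoms$element)]),
               collapse = ", "))
  }
  structure(list(atoms = atoms, bonds = bonds), class = "plc_mol")
}

#' Print method for molecule graphs
#' @param x a `plc_mol`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
print.plc_mol <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(sprintf(
    "<plc_mol> %d heavy atoms (+%d H), %d bonds, net charge %+d%s\n",
    nh, nrow(x$atoms) - nh, nrow(x$bonds), mol_net_charge(x),
    if (any(x$atoms$aromatic)) ", aromatic" else ""))
  invisible(x)
}

#' Net formal charge of a molecule
#' @param mol a `plc_mol`.
#' @return integer.
#' @export
mol_net_charge <- function(mol) as.integer(sum(mol$atoms$charge))

mol_heavy_count <- function(mol) sum(mol$atoms$element != "H")

# Neighbor indices of atom k (over all atoms, H included).
mol_neighbors <- function(mol, k) {
  b <- mol$bonds
  c(b$j[b$i == k], b$i[b$j == k])
}

bond_order_between <- function(mol, a, b) {
  hit <- (mol$bonds$i == a & mol$bonds$j == b) |
    (mol$bonds$i == b & mol$bonds$j == a)
  if (!any(hit)) return(0L)
  mol$bonds$order[which(hit)[1L]]
}

#' Convert a molecule to an igraph object
#'
#' Vertices carry the element symbol (`element` attribute); edges carry
#' `order`. Used for isomorphism matching and ring perception.
#'
#' @param mol a `plc_mol`.
#' @param heavy_only drop hydrogens first (indices are then relative to the
#'   heavy-atom subset).
#' @return an `igraph` graph.
#' @export
mol_to_igraph <- function(mol, heavy_only = TRUE) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  if (heavy_only) {
    keep <- which(atoms$element != "H")
    remap <- match(seq_len(nrow(atoms)), keep)
    atoms <- atoms[keep, , drop = FALSE]
    ok <- bonds$i %in% keep & bonds$j %in% keep
    bonds <- bonds[ok, , drop = FALSE]
    bonds$i <- remap[bonds$i]
    bonds$j <- remap[bonds$j]
  }
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = atoms$element)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
    g <- igraph::set_edge_attr(g, "order", value = bonds$order)
  }
  g
}

element_colors <- function(g) {
  as.integer(factor(igraph::vertex_attr(g, "element"),
                    levels = names(.covalent_radii)))
}

# ---- SDF (V2000) ----------------------------------------------------------

#' Write a molecule as SDF (V2000) text
#'
#' Formal charges are emitted in `M  CHG` property lines (never encoded via
#' aromatic-oxygen or implicit-valence tricks); bond orders are Kekule
#' integers. Round-trips through [parse_sdf()].
#'
#' @param mol a `plc_mol` with 3D coordinates.
#' @param title molecule title for the header block.
#' @param path optional file to write.
#' @return the SDF text as a single string, invisibly when `path` given.
#' @export
write_sdf <- function(mol, title = "plcurate", path = NULL) {
  a <- mol$atoms
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    stop("write error: atom(s) without finite coordinates")
  }
  b <- mol$bonds
  lines <- c(
    title, " plcurate", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element)
  )
  if (nrow(b)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order))
  }
  chg <- which(a$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, a$charge[grp]), collapse = "")))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Parse SDF (V2000) text into a molecule graph
#'
#' Reads the first molecule of an SDF document: atom block, bond block and
#' `M  CHG` charge properties. Bond type 4 is recorded as an aromatic flag
#' with a provisional single order.
#'
#' @param text SDF document (string, lines, or file path).
#' @return a `plc_mol`.
#' @export
parse_sdf <- function(text) {
  lines <- as_lines(text)
  if (length(lines) < 4L) stop("SDF parse error: truncated document")
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("SDF parse error: bad counts line")
  al <- lines[4L + seq_len(na)]
  atoms <- data.frame(
    element = trimws(substr(al, 32, 34)),
    charge = 0L,
    hyb = "other",
    aromatic = FALSE,
    x = as.numeric(substr(al, 1, 10)),
    y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)),
    stringsAsFactors = FALSE
  )
  if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    type <- as.integer(substr(bl, 7, 9))
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = ifelse(type == 4L, 1L, type),
      aromatic = type == 4L
    )
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0))
  }
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    nent <- as.integer(substr(l, 7, 9))
    for (k in seq_len(nent)) {
      off <- 10 + (k - 1) * 8
      idx <- as.integer(substr(l, off, off + 3))
      val <- as.integer(substr(l, off + 4, off + 7))
      atoms$charge[idx] <- val
    }
  }
  if (any(bonds$aromatic)) {
    arom_atoms <- unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))
    atoms$aromatic[arom_atoms] <- TRUE
  }
  plc_mol(atoms, bonds)
}

# ---- OpenBabel bridge -----------------------------------------------------

ob_convert <- function(from, to, source, opts = NULL) {
  args <- list(from = from, to = to, source = source)
  if (!is.null(opts)) {
    args$options <- data.frame(names = opts, args = rep("", length(opts)),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(ChemmineOB::convertFormat, args)
  if (!nzchar(trimws(out))) {
    stop("OpenBabel conversion ", from, " -> ", to, " produced no output")
  }
  out
}

#' Build a molecule graph from a SMILES string
#'
#' The SMILES is interpreted with OpenBabel; Kekule bond orders and formal
#' charges come from its SDF output, aromaticity flags and hybridization
#' from its mol2 atom typing (atom order is preserved across formats).
#' Counter-ions / extra fragments can be stripped beforehand with
#' [largest_organic_fragment()].
#'
#' @param smiles SMILES string.
#' @param coords `"none"` for topology only (2D placeholder coordinates),
#'   `"3d"` to embed a 3D conformer.
#' @return a `plc_mol`.
#' @export
.embed_cache <- new.env(parent = emptyenv())

mol_from_smiles <- function(smiles, coords = c("none", "3d")) {
  coords <- match.arg(coords)
  # 3D embedding goes through a stochastic conformer search whose
  # generator state advances across calls; memoizing per SMILES keeps
  # every later use of the same molecule on one reproducible conformer
  if (coords == "3d") {
    hit <- .embed_cache[[smiles]]
    if (!is.null(hit)) return(hit)
  }
  opts <- if (coords == "3d") "gen3d" else NULL
  sdf <- tryCatch(ob_convert("SMI", "SDF", smiles, opts),
                  error = function(e) {
                    stop("cannot interpret SMILES '", smiles, "': ",
                         conditionMessage(e))
                  })
  mol <- parse_sdf(sdf)
  mol2 <- ob_convert("SDF", "MOL2", sdf)
  mol <- annotate_from_mol2(mol, mol2)
  if (coords == "3d") .embed_cache[[smiles]] <- mol
  mol
}

# Read aromatic flags and hybridization from mol2 atom/bond typing.
annotate_from_mol2 <- function(mol, mol2_text) {
  lines <- as_lines(mol2_text)
  asec <- which(lines == "@<TRIPOS>ATOM")
  bsec <- which(lines == "@<TRIPOS>BOND")
  if (!length(asec)) return(mol)
  end_a <- if (length(bsec)) bsec[1L] - 1L else length(lines)
  al <- lines[(asec[1L] + 1L):end_a]
  al <- al[nzchar(trimws(al))]
  types <- vapply(strsplit(trimws(al), "[[:space:]]+"), `[`, "", 6L)
  n <- min(length(types), nrow(mol$atoms))
  suffix <- sub("^[^.]*\\.?", "", types[seq_len(n)])
  mol$atoms$aromatic[seq_len(n)] <- suffix == "ar"
  mol$atoms$hyb[seq_len(n)] <- c(
    "1" = "sp", "2" = "sp2", "ar" = "sp2", "am" = "sp2", "pl3" = "sp2",
    "co2" = "sp2", "3" = "sp3", "4" = "sp3"
  )[suffix]
  mol$atoms$hyb[is.na(mol$atoms$hyb)] <- "other"
  if (length(bsec)) {
    rest <- lines[(bsec[1L] + 1L):length(lines)]
    rest <- rest[nzchar(trimws(rest))]
    rest <- rest[!grepl("^@", rest)]
    for (tok in strsplit(trimws(rest), "[[:space:]]+")) {
      if (length(tok) >= 4L && tok[4L] == "ar") {
        i <- as.integer(tok[2L]); j <- as.integer(tok[3L])
        # mol2 tags carboxylate/equivalent-oxygen bonds "ar" too; only keep
        # flags where both atoms are genuinely aromatic-typed
        if (i <= nrow(mol$atoms) && j <= nrow(mol$atoms) &&
            mol$atoms$aromatic[i] && mol$atoms$aromatic[j]) {
          hit <- (mol$bonds$i == i & mol$bonds$j == j) |
            (mol$bonds$i == j & mol$bonds$j == i)
          mol$bonds$aromatic[hit] <- TRUE
        }
      }
    }
  }
  mol
}

#' Keep the largest organic fragment of a SMILES
#'
#' Strips counter-ions and co-crystallized extras from a multi-fragment
#' SMILES: the fragment with the most heavy atoms wins, with preference for
#' carbon-containing fragments.
#'
#' @param smiles SMILES string, possibly dot-disconnected.
#' @return single-fragment SMILES string.
#' @export
largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(smiles)
  score <- vapply(frags, function(f) {
    m <- tryCatch(mol_from_smiles(f), error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    mol_heavy_count(m) + 1000 * any(m$atoms$element == "C")
  }, 1.0)
  frags[which.max(score)]
}

#' Add explicit hydrogens with 3D positions
#'
#' Completes the hydrogen count implied by element, Kekule bond orders and
#' formal charge on every heavy atom, placing hydrogens at standard
#' geometry with OpenBabel. Heavy-atom coordinates are untouched.
#'
#' @param mol a `plc_mol` with 3D coordinates.
#' @return a `plc_mol` with explicit hydrogens appended after the heavy
#'   atoms (their `serial` is `NA`).
#' @export
mol_add_hydrogens <- function(mol) {
  nh0 <- nrow(mol$atoms)
  sdf <- write_sdf(mol)
  sdfh <- ob_convert("SDF", "SDF", sdf, "h")
  out <- parse_sdf(sdfh)
  if (nrow(out$atoms) < nh0) {
    stop("hydrogen addition removed atoms unexpectedly")
  }
  # heavy atoms keep their order; carry annotations over
  out$atoms$hyb[seq_len(nh0)] <- mol$atoms$hyb
  out$atoms$aromatic[seq_len(nh0)] <- mol$atoms$aromatic
  n_new <- nrow(out$atoms) - nh0
  out$atoms$name <- c(mol$atoms$name,
                      if (n_new > 0L) paste0("H", seq_len(n_new)))
  out$atoms$serial <- c(mol$atoms$serial, rep(NA_integer_, n_new))
  # restore exact heavy-atom coordinates (conversion may reformat)
  out$atoms$x[seq_len(nh0)] <- mol$atoms$x
  out$atoms$y[seq_len(nh0)] <- mol$atoms$y
  out$atoms$z[seq_len(nh0)] <- mol$atoms$z
  ab <- mol$bonds[, c("i", "j", "aromatic")]
  if (nrow(ab) && nrow(out$bonds)) {
    key_old <- paste(pmin(ab$i, ab$j), pmax(ab$i, ab$j))
    key_new <- paste(pmin(out$bonds$i, out$bonds$j),
                     pmax(out$bonds$i, out$bonds$j))
    hit <- match(key_new, key_old)
    out$bonds$aromatic <- ifelse(is.na(hit), FALSE, ab$aromatic[hit])
  }
  out
}

#' Canonical SMILES of a molecule graph
#'
#' @param mol a `plc_mol`.
#' @return canonical SMILES string (OpenBabel canonicalization).
#' @export
mol_to_smiles <- function(mol) {
  out <- ob_convert("SDF", "CAN", write_sdf(mol))
  strsplit(trimws(out), "[[:space:]]+")[[1]][1]
}
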