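# Protein completion: detect missing atoms/residues against the header
# sequence, rebuild what the rules allow, and protonate at pH 7.4.

#' Detect missing atoms and residues
#'
#' Compares every polymer chain against the complete deposited sequence
#' from the mmCIF header. Missing residues are header positions without
#' coordinates; missing atoms are modeled residues lacking atoms of their
#' standard template. Consecutive missing positions form segments,
#' classified terminal when they touch either sequence end, and
#' partitioned into those to repair (internal, length <=
#' `missing_segment_max`) and those to skip.
#'
#' @param protein a [plc_structure()] of polymer chains.
#' @param meta a `plc_metadata` from [parse_mmcif_header()].
#' @param cfg a [plc_config()].
#' @return an object of class `plc_missing_report`: list with
#'   `missing_atoms` (data frame chain/resseq/icode/resname/atom) and
#'   `segments` (data frame chain/start/end/start_resseq/end_resseq/
#'   length/terminal/repair).
#' @export
detect_missing <- function(protein, meta, cfg = plc_config()) {
  chains <- unique(protein$atoms$chain)
  miss_atoms <- list()
  segments <- list()
  for (ch in chains) {
    if (!chain_is_polymer(protein, ch)) next
    hs <- meta$full_sequences[[ch]]
    if (is.null(hs)) {
      stop("metadata error: chain ", ch, " absent from header sequences")
    }
    ca <- protein$atoms[protein$atoms$chain == ch, , drop = FALSE]
    present <- unique(ca$resseq)

    modeled <- hs$resseq %in% present
    # missing atoms within modeled residues
    for (rs in hs$resseq[modeled]) {
      res <- ca[ca$resseq == rs, , drop = FALSE]
      expected <- template_heavy_atoms(res$resname[1L])
      if (is.null(expected)) next
      absent <- setdiff(expected, res$name)
      if (length(absent)) {
        miss_atoms[[length(miss_atoms) + 1L]] <- data.frame(
          chain = ch, resseq = rs, icode = res$icode[1L],
          resname = res$resname[1L], atom = absent,
          stringsAsFactors = FALSE)
      }
    }
    # missing segments
    runs <- rle(!modeled)
    pos <- cumsum(c(1L, runs$lengths))
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      start <- pos[k]
      end <- pos[k] + runs$lengths[k] - 1L
      terminal <- start == 1L || end == length(hs$resseq)
      segments[[length(segments) + 1L]] <- data.frame(
        chain = ch, start = start, end = end,
        start_resseq = hs$resseq[start], end_resseq = hs$resseq[end],
        length = runs$lengths[k], terminal = terminal,
        repair = !terminal & runs$lengths[k] <= cfg$missing_segment_max,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    missing_atoms = if (length(miss_atoms)) do.call(rbind, miss_atoms)
                    else data.frame(chain = character(0),
                                    resseq = integer(0),
                                    icode = character(0),
                                    resname = character(0),
                                    atom = character(0)),
    segments = if (length(segments)) do.call(rbind, segments)
               else data.frame(chain = character(0), start = integer(0),
                               end = integer(0), start_resseq = integer(0),
                               end_resseq = integer(0), length = integer(0),
                               terminal = logical(0), repair = logical(0))
  ), class = "plc_missing_report")
}

#' @export
print.plc_missing_report <- function(x, ...) {
  cat(sprintf(
    "<plc_missing_report> %d residue(s) lack atoms; %d missing segment(s) (%d to repair)\n",
    length(unique(paste(x$missing_atoms$chain, x$missing_atoms$resseq))),
    nrow(x$segments), sum(x$segments$repair)))
  invisible(x)
}

#' Repair missing atoms and rebuildable segments
#'
#' Missing atoms are always added by superposing the idealized residue
#' template on the present atoms. Internal missing segments within the
#' length limit are rebuilt with template residues placed along the gap;
#' terminal segments and over-long gaps are left absent, preserving the
#' chain break in numbering (no spurious peptide bond is created: bonded
#' interactions downstream are distance-gated). Every added atom carries
#' `is_experimental = FALSE` and a repair record used by [write_pdb()]
#' annotations. Experimental atoms are never moved.
#'
#' @param protein a [plc_structure()].
#' @param report a `plc_missing_report` from [detect_missing()].
#' @param meta the `plc_metadata` (needed for residue names of rebuilt
#'   segments).
#' @param cfg a [plc_config()].
#' @return the repaired `plc_structure`, with attribute `"repairs"` (data
#'   frame of per-residue notes).
#' @export
repair_protein <- function(protein, report, meta, cfg = plc_config()) {
  atoms <- protein$atoms
  next_serial <- max(atoms$serial) + 1L
  repairs <- list()

  # 1. complete partial residues
  ma <- report$missing_atoms
  if (nrow(ma)) {
    for (key in unique(paste(ma$chain, ma$resseq, ma$icode, sep = "|"))) {
      rows <- ma[paste(ma$chain, ma$resseq, ma$icode, sep = "|") == key, ]
      sel <- atoms$chain == rows$chain[1L] &
        atoms$resseq == rows$resseq[1L] & atoms$icode == rows$icode[1L]
      res <- atoms[sel, , drop = FALSE]
      t <- fit_template(res, rows$resname[1L])
      if (is.null(t)) {
        stop("repair error: residue ", key, " (", rows$resname[1L],
             ") has no usable template fit")
      }
      add <- t[t$atom %in% rows$atom, , drop = FALSE]
      newa <- data.frame(
        serial = next_serial + seq_len(nrow(add)) - 1L,
        name = add$atom, alt = "", resname = res$resname[1L],
        chain = res$chain[1L], resseq = res$resseq[1L],
        icode = res$icode[1L], x = add$x, y = add$y, z = add$z,
        occupancy = 1, element = add$element, record = res$record[1L],
        is_experimental = FALSE, stringsAsFactors = FALSE)
      next_serial <- next_serial + nrow(add)
      atoms <- rbind(atoms, newa)
      repairs[[length(repairs) + 1L]] <- data.frame(
        chain = res$chain[1L], resseq = res$resseq[1L],
        icode = res$icode[1L],
        note = paste("added missing atoms:", paste(add$atom, collapse = " ")),
        stringsAsFactors = FALSE)
    }
  }

  # 2. rebuild internal segments within the length limit
  segs <- report$segments
  segs <- segs[segs$repair, , drop = FALSE]
  if (nrow(segs)) {
    for (si in seq_len(nrow(segs))) {
      sg <- segs[si, ]
      hs <- meta$full_sequences[[sg$chain]]
      anchor_prev <- hs$resseq[sg$start - 1L]
      anchor_next <- hs$resseq[sg$end + 1L]
      pa <- atoms[atoms$chain == sg$chain & atoms$resseq == anchor_prev, ]
      na <- atoms[atoms$chain == sg$chain & atoms$resseq == anchor_next, ]
      p0 <- unlist(pa[pa$name == "C", c("x", "y", "z")])
      p1 <- unlist(na[na$name == "N", c("x", "y", "z")])
      if (!length(p0)) p0 <- colMeans(pa[, c("x", "y", "z")])
      if (!length(p1)) p1 <- colMeans(na[, c("x", "y", "z")])
      nres <- sg$length
      existing_xyz <- as.matrix(atoms[, c("x", "y", "z")])
      for (k in seq_len(nres)) {
        idx <- sg$start + k - 1L
        resname <- hs$seq3[idx]
        frac <- k / (nres + 1)
        center <- p0 + (p1 - p0) * frac
        placed <- place_template_residue(resname, center, p1 - p0,
                                         existing_xyz)
        newa <- data.frame(
          serial = next_serial + seq_len(nrow(placed)) - 1L,
          name = placed$atom, alt = "", resname = resname,
          chain = sg$chain, resseq = hs$resseq[idx], icode = "",
          x = placed$x, y = placed$y, z = placed$z,
          occupancy = 1, element = placed$element, record = "ATOM",
          is_experimental = FALSE, stringsAsFactors = FALSE)
        next_serial <- next_serial + nrow(placed)
        atoms <- rbind(atoms, newa)
        existing_xyz <- rbind(existing_xyz,
                              as.matrix(placed[, c("x", "y", "z")]))
        repairs[[length(repairs) + 1L]] <- data.frame(
          chain = sg$chain, resseq = hs$resseq[idx], icode = "",
          note = paste("rebuilt missing residue", resname),
          stringsAsFactors = FALSE)
      }
    }
  }
  skipped <- report$segments[!report$segments$repair, , drop = FALSE]
  for (si in seq_len(nrow(skipped))) {
    sg <- skipped[si, ]
    repairs[[length(repairs) + 1L]] <- data.frame(
      chain = sg$chain, resseq = sg$start_resseq, icode = "",
      note = sprintf("gap of %d residue(s) left absent (%s)", sg$length,
                     if (sg$terminal) "terminal" else "over length limit"),
      stringsAsFactors = FALSE)
  }

  out <- plc_structure(protein$entry_id, order_structure_atoms(atoms),
                       protein$conect, protein$model)
  attr(out, "repairs") <- if (length(repairs)) do.call(rbind, repairs)
                          else NULL
  out
}

# Heavy atoms of a template residue dropped at `center`, oriented with the
# backbone N->C axis along `direction`; retries with jittered placement if
# anything lands closer than 1 A to an existing atom.
place_template_residue <- function(resname, center, direction,
                                   existing_xyz, max_tries = 8L) {
  t <- residue_template(resname)
  if (is.null(t)) stop("repair error: no template for residue ", resname)
  t <- t[t$element != "H" & t$atom != "OXT", , drop = FALSE]
  xyz <- as.matrix(t[, c("x", "y", "z")])
  # orient template N->C along the gap direction
  tn <- xyz[t$atom == "N", ]
  tc <- xyz[t$atom == "C", ]
  rot <- rotation_between(unit(tc - tn), unit(direction))
  xyz <- sweep(xyz, 2, colMeans(xyz)) %*% t(rot)
  for (try in seq_len(max_tries)) {
    offset <- if (try == 1L) c(0, 0, 0) else {
      # deterministic lateral offsets growing with each retry
      axis <- c(direction[2], -direction[1], direction[3])
      unit(axis) * 0.8 * try * (-1)^try
    }
    cand <- sweep(xyz, 2, center + offset, "+")
    if (nrow(existing_xyz) == 0L ||
        min_pair_distance(cand, existing_xyz)$min >= 1.0) {
      t$x <- cand[, 1]; t$y <- cand[, 2]; t$z <- cand[, 3]
      return(t)
    }
  }
  # accept the last candidate; residual strain is resolved by refinement
  t$x <- cand[, 1]; t$y <- cand[, 2]; t$z <- cand[, 3]
  t
}

# rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) return(diag(c(-1, -1, 1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Protonate a protein at pH 7.4
#'
#' Adds hydrogens by superposing idealized residue templates on the heavy
#' atoms. Fixed titration rules: LYS and ARG cationic, ASP and GLU
#' anionic, histidine neutral with the HID/HIE tautomer chosen
#' per-residue by the better hydrogen bond (the nitrogen whose protonated
#' form makes more donor-acceptor contacts within 3.5 A at an angle above
#' 120 degrees; tie or no polar neighbor: HIE). Cysteines in a detected
#' disulfide (SG-SG < 2.3 A) keep no thiol hydrogen. Added hydrogens are
#' `is_experimental = FALSE`; heavy atoms are never moved.
#'
#' @param protein a repaired [plc_structure()].
#' @param cfg a [plc_config()].
#' @return the protonated `plc_structure`, with attribute `"his_variants"`
#'   (named character vector per histidine).
#' @export
protonate_protein <- function(protein, cfg = plc_config()) {
  atoms <- protein$atoms[protein$atoms$element != "H", , drop = FALSE]
  heavy_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  next_serial <- max(atoms$serial) + 1L
  added <- list()
  his_variants <- character(0)

  ss_sg <- disulfide_sg_serials(atoms)
  keys <- unique(residue_key(atoms))
  for (key in keys) {
    sel <- residue_key(atoms) == key
    res <- atoms[sel, , drop = FALSE]
    resname <- map_nonstandard_residue(res$resname[1L])
    t <- fit_template(res, resname)
    if (is.null(t)) next
    hnames <- hydrogen_set(resname)
    # terminal handling: keep the extra amine H only at the chain start
    ca <- atoms[atoms$chain == res$chain[1L], ]
    is_nterm <- res$resseq[1L] == min(ca$resseq)
    if (!is_nterm) hnames <- setdiff(hnames, "H2")
    if (resname == "HIS") {
      variant <- choose_his_variant(res, t, atoms, heavy_xyz)
      his_variants[key] <- variant
      hnames <- setdiff(hnames, if (variant == "HIE") "HD1" else "HE2")
    }
    if (resname == "CYS" && any(res$serial[res$name == "SG"] %in% ss_sg)) {
      hnames <- setdiff(hnames, "HG")
    }
    hadd <- t[t$atom %in% hnames & t$element == "H", , drop = FALSE]
    # only place hydrogens whose heavy parent is actually present
    parent <- hydrogen_parents(resname)
    hadd <- hadd[parent[hadd$atom] %in% res$name, , drop = FALSE]
    if (!nrow(hadd)) next
    added[[length(added) + 1L]] <- data.frame(
      serial = next_serial + seq_len(nrow(hadd)) - 1L,
      name = hadd$atom, alt = "", resname = res$resname[1L],
      chain = res$chain[1L], resseq = res$resseq[1L],
      icode = res$icode[1L], x = hadd$x, y = hadd$y, z = hadd$z,
      occupancy = 1, element = "H", record = res$record[1L],
      is_experimental = FALSE, stringsAsFactors = FALSE)
    next_serial <- next_serial + nrow(hadd)
  }
  all_atoms <- if (length(added)) rbind(atoms, do.call(rbind, added))
               else atoms
  out <- plc_structure(protein$entry_id, order_structure_atoms(all_atoms),
                       protein$conect, protein$model)
  attr(out, "repairs") <- attr(protein, "repairs")
  attr(out, "his_variants") <- his_variants
  out
}

disulfide_sg_serials <- function(atoms, cutoff = 2.3) {
  sg <- atoms[atoms$name == "SG" & atoms$element == "S", , drop = FALSE]
  if (nrow(sg) < 2L) return(integer(0))
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  unique(c(sg$serial[hit[, 1]], sg$serial[hit[, 2]]))
}

# hydrogens a residue carries at pH 7.4 (before tautomer/terminal pruning)
hydrogen_set <- function(resname) {
  t <- residue_template(resname)
  h <- t$atom[t$element == "H"]
  h <- setdiff(h, c("HXT", "H3"))
  drop <- switch(resname,
    ASP = "HD2",   # carboxylate
    GLU = "HE2",   # carboxylate
    PRO = c("H", "H2"),
    character(0))
  setdiff(h, drop)
}

# map each template hydrogen to its heavy parent by nearest distance
hydrogen_parents <- function(resname) {
  t <- residue_template(resname)
  hv <- t[t$element != "H", ]
  hh <- t[t$element == "H", ]
  if (!nrow(hh)) return(stats::setNames(character(0), character(0)))
  parent <- vapply(seq_len(nrow(hh)), function(k) {
    d <- (hv$x - hh$x[k])^2 + (hv$y - hh$y[k])^2 + (hv$z - hh$z[k])^2
    hv$atom[which.min(d)]
  }, "")
  stats::setNames(parent, hh$atom)
}

# HID vs HIE: count polar contacts of each would-be proton
choose_his_variant <- function(res, t, atoms, heavy_xyz) {
  score <- function(hname, nname) {
    hpos <- unlist(t[t$atom == hname, c("x", "y", "z")])
    npos <- unlist(res[res$name == nname, c("x", "y", "z")])
    if (!length(hpos) || !length(npos)) return(-1L)
    polar <- atoms$element %in% c("N", "O") &
      !(residue_key(atoms) == residue_key(res)[1L])
    if (!any(polar)) return(0L)
    px <- heavy_xyz[polar, , drop = FALSE]
    d <- sqrt(colSums((t(px) - hpos)^2))
    cand <- which(d < 3.5)
    n <- 0L
    for (ci in cand) {
      acc <- px[ci, ]
      v1 <- npos - hpos
      v2 <- acc - hpos
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) *
        180 / pi
      if (ang > 120) n <- n + 1L
    }
    n
  }
  nd <- score("HD1", "ND1")
  ne <- score("HE2", "NE2")
  if (nd > ne) "HID" else "HIE"
}
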