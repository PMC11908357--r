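#' Parse a PDB-format document
#'
#' Reads coordinate records into the internal structure model. Only the
#' selected model of a multi-model (e.g. NMR) file is kept; alternate
#' locations are resolved to the highest-occupancy conformer (ties broken
#' by file order); deposited hydrogens are dropped so that downstream
#' protonation is uniform. CONECT records are collected as unordered
#' serial pairs.
#'
#' Annotation remarks written by [write_pdb()] (`REMARK  99 ADDED`) are
#' recognized on input and restore the `is_experimental` flag of atoms
#' added by the fixing stages, so structures round-trip through the writer.
#'
#' @param text PDB document as a single string or a character vector of
#'   lines, or the path of an existing file.
#' @param model model number to keep (default 1, the first).
#' @param entry_id identifier recorded on the structure; defaults to the
#'   HEADER id when present.
#' @param keep_hydrogens keep deposited hydrogens (default `FALSE`).
#' @return a [plc_structure()].
#' @export
parse_pdb <- function(text, model = 1L, entry_id = NULL,
                      keep_hydrogens = FALSE) {
  lines <- as_lines(text)
  lines <- select_model(lines, model)

  coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(coord)) {
    stop("empty structure: document contains no ATOM or HETATM records")
  }
  check_coordinate_lines(lines, which(coord))

  if (is.null(entry_id)) {
    hdr <- lines[grepl("^HEADER", lines)]
    entry_id <- if (length(hdr)) trimws(substr(hdr[1], 63, 66)) else "XXXX"
    if (!nzchar(entry_id)) entry_id <- "XXXX"
  }

  cl <- lines[coord]
  atoms <- data.frame(
    serial = as.integer(substr(cl, 7, 11)),
    name = trimws(substr(cl, 13, 16)),
    alt = trimws(substr(cl, 17, 17)),
    resname = trimws(substr(cl, 18, 20)),
    chain = trimws(substr(cl, 22, 22)),
    resseq = as.integer(substr(cl, 23, 26)),
    icode = trimws(substr(cl, 27, 27)),
    x = as.numeric(substr(cl, 31, 38)),
    y = as.numeric(substr(cl, 39, 46)),
    z = as.numeric(substr(cl, 47, 54)),
    occupancy = num_or(substr(cl, 55, 60), 1.0),
    element = normalize_element(substr(cl, 77, 78)),
    record = ifelse(substr(cl, 1, 4) == "ATOM", "ATOM", "HETATM"),
    is_experimental = TRUE,
    stringsAsFactors = FALSE
  )
  atoms$element <- infer_missing_elements(atoms$element, atoms$name)

  atoms <- resolve_altloc(atoms)
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (!nrow(atoms)) {
    stop("empty structure: no heavy atoms after alt-loc/hydrogen handling")
  }

  conect <- parse_conect(lines, atoms$serial)
  s <- plc_structure(entry_id, atoms, conect, model)
  restore_added_flags(s, lines)
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

select_model <- function(lines, model) {
  starts <- grep("^MODEL ", lines)
  if (!length(starts)) return(lines)
  ids <- as.integer(substr(lines[starts], 11, 14))
  pick <- match(model, ids)
  if (is.na(pick)) {
    stop("model ", model, " not present (models: ",
         paste(ids, collapse = ", "), ")")
  }
  ends <- grep("^ENDMDL", lines)
  end <- ends[ends > starts[pick]][1]
  if (is.na(end)) end <- length(lines)
  keep_body <- seq(starts[pick] + 1L, end - 1L)
  non_coord <- setdiff(seq_along(lines), unlist(mapply(
    function(s, e) s:e, starts,
    vapply(starts, function(s) {
      e <- ends[ends > s][1]
      if (is.na(e)) length(lines) else e
    }, 1L), SIMPLIFY = FALSE)))
  c(lines[intersect(non_coord, seq_len(starts[1] - 1L))],
    lines[keep_body],
    lines[non_coord[non_coord > max(ends, starts)]])
}

check_coordinate_lines <- function(lines, idx) {
  for (i in idx) {
    l <- lines[i]
    if (nchar(l) < 54) {
      stop("unparseable coordinate record at line ", i,
           ": shorter than 54 columns")
    }
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz)) {
      stop("unparseable coordinate record at line ", i,
           ": non-numeric coordinates")
    }
  }
  invisible(TRUE)
}

num_or <- function(x, default) {
  v <- suppressWarnings(as.numeric(x))
  v[is.na(v)] <- default
  v
}

# Fallback element assignment from atom names for files lacking columns
# 77-78. Two-letter symbols are tried first (Cl in "CL1"), then one letter.
infer_missing_elements <- function(element, name) {
  missing <- !nzchar(element)
  if (!any(missing)) return(element)
  guess <- function(nm) {
    core <- gsub("[0-9']", "", nm)
    if (!nzchar(core)) return("")
    two <- paste0(toupper(substr(core, 1, 1)), tolower(substr(core, 2, 2)))
    if (nchar(core) >= 2L && is_known_element(two) &&
        !two %in% c("Ca", "Cd", "Co", "Na", "Ne", "Nd", "Ho", "Os")) {
      return(two)
    }
    one <- toupper(substr(core, 1, 1))
    if (is_known_element(one)) one else ""
  }
  element[missing] <- vapply(name[missing], guess, "")
  if (any(!nzchar(element))) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(name[!nzchar(element)]), collapse = ", "))
  }
  element
}

# Highest-occupancy conformer wins; ties go to first occurrence in file.
resolve_altloc <- function(atoms) {
  if (!any(nzchar(atoms$alt))) return(atoms)
  key <- paste(residue_key(atoms), atoms$name)
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  dedup <- !duplicated(key[ord])
  out <- atoms[sort(ord[dedup]), , drop = FALSE]
  out$alt <- ""
  rownames(out) <- NULL
  out
}

parse_conect <- function(lines, valid_serials) {
  cl <- lines[grepl("^CONECT", lines)]
  if (!length(cl)) return(matrix(integer(0), ncol = 2))
  pairs <- list()
  for (l in cl) {
    fields <- substring(l, seq(7, 27, by = 5), seq(11, 31, by = 5))
    ser <- suppressWarnings(as.integer(fields))
    ser <- ser[!is.na(ser)]
    if (length(ser) >= 2L) {
      pairs[[length(pairs) + 1L]] <-
        cbind(ser[1L], ser[-1L])
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, pairs)
  m <- t(apply(m, 1L, sort))
  m <- unique(m)
  keep <- m[, 1] %in% valid_serials & m[, 2] %in% valid_serials
  m[keep, , drop = FALSE]
}

restore_added_flags <- function(s, lines) {
  rl <- lines[grepl("^REMARK  99 ADDED ATOM", lines)]
  if (!length(rl)) return(s)
  tok <- strsplit(trimws(sub("^REMARK  99 ADDED ATOM", "", rl)), "[[:space:]]+")
  for (t in tok) {
    if (length(t) < 3L) next
    chain <- t[1L]
    m <- regmatches(t[2L], regexec("^(-?[0-9]+)([A-Za-z]?)$", t[2L]))[[1]]
    if (!length(m)) next
    hit <- s$atoms$chain == chain &
      s$atoms$resseq == as.integer(m[2L]) &
      s$atoms$icode == m[3L] &
      s$atoms$name == t[3L]
    s$atoms$is_experimental[hit] <- FALSE
  }
  s
}

#' Write a structure as PDB text
#'
#' Produces standard fixed-column PDB text. Atoms added by the fixing
#' stages (`is_experimental == FALSE`) are declared in `REMARK  99 ADDED
#' ATOM` lines, and free-text per-residue notes can be supplied as fix
#' annotations; both are emitted before the coordinates so the provenance
#' of every rebuilt residue is visible in the file itself. Re-parsing the
#' output with [parse_pdb()] reproduces the structure (coordinates to
#' three decimals, flags included).
#'
#' @param s a [plc_structure()].
#' @param fix_annotations optional data frame with columns `chain`,
#'   `resseq`, `icode`, `note` (one remark per row).
#' @param path optional file to write.
#' @return the PDB text invisibly (a character vector of lines).
#' @export
write_pdb <- function(s, fix_annotations = NULL, path = NULL) {
  atoms <- order_structure_atoms(s$atoms)
  if (nrow(atoms) > 99999L) {
    stop("capacity error: PDB format cannot hold more than 99,999 atoms")
  }
  serial_map <- stats::setNames(seq_len(nrow(atoms)), atoms$serial)

  out <- c(
    sprintf("HEADER    CURATED COMPLEX                         %9s%4s",
            format(Sys.Date(), "%d-%b-%y"), substr(s$entry_id, 1, 4))
  )
  if (!is.null(fix_annotations) && nrow(fix_annotations)) {
    out <- c(out, sprintf(
      "REMARK  99 FIX %s %s%s %s",
      fix_annotations$chain, fix_annotations$resseq,
      fix_annotations$icode, fix_annotations$note))
  }
  added <- atoms[!atoms$is_experimental & atoms$element != "H", ]
  if (nrow(added)) {
    out <- c(out, sprintf("REMARK  99 ADDED ATOM %s %d%s %s %s",
                          added$chain, added$resseq, added$icode,
                          added$name, added$resname))
  }

  fmt_name <- function(name, element) {
    ifelse(nchar(name) >= 4L, substr(name, 1, 4),
           ifelse(nchar(element) == 2L,
                  formatC(name, width = -4),
                  paste0(" ", formatC(name, width = -3))))
  }
  rec <- formatC(atoms$record, width = -6)
  out <- c(out, sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, serial_map[as.character(atoms$serial)],
    fmt_name(atoms$name, atoms$element), "", atoms$resname, atoms$chain,
    atoms$resseq, atoms$icode, atoms$x, atoms$y, atoms$z,
    atoms$occupancy, 0, toupper(atoms$element)))

  if (nrow(s$conect)) {
    c1 <- serial_map[as.character(s$conect[, 1])]
    c2 <- serial_map[as.character(s$conect[, 2])]
    out <- c(out,
             sprintf("CONECT%5d%5d", c1, c2),
             sprintf("CONECT%5d%5d", c2, c1))
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Fetch an entry from the RCSB public archive
#'
#' Downloads the coordinate (PDB) and header (mmCIF) files for an accession
#' into a cache directory; files already cached are not fetched again. All
#' other code paths in the package accept local files only.
#'
#' @param entry_id four-character PDB accession.
#' @param cache_dir directory for cached downloads.
#' @param formats subset of `c("pdb", "cif")`.
#' @return named character vector of local file paths.
#' @export
fetch_rcsb <- function(entry_id, cache_dir = tempdir(),
                       formats = c("pdb", "cif")) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", entry_id))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (fmt in formats) {
    dest <- file.path(cache_dir, paste0(tolower(entry_id), ".", fmt))
    if (!file.exists(dest)) {
      url <- sprintf("https://files.rcsb.org/download/%s.%s",
                     toupper(entry_id), fmt)
      status <- tryCatch(
        utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
        error = function(e) -1L, warning = function(w) -1L)
      if (!identical(status, 0L) || !file.exists(dest) ||
          file.size(dest) == 0) {
        unlink(dest)
        stop("unable to fetch ", entry_id, " (", fmt,
             ") from RCSB; network unavailable or accession unknown")
      }
    }
    out[fmt] <- dest
  }
  out
}
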