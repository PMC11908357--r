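# Binding-affinity normalization: parse heterogeneous annotation strings,
# convert exact Kd/Ki to free energies, reject invalid values, and merge
# multi-source records into one machine-readable table.

.affinity_units <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
                     fM = 1e-15)

#' Parse one affinity annotation string
#'
#' Accepts the common dialects `"Kd=2nM"`, `"IC50~5uM"`, `"Ki>10mM"`,
#' with measurement in {Kd, Ki, IC50, EC50}, qualifier in
#' `=`, `~`, `>`, `<`, `>=`, `<=`, and unit in {M, mM, uM/µM, nM, pM, fM}.
#' Values are normalized to molar; the qualifier is preserved verbatim.
#' A free energy is attached only for exact (`=`) Kd/Ki records.
#'
#' @param raw annotation string.
#' @param entry_id,ligand_key,source provenance fields carried onto the
#'   record.
#' @param cfg a [plc_config()] (temperature and gas constant for the free
#'   energy).
#' @return an object of class `plc_affinity`: list with `entry_id`,
#'   `ligand_key`, `measurement`, `qualifier`, `value_molar`, `delta_g`
#'   (kJ/mol or `NA`), `source`, `raw_text`.
#' @export
parse_affinity <- function(raw, entry_id = NA_character_,
                           ligand_key = NA_character_, source = "other",
                           cfg = plc_config()) {
  if (!nzchar(trimws(raw))) stop("affinity parse error: empty annotation")
  txt <- gsub("[[:space:]]", "", raw)
  txt <- gsub("µ", "u", txt)  # micro sign
  m <- regexec(
    "^(Kd|Ki|IC50|EC50)(>=|<=|=|~|>|<)([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)(fM|pM|nM|uM|mM|M)$",
    txt, ignore.case = TRUE)
  tok <- regmatches(txt, m)[[1]]
  if (!length(tok)) {
    stop("affinity parse error: unrecognized annotation '", raw, "'")
  }
  meas <- c(KD = "Kd", KI = "Ki", IC50 = "IC50", EC50 = "EC50")[toupper(tok[2])]
  unit <- tok[5]
  if (!unit %in% names(.affinity_units)) {
    unit <- names(.affinity_units)[match(tolower(unit),
                                         tolower(names(.affinity_units)))]
  }
  value <- as.numeric(tok[4]) * .affinity_units[[unit]]
  if (!is.finite(value) || value <= 0) {
    stop("affinity parse error: non-positive value in '", raw, "'")
  }
  qualifier <- tok[3]
  dg <- if (meas %in% c("Kd", "Ki") && qualifier == "=") {
    dg_from_constant(value, cfg)
  } else {
    NA_real_
  }
  structure(list(entry_id = entry_id, ligand_key = ligand_key,
                 measurement = unname(meas), qualifier = qualifier,
                 value_molar = unname(value), delta_g = dg,
                 source = source, raw_text = raw),
            class = "plc_affinity")
}

#' Free energy from a dissociation/inhibition constant
#'
#' The standard relation `delta G = R T ln K` for an exact Kd or Ki, with
#' R and T from the configuration (defaults 8.31446e-3 kJ/(mol K) and
#' 298.15 K). `dg_from_constant(1)` is exactly zero.
#'
#' @param k dissociation or inhibition constant in molar; must be > 0.
#' @param cfg a [plc_config()].
#' @return free energy in kJ/mol.
#' @examples
#' dg_from_constant(1e-9)  # about -51.4 kJ/mol
#' @export
dg_from_constant <- function(k, cfg = plc_config()) {
  if (any(!is.finite(k) | k <= 0)) {
    stop("domain error: dissociation constant must be positive")
  }
  cfg$gas_constant * cfg$temperature * log(k)
}

#' Format an affinity record back to its annotation string
#'
#' Inverse of [parse_affinity()] up to unit choice: the most compact unit
#' with a mantissa in [1, 1000) is used. Parsing the result yields an
#' equal record.
#'
#' @param rec a `plc_affinity`.
#' @return annotation string such as `"Kd=2nM"`.
#' @export
format_affinity <- function(rec) {
  units <- rev(names(.affinity_units))  # fM first
  for (u in units) {
    mant <- rec$value_molar / .affinity_units[[u]]
    if (mant >= 1 && mant < 1000) {
      return(sprintf("%s%s%.6g%s", rec$measurement, rec$qualifier, mant, u))
    }
  }
  sprintf("%s%s%.6g%s", rec$measurement, rec$qualifier, rec$value_molar, "M")
}

affinity_to_row <- function(rec) {
  data.frame(entry_id = rec$entry_id, ligand = rec$ligand_key,
             measurement = rec$measurement, qualifier = rec$qualifier,
             value_molar = rec$value_molar, delta_g_kj_mol = rec$delta_g,
             source = rec$source, raw_text = rec$raw_text,
             stringsAsFactors = FALSE)
}

#' Read affinity rows from a source file
#'
#' Table-driven adapters for the supported dialects: BioLiP-style TSV
#' (columns `pdb_id`, `ligand`, `affinity`), MOAD-style CSV (columns
#' `PDB_ID`, `Ligand`, `Affinity`) and a generic CSV with columns
#' `entry_id`, `ligand`, `affinity`. Unparseable rows are quarantined,
#' not dropped silently.
#'
#' @param path input file.
#' @param dialect `"biolip"`, `"moad"` or `"generic"`.
#' @param cfg a [plc_config()].
#' @return list with `records` (list of `plc_affinity`) and `quarantine`
#'   (data frame of raw rows with the parse error message).
#' @export
read_affinity_table <- function(path, dialect = c("generic", "biolip",
                                                  "moad"),
                                cfg = plc_config()) {
  dialect <- match.arg(dialect)
  spec <- switch(dialect,
    biolip = list(sep = "\t", entry = "pdb_id", ligand = "ligand",
                  affinity = "affinity"),
    moad = list(sep = ",", entry = "PDB_ID", ligand = "Ligand",
                affinity = "Affinity"),
    generic = list(sep = ",", entry = "entry_id", ligand = "ligand",
                   affinity = "affinity"))
  df <- utils::read.table(path, sep = spec$sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- unlist(spec[c("entry", "ligand", "affinity")])
  if (!all(need %in% names(df))) {
    stop("affinity table '", path, "' lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  records <- list()
  quarantine <- list()
  src <- if (dialect == "generic") "other" else dialect
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      parse_affinity(df[[spec$affinity]][i],
                     entry_id = toupper(df[[spec$entry]][i]),
                     ligand_key = df[[spec$ligand]][i],
                     source = src, cfg = cfg),
      error = function(e) e)
    if (inherits(rec, "error")) {
      quarantine[[length(quarantine) + 1L]] <- data.frame(
        row = i, raw = df[[spec$affinity]][i],
        error = conditionMessage(rec), stringsAsFactors = FALSE)
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records,
       quarantine = if (length(quarantine)) do.call(rbind, quarantine)
                    else data.frame(row = integer(0), raw = character(0),
                                    error = character(0)))
}

#' Merge affinity records from multiple sources into one curated table
#'
#' Records are unioned by (entry, ligand, measurement); duplicates across
#' sources are deduplicated with precedence biolip > moad > other, with
#' value conflicts logged. Ki/Kd records above `max_valid_ki` are dropped
#' as invalid; every drop is a logged row, never silent. Merging the
#' merged table with itself changes nothing.
#'
#' @param records list of `plc_affinity` records (or a previously merged
#'   table's `table`).
#' @param cfg a [plc_config()].
#' @return list with `table` (curated data frame, columns entry_id,
#'   ligand, measurement, qualifier, value_molar, delta_g_kj_mol, source,
#'   raw_text) and `dropped` (data frame with a `reason` column).
#' @export
merge_sources <- function(records, cfg = plc_config()) {
  if (is.data.frame(records)) {
    tbl <- records
  } else {
    tbl <- do.call(rbind, lapply(records, affinity_to_row))
  }
  if (is.null(tbl) || !nrow(tbl)) {
    return(list(table = empty_affinity_table(),
                dropped = cbind(empty_affinity_table(),
                                reason = character(0))))
  }
  dropped <- list()

  invalid <- tbl$measurement %in% c("Kd", "Ki") &
    tbl$value_molar > cfg$max_valid_ki
  if (any(invalid)) {
    dropped[[1L]] <- cbind(tbl[invalid, , drop = FALSE],
                           reason = "invalid-affinity")
    tbl <- tbl[!invalid, , drop = FALSE]
  }

  prec <- c(biolip = 1L, moad = 2L, other = 3L)
  rank <- prec[tbl$source]
  rank[is.na(rank)] <- 4L
  key <- paste(tbl$entry_id, tbl$ligand, tbl$measurement, sep = "\r")
  ord <- order(key, rank, seq_len(nrow(tbl)))
  tbl <- tbl[ord, , drop = FALSE]
  key <- key[ord]
  dup <- duplicated(key)
  if (any(dup)) {
    first_of <- match(key[dup], key)
    same_value <- abs(tbl$value_molar[dup] - tbl$value_molar[first_of]) <=
      1e-12 * pmax(tbl$value_molar[dup], tbl$value_molar[first_of])
    # record provenance of agreeing duplicates on the surviving row
    for (k in which(dup)) {
      keep_row <- match(key[k], key)
      if (!grepl(tbl$source[k], tbl$provenance[keep_row] %||% "",
                 fixed = TRUE)) {
        tbl$provenance[keep_row] <- paste(
          unique(c(tbl$source[keep_row], tbl$source[k])), collapse = "+")
      }
    }
    dropped[[length(dropped) + 1L]] <- cbind(
      tbl[dup, setdiff(names(tbl), "provenance"), drop = FALSE],
      reason = ifelse(same_value, "duplicate", "conflict-lower-precedence"))
    tbl <- tbl[!dup, , drop = FALSE]
  }
  if (is.null(tbl$provenance)) tbl$provenance <- tbl$source
  tbl$provenance[is.na(tbl$provenance)] <- tbl$source[is.na(tbl$provenance)]
  rownames(tbl) <- NULL
  list(table = tbl[order(tbl$entry_id, tbl$ligand, tbl$measurement), ,
                   drop = FALSE],
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else cbind(empty_affinity_table(), reason = character(0)))
}

empty_affinity_table <- function() {
  data.frame(entry_id = character(0), ligand = character(0),
             measurement = character(0), qualifier = character(0),
             value_molar = numeric(0), delta_g_kj_mol = numeric(0),
             source = character(0), raw_text = character(0),
             stringsAsFactors = FALSE)
}

#' Write the curated affinity table as CSV
#'
#' @param merged result of [merge_sources()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_affinity_csv <- function(merged, path) {
  utils::write.csv(merged$table, path, row.names = FALSE)
  invisible(path)
}
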