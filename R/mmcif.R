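#' Parse an mmCIF header into entry metadata
#'
#' Extracts the metadata the curation workflow needs from the header
#' categories of an mmCIF document: resolution, deposit date, experimental
#' method, and — crucially — the complete deposited sequence of every
#' polymer chain with a modeled/unmodeled flag per position (from the
#' `pdbx_poly_seq_scheme` category, where an unmodeled position carries
#' `?` in its `pdb_mon_id`). Coordinate categories are ignored.
#'
#' @param text mmCIF document as a single string, character vector of
#'   lines, or path to an existing file.
#' @return a list of class `plc_metadata` with fields `entry_id`,
#'   `resolution` (A or `NA`), `deposit_date`, `experimental_method`, and
#'   `full_sequences`: a named list per chain of
#'   `list(seq3 = <3-letter codes>, seq = <one-letter string>,
#'   modeled = <logical>, resseq = <author numbers>)`.
#' @export
parse_mmcif_header <- function(text) {
  lines <- as_lines(text)
  kv <- cif_key_values(lines)
  loops <- cif_loops(lines)

  seq_loop <- loops[["pdbx_poly_seq_scheme"]]
  if (is.null(seq_loop)) {
    stop("metadata error: mmCIF header lacks the pdbx_poly_seq_scheme ",
         "sequence category")
  }
  need <- c("pdb_strand_id", "seq_id", "mon_id", "pdb_mon_id", "pdb_seq_num")
  if (!all(need %in% names(seq_loop))) {
    stop("metadata error: pdbx_poly_seq_scheme lacks column(s): ",
         paste(setdiff(need, names(seq_loop)), collapse = ", "))
  }
  full_sequences <- lapply(split(seq_loop, seq_loop$pdb_strand_id),
                           function(df) {
    df <- df[order(as.integer(df$seq_id)), ]
    modeled <- !(df$pdb_mon_id %in% c("?", "."))
    list(
      seq3 = df$mon_id,
      seq = paste(aa3_to_1(df$mon_id), collapse = ""),
      modeled = modeled,
      resseq = suppressWarnings(as.integer(df$pdb_seq_num))
    )
  })

  res <- kv[["_refine.ls_d_res_high"]] %||% kv[["_reflns.d_resolution_high"]]
  structure(list(
    entry_id = kv[["_entry.id"]] %||% "XXXX",
    resolution = if (is.null(res) || res %in% c("?", ".")) NA_real_
                 else as.numeric(res),
    deposit_date = kv[["_pdbx_database_status.recvd_initial_deposition_date"]] %||%
      NA_character_,
    experimental_method = kv[["_exptl.method"]] %||% NA_character_,
    full_sequences = full_sequences
  ), class = "plc_metadata")
}

aa3_to_1 <- function(codes) {
  one <- suppressWarnings(bio3d::aa321(codes))
  one[is.na(one) | one == "X"] <- "X"
  one
}

# Minimal tokenizer for header-style mmCIF: simple key-value items and
# loop_ blocks with whitespace-separated values (quoted strings honored).
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)[[1]]
  if (m[1] == -1L) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+",
                                   line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

cif_key_values <- function(lines) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (grepl("^_", l)) {
      tok <- cif_tokens(l)
      if (length(tok) >= 2L) {
        out[[tok[1L]]] <- paste(tok[-1L], collapse = " ")
      } else if (length(tok) == 1L && i < length(lines) &&
                 !grepl("^[_#]|^loop_", trimws(lines[i + 1L]))) {
        out[[tok[1L]]] <- trimws(gsub("^['\"]|['\"]$", "",
                                      trimws(lines[i + 1L])))
        i <- i + 1L
      }
    } else if (identical(l, "loop_")) {
      # skip loop bodies; handled by cif_loops
      i <- i + 1L
      while (i <= length(lines) && grepl("^_", trimws(lines[i]))) i <- i + 1L
      while (i <= length(lines) &&
             !grepl("^(_|#|loop_|data_)", trimws(lines[i])) &&
             nzchar(trimws(lines[i]))) i <- i + 1L
      next
    }
    i <- i + 1L
  }
  out
}

cif_loops <- function(lines) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (identical(trimws(lines[i]), "loop_")) {
      cols <- character(0)
      i <- i + 1L
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        cols <- c(cols, cif_tokens(trimws(lines[i]))[1L])
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && !grepl("^(_|#|loop_|data_)", trimws(lines[i])) &&
             nzchar(trimws(lines[i]))) {
        rows[[length(rows) + 1L]] <- cif_tokens(trimws(lines[i]))
        i <- i + 1L
      }
      if (length(cols) && length(rows)) {
        ok <- vapply(rows, length, 1L) == length(cols)
        m <- do.call(rbind, rows[ok])
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- sub("^_[^.]*\\.", "", cols)
        category <- sub("^_", "", sub("\\..*$", "", cols[1L]))
        out[[category]] <- df
      }
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Write an mmCIF-style header for a synthetic entry
#'
#' Emits the minimal header categories [parse_mmcif_header()] consumes;
#' used by the fixture generator so that sequence-based repair has ground
#' truth to work from.
#'
#' @param entry_id entry identifier.
#' @param sequences named list per chain:
#'   `list(seq3 = <3-letter codes>, modeled = <logical>,
#'   resseq = <author numbers>)`.
#' @param resolution optional resolution in angstroms.
#' @param deposit_date ISO date string.
#' @param method experimental method string.
#' @return character vector of mmCIF lines.
#' @export
write_mmcif_header <- function(entry_id, sequences, resolution = 2.0,
                               deposit_date = "2024-01-01",
                               method = "X-RAY DIFFRACTION") {
  out <- c(
    paste0("data_", entry_id),
    paste0("_entry.id ", entry_id),
    paste0("_exptl.method '", method, "'"),
    paste0("_pdbx_database_status.recvd_initial_deposition_date ",
           deposit_date)
  )
  if (!is.na(resolution)) {
    out <- c(out, sprintf("_refine.ls_d_res_high %.2f", resolution))
  }
  out <- c(out, "loop_",
           "_pdbx_poly_seq_scheme.pdb_strand_id",
           "_pdbx_poly_seq_scheme.seq_id",
           "_pdbx_poly_seq_scheme.mon_id",
           "_pdbx_poly_seq_scheme.pdb_seq_num",
           "_pdbx_poly_seq_scheme.pdb_mon_id")
  for (ch in names(sequences)) {
    sq <- sequences[[ch]]
    out <- c(out, sprintf("%s %d %s %d %s", ch, seq_along(sq$seq3), sq$seq3,
                          sq$resseq,
                          ifelse(sq$modeled, sq$seq3, "?")))
  }
  c(out, "#")
}
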