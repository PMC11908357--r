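#' Workflow configuration
#'
#' Single home for every numeric threshold and rule constant the curation
#' workflow uses, so that all stages read one validated configuration.
#' Defaults are the workflow's frozen curation constants.
#'
#' @param ... named overrides of individual fields (see Details).
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{protein_assoc_cutoff}{10.0 A. A biopolymer chain with any heavy
#'     atom closer than this to a ligand heavy atom is part of the
#'     associated protein.}
#'   \item{additive_cutoff}{4.0 A. HETATM residues within this distance of
#'     the associated protein are kept as additives.}
#'   \item{clash_cutoff}{2.0 A. A protein-ligand heavy-atom pair closer
#'     than this is a steric clash and rejects the complex.}
#'   \item{min_heavy_atoms}{4. Ligands with fewer heavy atoms are rejected.}
#'   \item{polymer_ligand_min_residues}{2 (inclusive) and}
#'   \item{polymer_ligand_max_residues}{20 (exclusive): the residue-count
#'     window defining a polymer-class ligand.}
#'   \item{allowed_elements}{H, C, N, O, F, P, S, Cl, Br, I. Any other
#'     element in a ligand rejects the complex.}
#'   \item{missing_segment_max}{10 residues. Internal missing segments up
#'     to this length are rebuilt; longer gaps and terminal gaps are left.}
#'   \item{ph}{7.4, the pH at which protonation rules are framed.}
#'   \item{rotamer_angle_cutoff}{60 degrees on any side-chain chi angle
#'     defines a rotamer-state change.}
#'   \item{max_valid_ki}{1e3 M. Ki/Kd above this are invalid annotations.}
#'   \item{temperature}{298.15 K, used for delta-G conversion.}
#'   \item{gas_constant}{8.31446e-3 kJ/(mol K).}
#'   \item{bond_tolerance}{1.3; atoms are bonded when their distance is
#'     below the covalent-radius sum times this factor.}
#'   \item{planarity_tol_deg}{10 degrees: improper-dihedral tolerance for
#'     the sp2/sp3 geometry check.}
#'   \item{minimize_tol}{10 kJ/mol energy tolerance and}
#'   \item{minimize_max_iter}{10000 iteration cap for constrained
#'     relaxation.}
#' }
#'
#' @return an object of class `plc_config` (a validated named list).
#' @seealso [load_config()]
#' @examples
#' cfg <- plc_config()
#' cfg$clash_cutoff
#' plc_config(clash_cutoff = 2.5)$clash_cutoff
#' @export
plc_config <- function(...) {
  cfg <- list(
    protein_assoc_cutoff = 10.0,
    additive_cutoff = 4.0,
    clash_cutoff = 2.0,
    min_heavy_atoms = 4L,
    polymer_ligand_max_residues = 20L,
    polymer_ligand_min_residues = 2L,
    allowed_elements = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    missing_segment_max = 10L,
    ph = 7.4,
    rotamer_angle_cutoff = 60.0,
    max_valid_ki = 1.0e3,
    temperature = 298.15,
    gas_constant = 8.31446e-3,
    bond_tolerance = 1.3,
    planarity_tol_deg = 10.0,
    minimize_tol = 10.0,
    minimize_max_iter = 10000L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    }
    for (k in names(overrides)) {
      cfg[[k]] <- coerce_config_value(k, overrides[[k]])
    }
  }
  cfg <- structure(cfg, class = "plc_config")
  validate_config(cfg)
  cfg
}

coerce_config_value <- function(key, value) {
  int_keys <- c("min_heavy_atoms", "polymer_ligand_max_residues",
                "polymer_ligand_min_residues", "missing_segment_max",
                "minimize_max_iter")
  if (key == "allowed_elements") {
    if (is.character(value) && length(value) == 1L && grepl("[ ,]", value)) {
      value <- strsplit(value, "[ ,]+")[[1]]
    }
    return(as.character(value[nzchar(value)]))
  }
  if (key %in% int_keys) {
    iv <- suppressWarnings(as.integer(value))
    if (is.na(iv)) stop("configuration key '", key, "' must be an integer")
    return(iv)
  }
  nv <- suppressWarnings(as.numeric(value))
  if (length(nv) != 1L || is.na(nv)) {
    stop("configuration key '", key, "' must be a single number")
  }
  nv
}

validate_config <- function(cfg) {
  lengths <- c("protein_assoc_cutoff", "additive_cutoff", "clash_cutoff")
  for (k in lengths) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("configuration invariant violated: ", k, " must be > 0")
    }
  }
  if (cfg$clash_cutoff >= cfg$protein_assoc_cutoff) {
    stop("configuration invariant violated: clash_cutoff must be smaller ",
         "than protein_assoc_cutoff")
  }
  if (cfg$polymer_ligand_min_residues < 2L ||
      cfg$polymer_ligand_min_residues >= cfg$polymer_ligand_max_residues) {
    stop("configuration invariant violated: polymer ligand residue window ",
         "requires 2 <= min < max")
  }
  if (!all(c("C", "H") %in% cfg$allowed_elements)) {
    stop("configuration invariant violated: allowed_elements must contain ",
         "C and H")
  }
  if (cfg$min_heavy_atoms < 1L) {
    stop("configuration invariant violated: min_heavy_atoms must be >= 1")
  }
  if (cfg$temperature <= 0 || cfg$gas_constant <= 0) {
    stop("configuration invariant violated: temperature and gas_constant ",
         "must be positive")
  }
  invisible(cfg)
}

#' Load a configuration from a YAML file
#'
#' Reads a flat key-value YAML document and overlays it on the defaults of
#' [plc_config()]. Unknown keys and invariant violations are errors naming
#' the offending key.
#'
#' @param path optional path to a YAML file; `NULL` returns the defaults.
#' @return a validated `plc_config`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("clash_cutoff: 2.5", f)
#' load_config(f)$clash_cutoff
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(plc_config())
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed configuration file '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(vals)) return(plc_config())
  if (!is.list(vals) || is.null(names(vals)) || any(!nzchar(names(vals)))) {
    stop("malformed configuration file '", path,
         "': expected a flat key-value mapping")
  }
  do.call(plc_config, vals)
}

#' Serialize a configuration to YAML text
#'
#' Round-trips with [load_config()]: writing the returned text to a file and
#' loading it reproduces the same configuration field-for-field.
#'
#' @param cfg a `plc_config`.
#' @return a single YAML string.
#' @export
format_config <- function(cfg) {
  stopifnot(inherits(cfg, "plc_config"))
  yaml::as.yaml(unclass(cfg), precision = 12L)
}

#' @export
print.plc_config <- function(x, ...) {
  cat("<plc_config> curation thresholds\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-28s %s\n", k, paste(v, collapse = " ")))
  }
  invisible(x)
}
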