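# Idealized residue geometry for the 20 standard amino acids (atom names,
# elements and ideal coordinates including hydrogens), derived from the
# Chemical Component Dictionary ideal coordinate sets. Shipped as plain
# text in extdata and cached per session.

.template_env <- new.env(parent = emptyenv())

load_aa_templates <- function() {
  if (!is.null(.template_env$tbl)) return(.template_env$tbl)
  path <- system.file("extdata", "aa_templates.csv", package = "plcurate")
  if (!nzchar(path)) {
    # during development (load_all) fall back to the source tree
    path <- file.path("inst", "extdata", "aa_templates.csv")
  }
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  .template_env$tbl <- tbl
  tbl
}

#' Idealized template for a standard residue
#'
#' @param resname 3-letter residue name (MSE and other common variants are
#'   mapped to their standard parent).
#' @return data frame with columns `atom`, `element`, `x`, `y`, `z`, or
#'   `NULL` when no template exists.
#' @export
residue_template <- function(resname) {
  resname <- map_nonstandard_residue(resname)
  tbl <- load_aa_templates()
  t <- tbl[tbl$resname == resname, c("atom", "element", "x", "y", "z")]
  if (!nrow(t)) return(NULL)
  rownames(t) <- NULL
  t
}

# common non-standard residues mapped to standard repair templates
map_nonstandard_residue <- function(resname) {
  switch(resname,
         MSE = "MET", SEC = "CYS", HYP = "PRO", SEP = "SER", TPO = "THR",
         PTR = "TYR", CSO = "CYS", MLY = "LYS", resname)
}

# heavy template atom names a modeled residue is expected to have
# (OXT is terminal-only and never demanded)
template_heavy_atoms <- function(resname) {
  t <- residue_template(resname)
  if (is.null(t)) return(NULL)
  setdiff(t$atom[t$element != "H"], "OXT")
}

# Superpose the template of `resname` onto the residue's present heavy
# atoms; returns the transformed template data frame, or NULL when fewer
# than 3 atoms are shared.
fit_template <- function(res_atoms, resname) {
  t <- residue_template(resname)
  if (is.null(t)) return(NULL)
  common <- intersect(res_atoms$name, t$atom[t$element != "H"])
  if (length(common) < 3L) return(NULL)
  ra <- res_atoms[match(common, res_atoms$name), ]
  ta <- t[match(common, t$atom), ]
  fit <- kabsch(as.matrix(ta[, c("x", "y", "z")]),
                as.matrix(ra[, c("x", "y", "z")]))
  xyz <- apply_kabsch(as.matrix(t[, c("x", "y", "z")]), fit)
  t$x <- xyz[, 1]; t$y <- xyz[, 2]; t$z <- xyz[, 3]
  t
}
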