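# The four rejection filters. Each rule returns a verdict list(rule_id,
# passed, evidence); apply_filters evaluates all of them (no short-circuit)
# so reports are complete.

rule_verdict <- function(rule_id, passed, evidence = "") {
  list(rule_id = rule_id, passed = passed, evidence = evidence)
}

#' Covalent-binder filter
#'
#' Fails when any CONECT pair of the parent structure joins a ligand atom
#' to a protein atom; a structure without CONECT records passes vacuously.
#' LINK-style evidence is not consulted here: CONECT is the primary signal,
#' and clashes from unrecorded covalent bonds are caught by [check_clash()].
#'
#' @param bundle a `plc_bundle` from [extract_complex()].
#' @return a verdict list with `rule_id = "covalent"`.
#' @export
check_covalent <- function(bundle) {
  conect <- bundle$conect
  if (is.null(conect) || !nrow(conect)) {
    return(rule_verdict("covalent", TRUE))
  }
  lig <- bundle$ligand$atoms$serial
  prot <- bundle$protein$atoms$serial
  cross <- (conect[, 1] %in% lig & conect[, 2] %in% prot) |
    (conect[, 2] %in% lig & conect[, 1] %in% prot)
  if (any(cross)) {
    pairs <- conect[cross, , drop = FALSE]
    rule_verdict("covalent", FALSE, paste(
      sprintf("CONECT %d-%d joins ligand and protein",
              pairs[, 1], pairs[, 2]), collapse = "; "))
  } else {
    rule_verdict("covalent", TRUE)
  }
}

#' Rare-element filter
#'
#' Fails when any ligand atom's element is outside the allowed set
#' (default H, C, N, O, F, P, S, Cl, Br, I).
#'
#' @param ligand a `plc_ligand`.
#' @param cfg a [plc_config()].
#' @return a verdict list with `rule_id = "rare_element"`.
#' @export
check_elements <- function(ligand, cfg = plc_config()) {
  els <- ligand$atoms$element
  if (!all(is_known_element(els))) {
    stop("data error: unknown element symbol(s) in ligand ", ligand$key,
         ": ", paste(unique(els[!is_known_element(els)]), collapse = ", "))
  }
  bad <- setdiff(unique(els), cfg$allowed_elements)
  if (length(bad)) {
    rule_verdict("rare_element", FALSE,
                 paste("disallowed element(s):", paste(bad, collapse = ", ")))
  } else {
    rule_verdict("rare_element", TRUE)
  }
}

#' Small-ligand filter
#'
#' Fails when the ligand has fewer than `min_heavy_atoms` heavy atoms
#' (strictly less than; the boundary count passes).
#'
#' @inheritParams check_elements
#' @return a verdict list with `rule_id = "small_ligand"`.
#' @export
check_size <- function(ligand, cfg = plc_config()) {
  n <- sum(ligand$atoms$element != "H")
  if (n < cfg$min_heavy_atoms) {
    rule_verdict("small_ligand", FALSE,
                 sprintf("%d heavy atoms (< %d)", n, cfg$min_heavy_atoms))
  } else {
    rule_verdict("small_ligand", TRUE)
  }
}

#' Steric-clash filter
#'
#' Fails when the minimum protein-ligand heavy-atom distance is strictly
#' below `clash_cutoff`; a pair at exactly the cutoff passes. Additives
#' are not part of the scan. Evidence carries the minimal pair and its
#' distance.
#'
#' @inheritParams check_covalent
#' @param cfg a [plc_config()].
#' @return a verdict list with `rule_id = "clash"`.
#' @export
check_clash <- function(bundle, cfg = plc_config()) {
  prot <- heavy_atoms(bundle$protein$atoms)
  if (!nrow(prot)) {
    stop("precondition error: bundle has an empty protein")
  }
  lig <- heavy_atoms(bundle$ligand$atoms)
  d <- min_pair_distance(as.matrix(lig[, c("x", "y", "z")]),
                         as.matrix(prot[, c("x", "y", "z")]))
  if (d$min < cfg$clash_cutoff) {
    rule_verdict("clash", FALSE, sprintf(
      "ligand atom %s and protein atom %s/%s %d at %.3f A",
      lig$name[d$i], prot$chain[d$j], prot$name[d$j], prot$resseq[d$j],
      d$min))
  } else {
    rule_verdict("clash", TRUE)
  }
}

#' Apply the four rejection filters to a bundle
#'
#' Evaluates the covalent-binder, rare-element, small-ligand and
#' steric-clash rules (in that order, all of them — no short-circuit) and
#' aggregates a report.
#'
#' @inheritParams check_clash
#' @return an object of class `plc_filter_report`: list with `passed`
#'   (logical) and `failures` (data frame of `rule_id`, `evidence`).
#' @export
apply_filters <- function(bundle, cfg = plc_config()) {
  verdicts <- list(
    check_covalent(bundle),
    check_elements(bundle$ligand, cfg),
    check_size(bundle$ligand, cfg),
    check_clash(bundle, cfg)
  )
  fails <- Filter(function(v) !v$passed, verdicts)
  failures <- data.frame(
    rule_id = vapply(fails, `[[`, "", "rule_id"),
    evidence = vapply(fails, `[[`, "", "evidence"),
    stringsAsFactors = FALSE
  )
  structure(list(passed = nrow(failures) == 0L, failures = failures),
            class = "plc_filter_report")
}

#' @export
print.plc_filter_report <- function(x, ...) {
  if (x$passed) {
    cat("<plc_filter_report> passed all four filters\n")
  } else {
    cat("<plc_filter_report> FAILED:\n")
    for (i in seq_len(nrow(x$failures))) {
      cat(sprintf("  %-12s %s\n", x$failures$rule_id[i],
                  x$failures$evidence[i]))
    }
  }
  invisible(x)
}
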