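refined_fixture <- function(defects = character(0), seed = 41, ...) {
  fx <- make_fixture(fixture_spec(seed = seed, defects = defects, ...))
  s <- parse_pdb(fx$pdb)
  meta <- parse_mmcif_header(fx$cif)
  lig <- identify_ligands(s, ligand_spec("ccd", ccd_code = "LIG"))[[1]]
  bundle <- extract_complex(s, lig)
  prot <- repair_protein(bundle$protein, detect_missing(bundle$protein, meta),
                         meta)
  prot <- protonate_protein(prot)
  fix <- fix_ligand(lig, reference = fx$reference_smiles)
  stopifnot(fix$status == "fixed")
  list(protein = prot, ligand = fix$mol)
}

expect_constraint_contract <- function(protein0, result) {
  a0 <- protein0$atoms[protein0$atoms$is_experimental,
                       c("serial", "x", "y", "z")]
  a1 <- result$protein$atoms[result$protein$atoms$is_experimental,
                             c("serial", "x", "y", "z")]
  m <- merge(a0, a1, by = "serial")
  expect_identical(m$x.x, m$x.y)
  expect_identical(m$y.x, m$y.y)
  expect_identical(m$z.x, m$z.y)
  expect_equal(result$max_moved_constrained, 0)
  expect_lte(result$energy_final, result$energy_initial)
}

test_that("experimental atoms never move and energy never increases", {
  parts <- refined_fixture()
  res <- minimize_complex(parts$protein, parts$ligand)
  expect_constraint_contract(parts$protein, res)
  # ligand heavy atoms are experimental too
  h0 <- parts$ligand$atoms[parts$ligand$atoms$element != "H", c("x", "y", "z")]
  h1 <- res$ligand_mol$atoms[res$ligand_mol$atoms$element != "H",
                             c("x", "y", "z")]
  expect_identical(h0, h1)
})

test_that("rebuilt-loop strain is relieved without touching crystal atoms", {
  parts <- refined_fixture("delete_internal_segment", segment_length = 4L)
  res <- minimize_complex(parts$protein, parts$ligand)
  expect_constraint_contract(parts$protein, res)
  expect_lt(res$energy_final, res$energy_initial)
})

test_that("a hydrogen placed onto a protein atom is pushed out", {
  parts <- refined_fixture(seed = 43)
  prot <- parts$protein
  # drop one ligand hydrogen 0.5 A from a protein oxygen
  lig <- parts$ligand
  o_row <- which(prot$atoms$element == "O")[1]
  o_pos <- unlist(prot$atoms[o_row, c("x", "y", "z")])
  h_idx <- which(lig$atoms$element == "H")[1]
  lig$atoms[h_idx, c("x", "y", "z")] <- as.list(o_pos + c(0.5, 0, 0))
  res <- minimize_complex(prot, lig)
  expect_constraint_contract(prot, res)
  h_new <- unlist(res$ligand_mol$atoms[h_idx, c("x", "y", "z")])
  expect_gt(sqrt(sum((h_new - o_pos)^2)), 1.2)
})

test_that("relaxation is deterministic", {
  parts <- refined_fixture(seed = 44)
  r1 <- minimize_complex(parts$protein, parts$ligand)
  r2 <- minimize_complex(parts$protein, parts$ligand)
  expect_identical(r1$protein$atoms, r2$protein$atoms)
  expect_identical(r1$ligand_mol$atoms, r2$ligand_mol$atoms)
  expect_identical(r1$energy_final, r2$energy_final)
})

test_that("unknown force-field specs are refused", {
  parts <- refined_fixture(seed = 45)
  expect_error(minimize_complex(parts$protein, parts$ligand,
                                ff_spec = "amber-like"),
               "force-field")
})
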