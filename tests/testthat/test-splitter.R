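# A hand-built structure: one 3-residue polymer chain along x, a ligand
# copy in two chains, and HETATM extras at controlled distances.
atom_row <- function(serial, name, element, resname, chain, resseq, x, y, z,
                     record = "ATOM") {
  data.frame(serial = serial, name = name, alt = "", resname = resname,
             chain = chain, resseq = resseq, icode = "", x = x, y = y,
             z = z, occupancy = 1, element = element, record = record,
             is_experimental = TRUE, stringsAsFactors = FALSE)
}

split_structure <- function() {
  atoms <- rbind(
    atom_row(1, "CA", "C", "ALA", "A", 1, 0, 0, 0),
    atom_row(2, "CA", "C", "ALA", "A", 2, 3.8, 0, 0),
    atom_row(3, "CA", "C", "ALA", "A", 3, 7.6, 0, 0),
    atom_row(4, "C1", "C", "ATP", "A", 90, 0, 5, 0, "HETATM"),
    atom_row(5, "C1", "C", "ATP", "B", 90, 0, -5, 0, "HETATM"),
    atom_row(6, "ZN", "Zn", "ZN", "C", 1, 0, 3, 0, "HETATM"),
    atom_row(7, "O", "O", "HOH", "C", 2, 0, 0, 4.5, "HETATM"))
  plc_structure("TST1", atoms)
}

test_that("one ligand instance arises per residue copy", {
  s <- split_structure()
  ligs <- identify_ligands(s, ligand_spec("ccd", ccd_code = "ATP"))
  expect_length(ligs, 2L)
  expect_equal(vapply(ligs, function(l) l$atoms$chain, ""), c("A", "B"))
})

test_that("unmatched specs and out-of-bounds polymers are errors", {
  s <- split_structure()
  expect_error(identify_ligands(s, ligand_spec("ccd", ccd_code = "GTP")),
               "matches nothing")
  # polymer spec naming a chain beyond the class bound
  big <- do.call(rbind, lapply(1:25, function(i) {
    atom_row(i, "CA", "C", "ALA", "P", i, i * 3.8, 0, 0)
  }))
  sp <- plc_structure("TST2", big)
  expect_error(
    identify_ligands(sp, ligand_spec("polymer", chain_id = "P")),
    "class violation")
  # a single residue is below the polymer minimum
  one <- plc_structure("TST3", atom_row(1, "CA", "C", "ALA", "Q", 1, 0, 0, 0))
  expect_error(identify_ligands(one, ligand_spec("polymer", chain_id = "Q")),
               "class violation")
})

test_that("a five-residue peptide chain is a polymer ligand", {
  pep <- do.call(rbind, lapply(1:5, function(i) {
    atom_row(i, "CA", "C", "GLY", "P", i, i * 3.8, 0, 0)
  }))
  s <- plc_structure("TST4", pep)
  ligs <- identify_ligands(s, ligand_spec("polymer", chain_id = "P"))
  expect_length(ligs, 1L)
  expect_equal(ligs[[1]]$n_residues, 5L)
})

test_that("association and additive shells bracket their cutoffs", {
  s <- split_structure()
  lig <- identify_ligands(s, ligand_spec("ccd", ccd_code = "ATP"))[[1]]
  b <- extract_complex(s, lig)
  # chain A CA at distance 5: included whole (3 residues)
  expect_equal(unique(b$protein$atoms$chain), "A")
  expect_equal(nrow(b$protein$atoms), 3L)
  # Zn at 3.0 A from protein -> additive; water at 4.5 A -> excluded;
  # the other ATP copy is never an additive
  expect_true("ZN" %in% b$additives$resname)
  expect_false("HOH" %in% b$additives$resname)
  expect_false("ATP" %in% b$additives$resname)
})

test_that("chains outside the association cutoff are dropped and orphans error", {
  atoms <- rbind(
    atom_row(1, "CA", "C", "ALA", "A", 1, 0, 9.5, 0),
    atom_row(2, "CA", "C", "ALA", "B", 1, 0, 10.5, 0),
    atom_row(3, "C1", "C", "LIG", "L", 1, 0, 0, 0, "HETATM"))
  s <- plc_structure("TST5", atoms)
  lig <- identify_ligands(s, ligand_spec("ccd", ccd_code = "LIG"))[[1]]
  b <- extract_complex(s, lig)
  expect_equal(unique(b$protein$atoms$chain), "A")

  far <- plc_structure("TST6", rbind(
    atom_row(1, "CA", "C", "ALA", "A", 1, 0, 30, 0),
    atom_row(2, "C1", "C", "LIG", "L", 1, 0, 0, 0, "HETATM")))
  ligf <- identify_ligands(far, ligand_spec("ccd", ccd_code = "LIG"))[[1]]
  expect_error(extract_complex(far, ligf), "orphan")
})

test_that("roles are disjoint and extraction is deterministic", {
  fx <- make_fixture(fixture_spec(seed = 7))
  s <- parse_pdb(fx$pdb)
  lig <- identify_ligands(s, ligand_spec("ccd", ccd_code = "LIG"))[[1]]
  b1 <- extract_complex(s, lig)
  b2 <- extract_complex(s, lig)
  expect_identical(b1$protein$atoms, b2$protein$atoms)
  expect_identical(b1$additives, b2$additives)
  roles <- c(b1$ligand$atoms$serial, b1$protein$atoms$serial,
             b1$additives$serial)
  expect_equal(anyDuplicated(roles), 0L)
})
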