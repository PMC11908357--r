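test_that("bond perception follows covalent-radius distances", {
  two_c <- function(d) {
    atoms <- data.frame(
      serial = 1:2, name = c("C1", "C2"), alt = "", resname = "LIG",
      chain = "L", resseq = 1L, icode = "", x = c(0, d), y = 0, z = 0,
      occupancy = 1, element = "C", record = "HETATM",
      is_experimental = TRUE, stringsAsFactors = FALSE)
    plcurate:::new_ligand(ligand_spec("ccd", ccd_code = "LIG"), atoms,
                          "L|1|")
  }
  bonded <- suppressWarnings(perceive_from_geometry(two_c(1.54)))
  expect_equal(nrow(bonded$bonds), 1L)
  apart <- suppressWarnings(perceive_from_geometry(two_c(3.0)))
  expect_equal(nrow(apart$bonds), 0L)
  expect_equal(attr(apart, "n_fragments"), 2L)
})

test_that("an ideal benzene geometry perceives as a 6-ring", {
  lig <- smiles_ligand("c1ccccc1")
  m <- perceive_from_geometry(lig)
  expect_equal(nrow(m$bonds), 6L)
  g <- mol_to_igraph(m, heavy_only = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
  expect_true(all(igraph::degree(g) == 2))
})

test_that("peptide references chain amide bonds with free termini", {
  gg <- peptide_smiles("GG")
  ga <- mol_to_igraph(mol_from_smiles(gg$smiles))
  gb <- mol_to_igraph(mol_from_smiles("NCC(=O)NCC(=O)O"))
  expect_true(igraph::graph.isomorphic.vf2(
    ga, gb,
    vertex.color1 = plcurate:::element_colors(ga),
    vertex.color2 = plcurate:::element_colors(gb))$iso)

  galm <- mol_from_smiles(peptide_smiles("GA")$smiles)
  # two residues: one amide N-C(=O) joins them; one methyl side chain
  expect_equal(sum(galm$atoms$element == "N"), 2L)
  expect_equal(sum(galm$atoms$element == "O"), 3L)
  expect_equal(sum(galm$atoms$element == "C"), 5L)

  expect_error(peptide_smiles("GXG"), "unsupported residue")
  expect_error(peptide_smiles("A"), "at least 2")
})

test_that("reference precedence is override > lookup > peptide builder", {
  lig <- smiles_ligand("c1ccccc1O")
  lig$spec$ccd_code <- "PHN"
  overrides <- data.frame(code = "PHN", smiles = "c1ccccc1O",
                          stringsAsFactors = FALSE)
  r1 <- resolve_reference(lig, overrides = overrides,
                          fetcher = function(code) "CCCC")
  expect_equal(r1$source, "override-table")
  r2 <- resolve_reference(lig, fetcher = function(code) "c1ccccc1O")
  expect_equal(r2$source, "ccd-lookup")
  expect_error(resolve_reference(lig), "unresolvable")

  pep <- list(spec = ligand_spec("polymer", chain_id = "P"),
              atoms = data.frame(resname = c("GLY", "GLY"),
                                 chain = "P", resseq = 1:2, icode = "",
                                 stringsAsFactors = FALSE),
              key = "P|1|")
  class(pep) <- "plc_ligand"
  r3 <- resolve_reference(pep)
  expect_equal(r3$source, "peptide-builder")
})

test_that("the geometry check flags all-single-bond references", {
  lig <- smiles_ligand("c1ccccc1")
  inferred <- perceive_from_geometry(lig)
  bad <- plcurate:::new_reference("C1CCCCC1", "ccd-lookup")
  chk <- validate_reference_geometry(bad, inferred)
  expect_false(chk$ok)
  expect_match(chk$diagnostic, "planar")

  good <- plcurate:::new_reference("c1ccccc1", "ccd-lookup")
  expect_true(validate_reference_geometry(good, inferred)$ok)

  ethane <- smiles_ligand("CC")
  ok <- validate_reference_geometry(
    plcurate:::new_reference("CC", "ccd-lookup"),
    suppressWarnings(perceive_from_geometry(ethane)))
  expect_true(ok$ok)
})

test_that("bond orders transfer through element-labelled isomorphism", {
  lig <- smiles_ligand("c1ccccc1")
  inferred <- perceive_from_geometry(lig)
  out <- transfer_bond_orders(inferred,
                              plcurate:::new_reference("c1ccccc1", "x"))
  expect_equal(out$status, "fixed")
  expect_true(all(out$mol$bonds$aromatic))
  expect_equal(sort(out$mol$bonds$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  # crystal coordinates preserved exactly
  expect_identical(out$mol$atoms$x, inferred$atoms$x)
})

test_that("missing atoms and wrong connectivity yield mismatch outcomes", {
  lig <- smiles_ligand("Ic1ccccc1")
  inferred <- perceive_from_geometry(lig)
  # reference with the iodine missing (atom-count difference)
  out <- transfer_bond_orders(inferred,
                              plcurate:::new_reference("c1ccccc1", "x"))
  expect_equal(out$status, "mismatch")
  expect_match(out$diagnostic, "atom count")

  # isopropyl crystal vs cyclopropyl reference (same composition,
  # different connectivity)
  iso <- smiles_ligand("CC(C)c1ccccc1")
  out2 <- transfer_bond_orders(
    perceive_from_geometry(iso),
    plcurate:::new_reference("C1CC1c1ccccc1", "x"))
  expect_equal(out2$status, "mismatch")
  expect_match(out2$diagnostic, "connectivity")
})

test_that("fix_ligand composes the stages and preserves heavy-atom coordinates", {
  lig <- smiles_ligand("CC(=O)Nc1ccc(O)cc1")
  out <- fix_ligand(lig, reference = "CC(=O)Nc1ccc(O)cc1")
  expect_equal(out$status, "fixed")
  fixed_heavy <- out$mol$atoms[out$mol$atoms$element != "H", ]
  expect_equal(fixed_heavy$x, lig$atoms$x)
  expect_equal(fixed_heavy$y, lig$atoms$y)
  expect_equal(fixed_heavy$z, lig$atoms$z)
  expect_true(sum(out$mol$atoms$element == "H") > 0)

  # forced mismatch: delete one atom
  short <- lig
  short$atoms <- short$atoms[-nrow(short$atoms), ]
  out2 <- fix_ligand(short, reference = "CC(=O)Nc1ccc(O)cc1")
  expect_equal(out2$status, "mismatch")

  # forced bad reference: saturated SMILES against aromatic geometry
  out3 <- fix_ligand(lig, reference = "CC(O)NC1CCC(O)CC1")
  expect_equal(out3$status, "bad-reference")
})
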