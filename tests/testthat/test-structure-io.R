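minimal_pdb <- c(
  "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
  "END")

test_that("minimal documents and CONECT records parse", {
  s <- parse_pdb(minimal_pdb, entry_id = "TEST")
  expect_s3_class(s, "plc_structure")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$name, "CA")
  expect_equal(s$atoms$resseq, 1L)

  with_conect <- c(
    "HETATM   10  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM   20  O1  LIG L   1       1.200   0.000   0.000  1.00  0.00           O",
    "CONECT   10   20", "END")
  s2 <- parse_pdb(with_conect)
  expect_equal(nrow(s2$conect), 1L)
  expect_equal(sort(s2$conect[1, ]), c(10L, 20L))
})

test_that("insertion codes and model selection are honored", {
  pdb <- c(
    "MODEL        1",
    "ATOM      1  CA  TYR A 100B     1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  TYR A 100B     9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END")
  s1 <- parse_pdb(pdb)
  expect_equal(s1$atoms$resseq, 100L)
  expect_equal(s1$atoms$icode, "B")
  expect_equal(s1$atoms$x, 1.0)
  s2 <- parse_pdb(pdb, model = 2)
  expect_equal(s2$atoms$x, 9.0)
  expect_error(parse_pdb(pdb, model = 3), "model 3")
})

test_that("alt-locs resolve to the highest-occupancy conformer", {
  pdb <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "END")
  s <- parse_pdb(pdb)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 5.0)
})

test_that("degenerate documents raise informative errors", {
  expect_error(parse_pdb(c("HEADER    NOTHING", "END")), "empty structure")
  bad <- c("ATOM      1  CA  ALA A   1       xx.000   2.000   3.000",
           "END")
  expect_error(parse_pdb(bad), "line 1")
})

test_that("PDB writer round-trips structures including added-atom flags", {
  fx <- make_fixture(fixture_spec(seed = 11,
                                  defects = "delete_side_chain_atom"))
  s <- parse_pdb(fx$pdb)
  meta <- parse_mmcif_header(fx$cif)
  rep1 <- repair_protein(s, detect_missing(s, meta), meta)
  txt <- write_pdb(rep1, fix_annotations = attr(rep1, "repairs"))
  expect_true(any(grepl("REMARK  99 FIX", txt)))
  expect_true(any(grepl("REMARK  99 ADDED ATOM", txt)))
  s2 <- parse_pdb(txt)
  expect_equal(nrow(s2$atoms), nrow(rep1$atoms))
  expect_equal(sum(!s2$atoms$is_experimental),
               sum(!rep1$atoms$is_experimental))
  a <- rep1$atoms[order(rep1$atoms$chain, rep1$atoms$resseq, rep1$atoms$name), ]
  b <- s2$atoms[order(s2$atoms$chain, s2$atoms$resseq, s2$atoms$name), ]
  expect_equal(a$x, b$x, tolerance = 1e-3)
  expect_equal(a$element, b$element)
})

test_that("annotation-free writes carry no fix remarks", {
  s <- parse_pdb(minimal_pdb)
  txt <- write_pdb(s)
  expect_false(any(grepl("REMARK  99", txt)))
})

test_that("mmCIF headers yield per-position modeled flags", {
  seqs <- list(A = list(seq3 = c("ALA", "CYS", "ASP", "GLU", "PHE"),
                        resseq = 1:5,
                        modeled = c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  meta <- parse_mmcif_header(write_mmcif_header("1ABC", seqs))
  expect_equal(meta$entry_id, "1ABC")
  expect_equal(meta$full_sequences$A$seq, "ACDEF")
  expect_equal(meta$full_sequences$A$modeled,
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(meta$resolution, 2.0)

  # resolution is optional (e.g. NMR entries)
  meta2 <- parse_mmcif_header(
    write_mmcif_header("1ABC", seqs, resolution = NA))
  expect_true(is.na(meta2$resolution))

  # a header without the sequence category is a metadata error
  expect_error(parse_mmcif_header(c("data_X", "_entry.id X")),
               "sequence category")
})

test_that("header sequences longer than the modeled chain flag the tail", {
  seqs <- list(A = list(seq3 = rep("ALA", 8), resseq = 1:8,
                        modeled = c(rep(TRUE, 5), rep(FALSE, 3))))
  meta <- parse_mmcif_header(write_mmcif_header("2DEF", seqs))
  expect_equal(sum(!meta$full_sequences$A$modeled), 3L)
  expect_equal(which(!meta$full_sequences$A$modeled), 6:8)
})

test_that("SDF writer encodes charges in the charge block and round-trips", {
  acetate <- mol_from_smiles("CC(=O)[O-]", coords = "3d")
  txt <- write_sdf(acetate)
  expect_true(any(grepl("^M  CHG", strsplit(txt, "\n")[[1]])))
  back <- parse_sdf(txt)
  expect_true(chem_equal(acetate, back))
  expect_equal(mol_net_charge(back), -1L)

  methane <- plc_mol(
    data.frame(element = "C", charge = 0L, hyb = "sp3", aromatic = FALSE,
               x = 0, y = 0, z = 0),
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0)))
  lines <- strsplit(write_sdf(methane), "\n")[[1]]
  expect_match(lines[4], "^  1  0")
})
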