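fixture_parts <- function(defects = character(0), seed = 31, ...) {
  fx <- make_fixture(fixture_spec(seed = seed, defects = defects, ...))
  s <- parse_pdb(fx$pdb)
  meta <- parse_mmcif_header(fx$cif)
  lig <- identify_ligands(s, ligand_spec("ccd", ccd_code = "LIG"))[[1]]
  bundle <- extract_complex(s, lig)
  list(fx = fx, s = s, meta = meta, bundle = bundle)
}

test_that("terminal and internal gaps classify by the length rules", {
  p <- fixture_parts("delete_terminal_segment", segment_length = 3L)
  r <- detect_missing(p$bundle$protein, p$meta)
  expect_equal(nrow(r$segments), 1L)
  expect_true(r$segments$terminal)
  expect_false(r$segments$repair)
  expect_equal(r$segments$length, 3L)

  p2 <- fixture_parts("delete_internal_segment", segment_length = 4L)
  r2 <- detect_missing(p2$bundle$protein, p2$meta)
  expect_false(r2$segments$terminal)
  expect_true(r2$segments$repair)

  # an internal gap beyond the limit is detected but not repaired
  p3 <- fixture_parts("delete_internal_segment", segment_length = 12L,
                      n_res = 30L)
  r3 <- detect_missing(p3$bundle$protein, p3$meta)
  expect_false(r3$segments$repair)
  expect_equal(r3$segments$length, 12L)

  # a 10-residue gap sits exactly at the limit and is rebuilt
  p4 <- fixture_parts("delete_internal_segment", segment_length = 10L,
                      n_res = 30L)
  expect_true(detect_missing(p4$bundle$protein, p4$meta)$segments$repair)
})

test_that("a deleted side-chain atom is detected and re-added", {
  p <- fixture_parts("delete_side_chain_atom")
  r <- detect_missing(p$bundle$protein, p$meta)
  expect_equal(r$missing_atoms$atom, "NZ")
  expect_equal(r$missing_atoms$resname, "LYS")

  rep1 <- repair_protein(p$bundle$protein, r, p$meta)
  expect_true("NZ" %in% rep1$atoms$name[rep1$atoms$resname == "LYS"])
  added <- rep1$atoms[!rep1$atoms$is_experimental, ]
  expect_equal(added$name, "NZ")
  # the rebuilt NZ lands at a chemically plausible CE distance
  lys <- rep1$atoms[rep1$atoms$resname == "LYS", ]
  d <- sqrt(sum((unlist(lys[lys$name == "NZ", c("x", "y", "z")]) -
                   unlist(lys[lys$name == "CE", c("x", "y", "z")]))^2))
  expect_lt(abs(d - 1.49), 0.25)
})

test_that("repair rebuilds allowed gaps, skips the rest, and is idempotent", {
  p <- fixture_parts("delete_internal_segment", segment_length = 4L)
  before <- p$bundle$protein
  r <- detect_missing(before, p$meta)
  rep1 <- repair_protein(before, r, p$meta)

  added <- rep1$atoms[!rep1$atoms$is_experimental, ]
  expect_equal(length(unique(added$resseq)), 4L)
  expect_true(all(!added$is_experimental))
  # experimental atoms are untouched, to full precision
  kept <- rep1$atoms[rep1$atoms$is_experimental, ]
  expect_equal(nrow(kept), nrow(before$atoms))
  m <- merge(before$atoms[, c("serial", "x", "y", "z")],
             kept[, c("serial", "x", "y", "z")], by = "serial")
  expect_identical(m$x.x, m$x.y)
  expect_identical(m$z.x, m$z.y)

  # idempotence
  r2 <- detect_missing(rep1, p$meta)
  expect_equal(nrow(r2$missing_atoms), 0L)
  expect_equal(nrow(r2$segments), 0L)
  rep2 <- repair_protein(rep1, r2, p$meta)
  expect_equal(nrow(rep2$atoms), nrow(rep1$atoms))

  # terminal gaps stay absent
  pt <- fixture_parts("delete_terminal_segment", segment_length = 3L)
  rt <- repair_protein(pt$bundle$protein,
                       detect_missing(pt$bundle$protein, pt$meta), pt$meta)
  expect_equal(nrow(rt$atoms[!rt$atoms$is_experimental, ]), 0L)
})

test_that("a chain absent from the header is a metadata error", {
  p <- fixture_parts()
  meta <- p$meta
  names(meta$full_sequences) <- "Z"
  expect_error(detect_missing(p$bundle$protein, meta), "metadata error")
})

test_that("protonation applies the fixed titration rules", {
  p <- fixture_parts()
  pr <- protonate_protein(p$bundle$protein)
  a <- pr$atoms

  # LYS: three protons on the terminal amine
  expect_equal(sum(grepl("^HZ", a$name[a$resname == "LYS"])), 3L)
  # ASP: no carboxyl proton
  expect_false("HD2" %in% a$name[a$resname == "ASP"])
  # HIS: exactly one of HD1/HE2
  his_h <- a$name[a$resname == "HIS" & a$element == "H"]
  expect_equal(sum(c("HD1", "HE2") %in% his_h), 1L)
  # free CYS keeps its thiol proton
  expect_true("HG" %in% a$name[a$resname == "CYS"])
  # every hydrogen is marked non-experimental; heavy atoms unmoved
  expect_true(all(!a$is_experimental[a$element == "H"]))
  m <- merge(p$bundle$protein$atoms[, c("serial", "x")],
             a[a$element != "H", c("serial", "x")], by = "serial")
  expect_identical(m$x.x, m$x.y)
  # count conservation
  expect_equal(nrow(a), nrow(p$bundle$protein$atoms) +
                 sum(a$element == "H"))
})

test_that("histidine tautomer follows the hydrogen-bond criterion", {
  # place an acceptor near the template HD1 position: expect HID
  p <- fixture_parts()
  prot <- p$bundle$protein
  his <- prot$atoms[prot$atoms$resname == "HIS", ]
  t <- plcurate:::fit_template(his, "HIS")
  hd1 <- unlist(t[t$atom == "HD1", c("x", "y", "z")])
  nd1 <- unlist(his[his$name == "ND1", c("x", "y", "z")])
  acc_pos <- hd1 + (hd1 - nd1) / sqrt(sum((hd1 - nd1)^2)) * 1.8
  acceptor <- prot$atoms[1, ]
  acceptor$serial <- max(prot$atoms$serial) + 1L
  acceptor$name <- "O"
  acceptor$element <- "O"
  acceptor$resname <- "HOH"
  acceptor$chain <- "W"
  acceptor$record <- "HETATM"
  acceptor[, c("x", "y", "z")] <- as.list(acc_pos)
  prot$atoms <- rbind(prot$atoms, acceptor)
  pr <- protonate_protein(prot)
  expect_equal(unname(attr(pr, "his_variants")[grep("12",
    names(attr(pr, "his_variants")))]), "HID")
})

test_that("disulfide cysteines lose the thiol proton", {
  p <- fixture_parts()
  prot <- p$bundle$protein
  # add a second CYS whose SG sits 2.0 A from the existing one
  cys <- prot$atoms[prot$atoms$resname == "CYS", ]
  sg <- cys[cys$name == "SG", ]
  partner <- cys
  partner$serial <- max(prot$atoms$serial) + seq_len(nrow(partner))
  partner$resseq <- 99L
  # translate the copy so its SG lies 2.0 A from the original SG
  partner[, c("x", "y", "z")] <- sweep(as.matrix(cys[, c("x", "y", "z")]),
                                       2, c(2.0, 0, 0), "+")
  prot$atoms <- rbind(prot$atoms, partner)
  pr <- protonate_protein(prot)
  expect_false("HG" %in% pr$atoms$name[pr$atoms$resname == "CYS"])
})
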