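two_chain_fixture <- function(rotate = NULL, angle = 90) {
  fx <- make_fixture(fixture_spec(seed = 51))
  s <- parse_pdb(fx$pdb)
  lig <- identify_ligands(s, ligand_spec("ccd", ccd_code = "LIG"))[[1]]
  a <- s$atoms[s$atoms$chain == "A", ]
  b <- a
  b$chain <- "B"
  if (!is.null(rotate)) b <- rotate_side_chain(b, rotate, angle)
  list(a = a, b = b, lig = lig)
}

test_that("rotamer changes bracket the 60-degree cutoff", {
  lys_pos <- 5L
  ch <- two_chain_fixture(rotate = lys_pos, angle = 65)
  cmp <- compare_rotamers(ch$a, ch$b, ch$lig)
  row <- cmp$residues[cmp$residues$resseq == lys_pos, ]
  expect_true(row$changed)
  expect_gt(row$max_chi_diff, 60)

  ch2 <- two_chain_fixture(rotate = lys_pos, angle = 55)
  cmp2 <- compare_rotamers(ch2$a, ch2$b, ch2$lig)
  expect_false(cmp2$residues$changed[cmp2$residues$resseq == lys_pos])

  # identical chains: nothing changes, ALA carries no chi
  ch3 <- two_chain_fixture()
  cmp3 <- compare_rotamers(ch3$a, ch3$b, ch3$lig)
  expect_equal(cmp3$n_changed, 0L)
  expect_false(any(cmp3$residues$has_chi[cmp3$residues$resname == "ALA"]))
})

test_that("chi differences use the periodic metric", {
  # enumerated brute force over the angle grid
  brute <- function(a, b) {
    d <- abs(a - b)
    min(d, 360 - d)
  }
  grid <- seq(-175, 180, by = 35)
  for (a in grid) for (b in grid) {
    expect_equal(plcurate:::angle_diff_periodic(a, b), brute(a, b))
  }
  expect_equal(plcurate:::angle_diff_periodic(-179, 179), 2)
  # symmetric terminal chi (ASP chi2) folds by 180 degrees
  expect_equal(plcurate:::chi_difference(170, -10, "ASP", 2L), 0)
  expect_equal(plcurate:::chi_difference(170, -10, "LYS", 2L), 180)
})

test_that("rotamer comparison is symmetric in its chains", {
  ch <- two_chain_fixture(rotate = 5L, angle = 75)
  f <- compare_rotamers(ch$a, ch$b, ch$lig)
  r <- compare_rotamers(ch$b, ch$a, ch$lig)
  expect_equal(f$n_changed, r$n_changed)
  expect_equal(f$n_near_site, r$n_near_site)
  expect_equal(f$residues$changed, r$residues$changed)
})

test_that("sequence-mismatched chains are a pairing error", {
  ch <- two_chain_fixture()
  ch$b$resname[ch$b$resseq == 5] <- "ARG"
  expect_error(compare_rotamers(ch$a, ch$b, ch$lig), "pairing error")
})

test_that("superposed RMSD matches a brute-force quaternion oracle", {
  # oracle: quaternion-parameterized rigid search on small instances
  quat_rmsd <- function(a, b, n_grid = 14) {
    a <- sweep(a, 2, colMeans(a))
    b <- sweep(b, 2, colMeans(b))
    best <- Inf
    gr <- seq(-1, 1, length.out = n_grid)
    for (q1 in gr) for (q2 in gr) for (q3 in gr) for (q4 in gr) {
      n <- sqrt(q1^2 + q2^2 + q3^2 + q4^2)
      if (n < 1e-6) next
      q <- c(q1, q2, q3, q4) / n
      R <- matrix(c(
        1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
        2 * (q[2] * q[4] + q[3] * q[1]),
        2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
        2 * (q[3] * q[4] - q[2] * q[1]),
        2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
        1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
      best <- min(best, sqrt(mean(rowSums((a %*% t(R) - b)^2))))
    }
    best
  }
  set.seed(7)
  for (rep in 1:3) {
    a <- matrix(rnorm(12), 4)
    b <- matrix(rnorm(12), 4)
    expect_equal(compute_rmsd(a, b), quat_rmsd(a, b), tolerance = 0.02)
    expect_lte(compute_rmsd(a, b), quat_rmsd(a, b) + 1e-9)
  }
})

test_that("RMSD is rigid-transform invariant and exact on matched sets", {
  set.seed(8)
  a <- matrix(rnorm(18), 6)
  expect_equal(compute_rmsd(a, a), 0)
  expect_equal(compute_rmsd(a, sweep(a, 2, c(1, 0, 0), "+")), 0,
               tolerance = 1e-9)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(compute_rmsd(a %*% R, a), 0, tolerance = 1e-9)
  expect_error(compute_rmsd(a, a[1:3, ]), "correspondence")
})

test_that("count descriptors are exact on hand-checked molecules", {
  cases <- list(
    list(smi = "c1ccccc1", heavy = 6L, hbd = 0L, hba = 0L, rotb = 0L,
         mw = 78.11),
    list(smi = "CC(=O)Oc1ccccc1C(=O)O", heavy = 13L, hbd = 1L, hba = 4L,
         rotb = 3L, mw = 180.16),                       # aspirin
    list(smi = "CC(=O)Nc1ccc(O)cc1", heavy = 11L, hbd = 2L, hba = 3L,
         rotb = 1L, mw = 151.16),                       # paracetamol
    list(smi = "OCCO", heavy = 4L, hbd = 2L, hba = 2L, rotb = 1L,
         mw = 62.07),
    list(smi = "O=C=O", heavy = 3L, hbd = 0L, hba = 2L, rotb = 0L,
         mw = 44.01))
  for (cs in cases) {
    mol <- mol_add_hydrogens(mol_from_smiles(cs$smi, coords = "3d"))
    p <- ligand_properties(mol)
    expect_equal(p$n_heavy_atoms, cs$heavy, label = cs$smi)
    expect_equal(p$n_hbd, cs$hbd, label = cs$smi)
    expect_equal(p$n_hba, cs$hba, label = cs$smi)
    expect_equal(p$n_rotatable_bonds, cs$rotb, label = cs$smi)
    expect_equal(p$molecular_weight, cs$mw, tolerance = 1e-3,
                 label = cs$smi)
    expect_gte(p$qed, 0)
    expect_lte(p$qed, 1)
  }
})

test_that("the QED desirability composite reproduces reference values", {
  # descriptor vectors evaluated independently with the published
  # parameterization (oracle: the original desirability functions run in
  # the rdkit implementation on these exact inputs)
  expect_equal(qed_score(mw = 286.34, alogp = 1.95, hba = 4, hbd = 1,
                         psa = 72.2, rotb = 4, arom = 3, alerts = 0),
               0.795367, tolerance = 1e-4)
  expect_equal(qed_score(mw = 720, alogp = 6.5, hba = 12, hbd = 6,
                         psa = 190, rotb = 14, arom = 5, alerts = 3),
               0.041574, tolerance = 1e-4)
  # monotone degradation with added violations
  q_base <- qed_score(300, 2.5, 4, 1, 60, 4, 2, 0)
  q_heavy <- qed_score(720, 6.5, 12, 6, 190, 14, 5, 3)
  expect_gt(q_base, q_heavy)
})
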