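fixture_bundle <- function(defects = character(0), seed = 21, ...) {
  fx <- make_fixture(fixture_spec(seed = seed, defects = defects, ...))
  s <- parse_pdb(fx$pdb)
  lig <- identify_ligands(s, ligand_spec("ccd", ccd_code = "LIG"))[[1]]
  extract_complex(s, lig)
}

test_that("covalent rule fires on ligand-protein CONECT only", {
  b <- fixture_bundle("add_covalent_conect")
  v <- check_covalent(b)
  expect_false(v$passed)
  expect_match(v$evidence, "CONECT")

  clean <- fixture_bundle()
  # intra-ligand CONECT pairs are present in every fixture and are fine
  expect_true(nrow(clean$conect) > 0)
  expect_true(check_covalent(clean)$passed)

  no_conect <- clean
  no_conect$conect <- matrix(integer(0), ncol = 2)
  expect_true(check_covalent(no_conect)$passed)
})

test_that("element rule rejects Se and B but accepts organics", {
  b <- fixture_bundle("swap_element_to")
  v <- check_elements(b$ligand)
  expect_false(v$passed)
  expect_match(v$evidence, "Se")

  clean <- fixture_bundle()
  expect_true(check_elements(clean$ligand)$passed)

  boron <- clean
  boron$ligand$atoms$element[1] <- "B"
  expect_false(check_elements(boron$ligand)$passed)

  unknown <- clean
  unknown$ligand$atoms$element[1] <- "Qq"
  expect_error(check_elements(unknown$ligand), "data error")
})

test_that("size rule is strict at the heavy-atom boundary", {
  tiny <- fixture_bundle("tiny_ligand")
  expect_equal(sum(tiny$ligand$atoms$element != "H"), 3L)
  expect_false(check_size(tiny$ligand)$passed)

  # exactly 4 heavy atoms passes ("less than 4" is strict)
  four <- tiny
  extra <- four$ligand$atoms[1, ]
  extra$serial <- max(four$ligand$atoms$serial) + 1L
  extra$x <- extra$x + 1.4
  four$ligand$atoms <- rbind(four$ligand$atoms, extra)
  expect_true(check_size(four$ligand)$passed)
})

test_that("clash rule brackets the 2 A cutoff with strict inequality", {
  b <- fixture_bundle("create_clash", clash_distance = 1.8)
  v <- check_clash(b)
  expect_false(v$passed)
  expect_match(v$evidence, "1.8")

  ok <- fixture_bundle(placement = 3.5)
  expect_true(check_clash(ok)$passed)

  # an exactly-2.0 A pair passes: "closer than" is a strict inequality
  exact <- ok
  exact$ligand$atoms <- exact$ligand$atoms[1, ]
  exact$protein$atoms <- exact$protein$atoms[1, ]
  exact$ligand$atoms[, c("x", "y", "z")] <- list(0, 0, 0)
  exact$protein$atoms[, c("x", "y", "z")] <- list(2.0, 0, 0)
  expect_true(check_clash(exact)$passed)
  exact$protein$atoms[, "x"] <- 1.999
  expect_false(check_clash(exact)$passed)

  empty <- ok
  empty$protein$atoms <- empty$protein$atoms[0, ]
  expect_error(check_clash(empty), "precondition")
})

test_that("reports aggregate all rules without short-circuiting", {
  clean <- fixture_bundle()
  r <- apply_filters(clean)
  expect_true(r$passed)
  expect_equal(nrow(r$failures), 0L)

  both <- fixture_bundle(c("swap_element_to", "create_clash"),
                         clash_distance = 1.5)
  r2 <- apply_filters(both)
  expect_false(r2$passed)
  expect_setequal(r2$failures$rule_id, c("rare_element", "clash"))
})

test_that("a covalent bond stripped of its CONECT is caught by the clash rule", {
  b <- fixture_bundle("create_clash", clash_distance = 1.5)
  b$conect <- matrix(integer(0), ncol = 2)
  r <- apply_filters(b)
  expect_false(r$passed)
  expect_true("clash" %in% r$failures$rule_id)
  expect_false("covalent" %in% r$failures$rule_id)
})

test_that("check_clash agrees with a brute-force scan and is monotone in the cutoff", {
  set.seed(42)
  base <- fixture_bundle()
  lx <- as.matrix(base$ligand$atoms[, c("x", "y", "z")])
  px <- as.matrix(base$protein$atoms[
    base$protein$atoms$element != "H", c("x", "y", "z")])
  for (rep in 1:25) {
    b <- base
    shift <- stats::rnorm(3, sd = 3)
    b$ligand$atoms[, c("x", "y", "z")] <- sweep(lx, 2, shift, "+")
    brute <- min(sqrt(outer(rowSums(sweep(lx, 2, shift, "+")^2),
                            rowSums(px^2), "+") -
                        2 * tcrossprod(sweep(lx, 2, shift, "+"), px)))
    v <- check_clash(b)
    expect_equal(v$passed, brute >= 2.0)
    # shrinking the cutoff never converts a passing bundle to failing
    if (v$passed) {
      expect_true(check_clash(b, plc_config(clash_cutoff = 1.0))$passed)
    } else {
      # and a failing bundle keeps failing under any larger cutoff
      expect_false(check_clash(b, plc_config(clash_cutoff = 3.0))$passed)
    }
  }
})
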