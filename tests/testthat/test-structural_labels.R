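test_that("group_by_compound partitions by 14-character prefix", {
  a1 <- toy_spectrum("a1", inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N")
  a2 <- toy_spectrum("a2", inchikey = "AAAAAAAAAAAAAA-CCCCCCCCCC-N")
  b1 <- toy_spectrum("b1", inchikey = "DDDDDDDDDDDDDD-BBBBBBBBBB-N")
  g <- group_by_compound(list(a1, a2, b1))
  expect_identical(names(g), c("AAAAAAAAAAAAAA", "DDDDDDDDDDDDDD"))
  expect_length(g[["AAAAAAAAAAAAAA"]], 2L)
  expect_length(group_by_compound(list()), 0L)
  nokey <- toy_spectrum("x", inchikey = NULL)
  expect_error(group_by_compound(list(nokey)), "x")
})

test_that("representative structure is the mode, ties broken lexicographically", {
  mk <- function(id, smiles) toy_spectrum(id, smiles = smiles)
  grp <- list(mk("1", "CCO"), mk("2", "CCO"), mk("3", "CCO"), mk("4", "OCC"))
  expect_identical(select_representative_structure(grp), "CCO")
  expect_identical(select_representative_structure(list(mk("1", "c1ccccc1"))),
                   "c1ccccc1")
  tie <- list(mk("1", "B"), mk("2", "A"), mk("3", "B"), mk("4", "A"))
  expect_identical(select_representative_structure(tie), "A")
})

test_that("tanimoto and dice match brute-force set counting", {
  a <- fingerprint(c(1, 2, 3), n_bits = 16, positions = TRUE)
  b <- fingerprint(c(2, 3, 4), n_bits = 16, positions = TRUE)
  expect_equal(tanimoto(a, b), 0.5)         # |I|=2, |U|=4
  expect_equal(dice(a, b), 2 / 3)           # 2*2/(3+3)
  expect_equal(tanimoto(a, a), 1.0)
  disjoint <- fingerprint(c(10, 11), n_bits = 16, positions = TRUE)
  expect_equal(tanimoto(a, disjoint), 0.0)
  expect_equal(dice(a, disjoint), 0.0)
  zero <- fingerprint(integer(0), n_bits = 16, positions = TRUE)
  expect_equal(tanimoto(zero, zero), 0.0)   # 0/0 convention
  expect_error(tanimoto(a, fingerprint(1, n_bits = 8, positions = TRUE)),
               "lengths differ")
})

test_that("dice >= tanimoto on random fingerprints, equal only at 0 and 1", {
  set.seed(8)
  for (i in 1:50) {
    a <- rbinom(64, 1, 0.3)
    b <- rbinom(64, 1, 0.3)
    t <- tanimoto(a, b); d <- dice(a, b)
    expect_gte(d, t)
    if (d == t) expect_true(t %in% c(0, 1))
    expect_equal(t, oracle_tanimoto(a, b))
    expect_equal(d, oracle_dice(a, b))
  }
})

test_that("label matrix matches the brute-force double loop exactly", {
  set.seed(9)
  fps <- stats::setNames(lapply(1:5, function(i)
    fingerprint(rbinom(32, 1, 0.4), fp_type = "synthetic")),
    paste0(sprintf("KEY%011d", 1:5)))
  for (metric in c("tanimoto", "dice")) {
    lm <- build_label_matrix(fingerprints = fps, metric = metric)
    oracle <- if (metric == "tanimoto") oracle_tanimoto else oracle_dice
    for (i in 1:5) for (j in 1:5) {
      expected <- if (i == j) 1.0 else oracle(fps[[i]]$bits, fps[[j]]$bits)
      expect_equal(lm$scores[i, j], expected)
    }
    expect_identical(lm$scores, t(lm$scores))
    expect_equal(unname(diag(lm$scores)), rep(1, 5))
  }
})

test_that("label matrix is permutation-equivariant in compound order", {
  set.seed(10)
  fps <- stats::setNames(lapply(1:6, function(i)
    fingerprint(rbinom(32, 1, 0.3))), paste0("K", 1:6))
  lm <- build_label_matrix(fingerprints = fps)
  perm <- c(4, 1, 6, 2, 5, 3)
  lm2 <- build_label_matrix(fingerprints = fps[perm])
  expect_equal(lm2$scores, lm$scores[perm, perm])
})

test_that("RDKit fingerprints are deterministic and canonicalized", {
  ## two SMILES spellings of ethanol must give identical daylight bits
  f1 <- compute_fingerprint("CCO", "daylight", 512)
  f2 <- compute_fingerprint("OCC", "daylight", 512)
  expect_identical(f1$bits, f2$bits)
  expect_identical(f1$n_bits, 512L)
  f3 <- compute_fingerprint("CCO", "daylight", 512)
  expect_identical(f1$bits, f3$bits)
  ## morgan bits differ from daylight bits for a non-trivial molecule
  m2 <- compute_fingerprint("CC(=O)Oc1ccccc1C(=O)O", "morgan2", 512)
  expect_gt(sum(m2$bits), 0)
  expect_error(compute_fingerprint("not_a_molecule(", "daylight", 512),
               "unparseable")
  expect_error(compute_fingerprint("", "daylight", 512), "empty")
})

test_that("label matrix from real structures goes through RDKit", {
  sp <- list(
    toy_spectrum("e1", inchikey = "LFQSCWFLJHTTHZ-UHFFFAOYSA-N", smiles = "CCO"),
    toy_spectrum("e2", inchikey = "LFQSCWFLJHTTHZ-AAAAAAAAAA-N", smiles = "CCO"),
    toy_spectrum("p1", inchikey = "BDERNNFJNOPAEC-UHFFFAOYSA-N", smiles = "CCCO"),
    toy_spectrum("b1", inchikey = "UHOVQNZJYSORNB-UHFFFAOYSA-N",
                 smiles = "c1ccccc1"))
  lm <- build_label_matrix(groups = group_by_compound(sp),
                           fp_type = "daylight", n_bits = 1024)
  expect_identical(dim(lm$scores), c(3L, 3L))
  expect_equal(unname(diag(lm$scores)), rep(1, 3))
  ## ethanol vs propanol are structurally closer than ethanol vs benzene
  expect_gt(lm$scores["LFQSCWFLJHTTHZ", "BDERNNFJNOPAEC"],
            lm$scores["LFQSCWFLJHTTHZ", "UHOVQNZJYSORNB"])
  expect_match(lm$version_tag, "rdkit")
})
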