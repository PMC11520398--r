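test_that("parseSmiles builds the expected graphs for simple molecules", {
  eth <- parseSmiles("CCO")
  expect_equal(nrow(atoms(eth)), 3L)
  expect_equal(nrow(bonds(eth)), 2L)
  expect_true(all(bonds(eth)$order == "single"))
  expect_length(rings(eth), 0L)

  benz <- parseSmiles("c1ccccc1")
  expect_equal(nrow(atoms(benz)), 6L)
  expect_true(all(atoms(benz)$aromatic))
  expect_equal(lengths(rings(benz)), 6L)

  err <- tryCatch(parseSmiles("C(C("), invalidSmilesError = function(e) e)
  expect_s3_class(err, "invalidSmilesError")
  expect_equal(err$smiles, "C(C(")
})

test_that("kekulized aromatic rings are perceived as aromatic", {
  kek <- parseSmiles("C1=CC=CC=C1")
  expect_true(all(atoms(kek)$aromatic))
  expect_identical(canonicalSmiles("C1=CC=CC=C1"),
                   canonicalSmiles("c1ccccc1"))
})

test_that("canonicalization unifies isomorphic writings and is idempotent", {
  expect_identical(canonicalSmiles("OCC"), canonicalSmiles("CCO"))
  can <- canonicalSmiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(canonicalSmiles(can), can)
  expect_error(canonicalSmiles("C(("), class = "invalidSmilesError")
})

test_that("canonicalization is invariant under randomized rewritings", {
  smis <- genMolecules(100L, seed = 17L)
  for (s in smis) {
    mol <- parseSmiles(s)
    can <- canonicalSmiles(mol)
    expect_identical(canonicalSmiles(can), can)
    for (k in 1:2) {
      rw <- randomSmilesRewrite(mol, seed = k)
      expect_true(isValidSmiles(rw))
      expect_identical(canonicalSmiles(rw), can)
      # the rewriting really is a different-but-isomorphic graph writing
      m2 <- parseSmiles(rw)
      g1 <- igraph::graph_from_data_frame(
        bonds(mol)[, c("i", "j")] + 1L, directed = FALSE,
        vertices = data.frame(id = seq_len(nrow(atoms(mol)))))
      g2 <- igraph::graph_from_data_frame(
        bonds(m2)[, c("i", "j")] + 1L, directed = FALSE,
        vertices = data.frame(id = seq_len(nrow(atoms(m2)))))
      expect_true(igraph::isomorphic(
        g1, g2, method = "vf2",
        vertex.color1 = as.integer(factor(
          atoms(mol)$element, levels = sort(unique(c(atoms(mol)$element,
                                                     atoms(m2)$element))))),
        vertex.color2 = as.integer(factor(
          atoms(m2)$element, levels = sort(unique(c(atoms(mol)$element,
                                                    atoms(m2)$element)))))))
    }
  }
})

test_that("fingerprints are deterministic and canonical-invariant", {
  for (scheme in c("path", "maccs", "morgan")) {
    f1 <- molFingerprint("CCO", scheme)
    f2 <- molFingerprint("OCC", scheme)
    expect_identical(f1@bits, f2@bits)
    expect_equal(tanimoto(f1, f2), 1.0)
  }
  # methane and benzene must differ on MACCS keys
  expect_false(setequal(molFingerprint("C", "maccs")@bits,
                        molFingerprint("c1ccccc1", "maccs")@bits))
})

test_that("tanimoto matches set arithmetic and handles edge cases", {
  fp <- function(bits) new("Fingerprint", scheme = "path",
                           bits = as.integer(bits), nBits = 1024L)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(1, 2, 3))), 1.0)
  expect_equal(tanimoto(fp(c(1, 2)), fp(c(3, 4))), 0.0)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 4))), 0.5)
  expect_warning(z <- tanimoto(fp(integer(0)), fp(integer(0))),
                 "empty")
  expect_equal(z, 0.0)
  fm <- molFingerprint("CCO", "morgan")
  expect_error(tanimoto(fp(1:3), fm), "mismatch")
})

test_that("tanimoto is symmetric, bounded and agrees with the bit oracle", {
  set.seed(31)
  nBits <- 256L
  for (i in seq_len(1000L)) {
    a <- sort(sample(0:(nBits - 1L), sample(0:20, 1)))
    b <- sort(sample(0:(nBits - 1L), sample(1:20, 1)))
    fa <- new("Fingerprint", scheme = "path", bits = as.integer(a),
              nBits = nBits)
    fb <- new("Fingerprint", scheme = "path", bits = as.integer(b),
              nBits = nBits)
    s <- suppressWarnings(tanimoto(fa, fb))
    expect_equal(s, oracleTanimoto(a, b, nBits))
    expect_equal(s, suppressWarnings(tanimoto(fb, fa)))
    expect_gte(s, 0); expect_lte(s, 1)
  }
  # self-similarity of real molecules
  smis <- genMolecules(20L, seed = 3L)
  for (s in smis) {
    f <- molFingerprint(s, "morgan")
    if (length(f@bits)) expect_equal(tanimoto(f, f), 1.0)
  }
})

test_that("atomEnvironment reports neighbours, aromaticity and rings", {
  benz <- parseSmiles("c1ccccc1")
  env <- atomEnvironment(benz, 0L)
  expect_equal(nrow(env$neighbors), 2L)
  expect_true(all(env$neighbors$element == "C"))
  expect_true(env$aromatic)
  expect_equal(env$ringSizes, 6L)

  eth <- parseSmiles("CCO")
  env <- atomEnvironment(eth, 2L)
  expect_equal(env$neighbors$element, "C")
  expect_false(env$aromatic)
  expect_length(env$ringSizes, 0L)

  cp <- parseSmiles("C1CC1")
  for (i in 0:2) {
    env <- atomEnvironment(cp, i)
    expect_equal(nrow(env$neighbors), 2L)
    expect_equal(env$ringSizes, 3L)
  }
  expect_error(atomEnvironment(eth, 3L), "out of range")
})

test_that("atomEnvironment agrees with brute-force search on small molecules", {
  smis <- Filter(function(s) nrow(atoms(parseSmiles(s))) <= 8L,
                 genMolecules(60L, seed = 23L))
  expect_gt(length(smis), 5L)
  for (s in smis) {
    mol <- parseSmiles(s)
    b <- bonds(mol)
    for (v in atoms(mol)$index) {
      env <- atomEnvironment(mol, v)
      expect_equal(env$neighbors$index, sort(c(b$j[b$i == v], b$i[b$j == v])))
      oracle <- oracleSmallestCycle(mol, v)
      if (is.na(oracle)) {
        expect_length(env$ringSizes, 0L)
      } else {
        expect_equal(min(env$ringSizes), oracle)
      }
    }
  }
})
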