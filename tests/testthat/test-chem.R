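test_that("canonicalization identifies equivalent notations and is idempotent", {
  expect_identical(canonicalize("C1=CC=CC=C1"), canonicalize("c1ccccc1"))
  s <- canonicalize("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(canonicalize(s), s)
  expect_error(canonicalize("not_a_smiles"), "invalid molecule")
  expect_error(canonicalize(""), "non-empty")
})

test_that("morgan fingerprints are deterministic and distinguish structures", {
  fp <- morgan_fingerprint(c(a = "C1=CC=CC=C1", b = "c1ccccc1", c = "C"))
  expect_identical(fp[["a"]]$bits, fp[["b"]]$bits)
  expect_lt(tanimoto(fp[["a"]], fp[["c"]]), 1)
})

test_that("halving n_bits folds the fingerprint exactly (OR over index mod)", {
  for (smi in c("c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "O=[N+]([O-])c1ccc(Cl)cc1")) {
    f2048 <- morgan_fingerprint(smi, n_bits = 2048)[[1]]
    f1024 <- morgan_fingerprint(smi, n_bits = 1024)[[1]]
    folded <- sort(unique(f2048$bits %% 1024L))
    expect_identical(folded, f1024$bits)
  }
})

test_that("tanimoto matches hand counts and documented conventions", {
  a <- make_fp(c(1, 2, 3)); b <- make_fp(c(2, 3, 4))
  expect_equal(tanimoto(a, b), 0.5)            # |cap|=2, |cup|=4
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(make_fp(1:3), make_fp(4:6)), 0.0)
  expect_equal(tanimoto(make_fp(integer(0)), make_fp(integer(0))), 1.0)
  expect_error(tanimoto(make_fp(1, 64), make_fp(1, 128)), "length")
})

test_that("tanimoto is symmetric and equals 1 iff bit sets are equal", {
  set.seed(1)
  for (k in 1:500) {
    a <- make_fp(sample(0:63, sample(1:20, 1)))
    b <- make_fp(sample(0:63, sample(1:20, 1)))
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    if (setequal(a$bits, b$bits)) expect_equal(tanimoto(a, b), 1.0)
    else expect_lt(tanimoto(a, b), 1.0)
  }
})

test_that("scaffolds keep ring systems and drop side chains", {
  expect_identical(bemis_murcko_scaffold("c1ccccc1"),
                   canonicalize("c1ccccc1"))
  expect_identical(bemis_murcko_scaffold("CCO"), "")
  expect_identical(bemis_murcko_scaffold("Cc1ccccc1"),
                   bemis_murcko_scaffold("c1ccccc1"))
})

test_that("appending alkyl side chains never changes the scaffold", {
  pairs <- list(
    c("c1ccccc1", "CCc1ccccc1"),
    c("c1ccncc1", "Cc1ccncc1"),
    c("c1ccc2ccccc2c1", "CCCc1ccc2ccccc2c1"),
    c("C1CCCCC1", "CC1CCCCC1"),
    c("c1ccsc1", "CCc1ccsc1"),
    c("c1ccoc1", "Cc1ccoc1"),
    c("c1ccc(-c2ccccc2)cc1", "Cc1ccc(-c2ccccc2)cc1"),
    c("C1CCNCC1", "CCC1CCNCC1"),
    c("c1ccc2[nH]ccc2c1", "Cc1ccc2[nH]ccc2c1"),
    c("c1ccc(Cc2ccccc2)cc1", "CCc1ccc(Cc2ccccc2)cc1"))
  for (p in pairs)
    expect_identical(bemis_murcko_scaffold(p[1]), bemis_murcko_scaffold(p[2]))
})

test_that("most_similar agrees with exhaustive search, honors threshold and ties", {
  lib <- generate_molecules(30, 10, seed = 9)
  fps <- morgan_fingerprint(lib$canonical_smiles, ids = lib$id)
  qmols <- generate_molecules(100, 10, seed = 10)
  for (k in seq_len(nrow(qmols))) {
    q <- qmols[k, , drop = FALSE]
    q$id <- paste0("q", k)
    hit <- most_similar(q, lib, threshold = 0.3)
    fq <- morgan_fingerprint(q$canonical_smiles, ids = q$id)[[1]]
    sims <- vapply(fps, function(f) tanimoto(fq, f), 0)
    mx <- max(sims)
    if (mx < 0.3) {
      expect_null(hit)
    } else {
      expect_equal(hit$similarity, mx)
      expect_identical(hit$neighbor_id, sort(lib$id[sims == mx])[1])
    }
  }
})

test_that("most_similar tie-break picks the lexicographically smaller id", {
  lib <- molecule_table(c("zz", "aa"), c("Cc1ccccc1", "Cc1ccccc1"))
  q <- molecule_table("q", "CC1=CC=CC=C1")
  hit <- most_similar(q[1, ], lib, threshold = 0.7)
  expect_identical(hit$neighbor_id, "aa")
  expect_equal(hit$similarity, 1.0)
})

test_that("most_similar handles empty libraries and threshold misses", {
  lib <- molecule_table("a", "c1ccccc1")
  q <- molecule_table("q", "CCCCCCCC")
  expect_null(most_similar(q[1, ], lib[0, ], 0.5))
  expect_null(most_similar(q[1, ], lib, 0.99))
})

test_that("fingerprint hex export encodes exactly the set bits", {
  fps <- morgan_fingerprint(c(a = "c1ccccc1", b = "CCO"), n_bits = 128)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fps, tmp)
  lines <- read.delim(tmp, header = FALSE, stringsAsFactors = FALSE)
  expect_identical(lines[[1]], c("a", "b"))
  for (r in 1:2) {
    nib <- strtoi(strsplit(lines[[2]][r], "")[[1]], base = 16L)
    decoded <- unlist(lapply(seq_along(nib), function(k) {
      on <- c(bitwAnd(nib[k], 8L) > 0, bitwAnd(nib[k], 4L) > 0,
              bitwAnd(nib[k], 2L) > 0, bitwAnd(nib[k], 1L) > 0)
      (4 * (k - 1) + 0:3)[on]
    }))
    expect_identical(sort(as.integer(decoded)), fps[[r]]$bits)
  }
})

test_that("molecule CSV round-trips and drops unparseable rows with a warning", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "a,c1ccccc1", "b,not_a_smiles", "c,CCO"), tmp)
  expect_warning(mols <- read_molecules(tmp), "unparseable")
  expect_identical(mols$id, c("a", "c"))
})
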