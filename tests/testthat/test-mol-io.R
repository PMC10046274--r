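test_that("molecule tables parse from csv and smi, preserving order", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "a,CCO", "b,c1ccccc1", "c,CC(=O)O"), csv)
  tab <- read_molecule_table(csv)
  expect_equal(tab$id, c("a", "b", "c"))
  expect_equal(tab$smiles[1], "CCO")

  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1"), smi)
  tab2 <- read_molecule_table(smi)
  expect_equal(tab2$id, c("mol1", "mol2"))
  expect_equal(tab2$smiles, c("CCO", "c1ccccc1"))
})

test_that("malformed molecule tables are rejected", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "a,CCO", "a,CCN"), dup)
  expect_error(read_molecule_table(dup), class = "molclust_validation_error")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,structure", "a,CCO"), nocol)
  expect_error(read_molecule_table(nocol), class = "molclust_format_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,smiles", empty)
  expect_error(read_molecule_table(empty), class = "molclust_validation_error")
})

test_that("Morgan fingerprints are deterministic, bounded, and skip bad SMILES", {
  mols <- tibble::tibble(id = c("e1", "e2", "bad", "benzene"),
                         smiles = c("CCO", "CCO", "notasmiles", "c1ccccc1"))
  expect_warning(fps <- compute_fingerprints(mols, radius = 2, n_bits = 1024),
                 "skipped 1")
  expect_equal(fps$ids, c("e1", "e2", "benzene"))
  expect_equal(attr(fps, "skipped"), "bad")
  expect_identical(fps$bits[1, ], fps$bits[2, ])   # same SMILES, same row
  n_on <- sum(fps$bits[1, ])
  expect_gte(n_on, 1)
  expect_lte(n_on, 1024)
  expect_equal(fps$radius, 2L)
})

test_that("all-unparseable input is an error", {
  mols <- tibble::tibble(id = "x", smiles = "definitelynotasmiles")
  expect_error(suppressWarnings(compute_fingerprints(mols)),
               class = "molclust_validation_error")
})

test_that("fingerprint TSV round-trips exactly, including degenerate sets", {
  set.seed(42)
  fps <- fingerprint_set(matrix(rbinom(5 * 1024, 1, 0.05), 5, 1024),
                         ids = paste0("mol", 1:5), radius = 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fps, f)
  back <- read_fingerprints(f)
  expect_identical(back$bits, fps$bits)
  expect_identical(back$ids, fps$ids)
  expect_identical(back$radius, fps$radius)

  # planted labels survive the round trip
  fps2 <- fingerprint_set(matrix(c(1L, 0L, 0L, 1L), 2, 2),
                          labels_true = c("1", "outlier"))
  write_fingerprints(fps2, f)
  expect_identical(read_fingerprints(f)$labels_true, c("1", "outlier"))

  # empty set
  empty <- fingerprint_set(matrix(integer(0), 0, 16))
  write_fingerprints(empty, f)
  back_empty <- read_fingerprints(f)
  expect_equal(nrow(back_empty$bits), 0)
  expect_equal(back_empty$n_bits, 16)

  # non-byte-aligned width
  odd <- fingerprint_set(matrix(rbinom(30, 1, 0.5), 3, 10))
  write_fingerprints(odd, f)
  expect_identical(read_fingerprints(f)$bits, odd$bits)
})

test_that("corrupt fingerprint files raise format errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#molclust-fingerprints\tn_bits=16\tradius=2",
               paste0("a\t", strrep("00", 4))), f)  # 32 bits claimed 16? no: 4 bytes
  expect_error(read_fingerprints(f), class = "molclust_format_error")

  writeLines(c("id\tbits", "a\t00"), f)
  expect_error(read_fingerprints(f), class = "molclust_format_error")
})

test_that("fingerprint sets validate their invariants", {
  expect_error(fingerprint_set(matrix(2L, 1, 4)),
               class = "molclust_validation_error")
  expect_error(fingerprint_set(matrix(0L, 2, 4), ids = c("a", "a")),
               class = "molclust_validation_error")
  fps <- fingerprint_set(matrix(0L, 2, 4), ids = c("a", "b"))
  expect_equal(fps[c("b", "a")]$ids, c("b", "a"))
})
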