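test_that("read_fasta parses records, normalises case and strips gaps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 first record", "mtyKLI", "lngk", ">s2", "AAA-AA"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_identical(names(seqs), c("s1", "s2"))
  expect_identical(unname(seqs[1L]), "MTYKLILNGK")
  expect_identical(unname(seqs[2L]), "AAAAA")  # gaps stripped
})

test_that("read_fasta rejects malformed input with an informative error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MTYKLI", ">s1", "AAA"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">s1", "AB1CD"), f)
  expect_error(read_fasta(f), "non-amino-acid")
})

test_that("alignment mode keeps gaps and validates row lengths", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-DE", ">b", "ACWDE"), f)
  aln <- read_fasta(f, alignment = TRUE)
  expect_s3_class(aln, "alignment")
  expect_identical(unname(unclass(aln))[1L], "AC-DE")
  writeLines(c(">a", "ACDE", ">b", "ACWDEF"), f)
  expect_error(read_fasta(f, alignment = TRUE), "unequal")
})

test_that("FASTA writing round-trips records exactly", {
  seqs <- c(one = strrep("ACDEFGHIKLMNPQRSTVWY", 7), two = "MKV")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("the packaged chameleon pair is 56 residues at 98% identity", {
  f <- system.file("extdata", "synthetic_ga_gb98.fasta",
                   package = "switchfold")
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_identical(unname(nchar(seqs)), c(56L, 56L))
  expect_identical(percent_identity(seqs[[1L]], seqs[[2L]]), 98L)
})

test_that("percent identity rounds to integers and handles gaps", {
  a <- strrep("A", 56)
  expect_identical(percent_identity(a, a), 100L)
  b <- paste0(strrep("A", 55), "G")
  expect_identical(percent_identity(a, b), 98L)
  half <- paste0(strrep("G", 28), strrep("A", 28))
  expect_identical(percent_identity(a, half), 50L)
  ## symmetric; gap columns excluded from the denominator
  expect_identical(percent_identity(b, a), 98L)
  expect_identical(percent_identity("AC-D", "ACWD"), 100L)
  expect_error(percent_identity("ACD", "AC"), "equal length")
})

test_that("percent identity is 100 iff compared columns are identical", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    a <- paste(sample(c("A", "C", "G"), n, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G"), n, TRUE), collapse = "")
    pid <- percent_identity(a, b)
    expect_identical(pid, percent_identity(b, a))
    expect_identical(pid == 100L, identical(a, b) ||
                       sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) /
                         n < 0.005)
  }
})

write_toy_pdb <- function(path, models = 1L, end = TRUE, shift = 10) {
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    off <- (m - 1L) * shift
    k <- 0L
    for (r in 1:3) {
      for (at in c("N", "CA", "CB")) {
        k <- k + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          k, at, r, r * 3.8 + off, 0, 0, substr(at, 1, 1)))
      }
    }
    if (models > 1L) lines <- c(lines, "ENDMDL")
  }
  if (end) lines <- c(lines, "END")
  writeLines(lines, path)
}

test_that("read_pdb parses toy files, models and dialect quirks", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f)
  st <- read_pdb(f)
  expect_s3_class(st, "structure3d")
  expect_length(st$resno, 3L)
  expect_identical(st$sequence, c("A", "A", "A"))
  expect_identical(st$resno, 1:3)  # ordering and numbering preserved

  write_toy_pdb(f, models = 2L)
  st2 <- read_pdb(f, model = 2L)
  expect_equal(ca_coords(st2)[1L, 1L], 3.8 + 10, tolerance = 1e-6)
  expect_identical(st2$model, 2L)
  expect_error(read_pdb(f, model = 5L), "model")

  write_toy_pdb(f, end = FALSE)  # no END record
  expect_silent(st3 <- read_pdb(f))
  expect_length(st3$resno, 3L)
})

test_that("read_pdb drops residues without C-alpha and empty files error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  LEU A   3       7.600   0.000   0.000  1.00  0.00           C")
  writeLines(lines, f)
  expect_warning(st <- read_pdb(f), "C-alpha")
  expect_identical(st$resno, c(1L, 3L))
  writeLines("REMARK nothing here", f)
  expect_error(suppressWarnings(read_pdb(f)))
})

test_that("structure PDB round-trip preserves coordinates and sequence", {
  st <- make_structure("hairpin", 12, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, f)
  st2 <- read_pdb(f)
  expect_identical(st2$sequence, st$sequence)
  expect_lt(max(abs(ca_coords(st2) - ca_coords(st))), 1e-2)  # PDB precision
})
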