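test_that("separation bins follow the 1-8, 9-20, then decade rule", {
  expect_identical(bin_of(c(1, 8)), c(1L, 1L))
  expect_identical(bin_of(c(9, 20)), c(2L, 2L))
  expect_identical(bin_of(c(21, 30, 31, 40)), c(3L, 3L, 4L, 4L))
  expect_identical(bin_of(41), 5L)   # decades continue
  expect_identical(bin_of(95), 10L)
  expect_error(bin_of(0), ">= 1")
})

test_that("helix statistics match a brute-force recomputation", {
  helix <- make_structure("helix", 20, sequence = strrep("A", 20))
  tab <- build_table(helix)
  ## brute force over all pairs with k = 1..8
  xyz <- ca_coords(helix)
  d <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    if (j - i <= 8) d <- c(d, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  expect_equal(tab$mean["A", "A", 1], mean(d))
  expect_equal(tab$sd["A", "A", 1], sd(d))
  expect_identical(tab$n["A", "A", 1], length(d))
  ## short-range helix distances average in the expected window
  expect_gt(tab$mean["A", "A", 1], 5.0)
  expect_lt(tab$mean["A", "A", 1], 7.5)
})

test_that("table statistics are idempotent under duplicated structures", {
  s <- make_structure("hairpin", 14, seed = 3)
  one <- build_table(list(s))
  two <- build_table(list(s, s))
  expect_equal(two$mean, one$mean)
  expect_identical(two$n, 2L * one$n)
})

test_that("table is symmetric in the residue-type pair", {
  tab <- build_table(make_reference_set(4, seed = 2))
  for (m in seq_len(tab$max_bin)) {
    expect_identical(tab$mean[, , m], t(tab$mean[, , m]))
    expect_identical(tab$n[, , m], t(tab$n[, , m]))
  }
})

test_that("build_table equals a brute-force two-loop recomputation", {
  structs <- make_reference_set(3, seed = 7)
  tab <- build_table(structs)
  ## independent recomputation for a handful of populated cells
  acc <- list()
  for (s in structs) {
    xyz <- ca_coords(s)
    sq <- s$sequence
    n <- nrow(xyz)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      key <- paste(sort(c(sq[i], sq[j])), collapse = "")
      m <- bin_of(j - i)
      k <- paste(key, m)
      acc[[k]] <- c(acc[[k]], sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    }
  }
  for (k in sample(names(acc), 25)) {
    parts <- strsplit(k, " ")[[1]]
    ab <- strsplit(parts[1], "")[[1]]
    m <- as.integer(parts[2])
    expect_equal(tab$mean[ab[1], ab[2], m], mean(acc[[k]]),
                 tolerance = 1e-10)
    expect_identical(tab$n[ab[1], ab[2], m], length(acc[[k]]))
  }
})

test_that("pooled mean distance grows with the separation bin", {
  tab <- build_table(make_reference_set(6, seed = 1))
  pooled <- sapply(seq_len(tab$max_bin), function(m) {
    w <- tab$n[, , m]
    sum(tab$mean[, , m] * w, na.rm = TRUE) / sum(w)
  })
  expect_gt(pooled[length(pooled)], pooled[1])
  expect_gt(mean(diff(pooled) >= 0), 0.5)  # non-decreasing on average
})

test_that("degenerate inputs give flagged, not fabricated, statistics", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(paste0(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
    "  1.00  0.00           C"), f)
  one_res <- read_pdb(f)
  tab <- build_table(one_res)
  expect_true(all(tab$n == 0L))
  expect_true(all(is.na(tab$mean)))
  expect_error(build_table(list()), "at least one")
  expect_error(fill_missing(tab), "no populated cells")
})

test_that("fill_missing imputes pooled values and floors the spread", {
  tab <- build_table(make_structure("helix", 12, seed = 4))
  filled <- fill_missing(tab)
  expect_false(anyNA(filled$mean))
  expect_true(all(filled$sd >= 0.5))
  ## populated cells keep their own means
  pop <- tab$n > 0L & !is.na(tab$mean)
  expect_equal(filled$mean[pop], tab$mean[pop])
  ## imputed cells keep n = 0 (still flagged)
  expect_true(any(filled$n == 0L))
})

test_that("the TSV interchange format round-trips the table", {
  tab <- fill_missing(build_table(make_reference_set(3, seed = 9)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dist_table(tab, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("A", "B", "M", "mean_A", "sd_A", "n"))
  tab2 <- read_dist_table(f)
  expect_equal(tab2$mean, tab$mean)
  expect_equal(tab2$sd, tab$sd)
  expect_identical(unname(tab2$n), unname(tab$n))
})
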