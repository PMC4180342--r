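test_that("contact frequencies are per-run pools averaged over runs", {
  c1 <- matrix(0L, 4, 4); c1[1, 3] <- c1[3, 1] <- 2L
  c2 <- matrix(0L, 4, 4); c2[1, 3] <- c2[3, 1] <- 1L
  g <- contact_frequency(list(fake_run(c1, 3L), fake_run(c2, 3L)))
  expect_equal(g[1, 3], mean(c(2 / 3, 1 / 3)))
  expect_equal(g[2, 4], 0)
  ## single run, hand-counted: in contact 2 of 3 conformations
  g1 <- contact_frequency(fake_run(c1, 3L))
  expect_equal(g1[1, 3], 2 / 3)
  expect_error(contact_frequency(fake_run(c1, 0L)), "zero sampled")
})

test_that("rigid-geometry limits give g = 1 and g = 0", {
  ## a chain that never moves: contact iff within 10 A
  xyz <- cbind(c(0, 3.8, 7.6, 11.4), 0, 0)
  fp <- flat_potential(4)
  p <- coil_params(r_cut = 0, eps_hc = 0, gamma = 1e-9)
  set.seed(2)
  res <- coil_sweeps(xyz, fp$rbar, fp$sigma, p, n_sweeps = 20,
                     record_contacts = TRUE)
  g <- contact_frequency(fake_run(res$counts, res$n_samples))
  expect_equal(g[1, 3], 1)   # 7.6 A apart
  expect_equal(g[1, 4], 0)   # 11.4 A apart
})

test_that("uniform contact frequencies give an identically zero profile", {
  n <- 30
  g <- matrix(0.4, n, n)
  fp <- f_profile(g)
  expect_true(all(fp$F == 0))
  expect_false(any(fp$is_peak))
})

test_that("an engineered above-baseline pair peaks exactly there", {
  n <- 50
  g <- matrix(0, n, n)
  for (m in 1:(n - 1)) {
    idx <- cbind(1:(n - m), (1:(n - m)) + m)
    g[idx] <- 0.2; g[idx[, 2:1]] <- 0.2
  }
  g[10, 40] <- g[40, 10] <- 0.5
  fp <- f_profile(g)
  expect_identical(fp$residue[fp$is_peak], c(10L, 40L))
  expect_equal(fp$F[10], fp$F[40])
})

test_that("f_profile equals the brute-force double loop", {
  set.seed(14)
  n <- 18
  g <- matrix(runif(n * n), n, n)
  g <- (g + t(g)) / 2
  expect_equal(f_profile(g)$F, brute_f(g), tolerance = 1e-12)
  expect_error(f_profile(matrix(0.1, 2, 2)), "at least 3")
})

test_that("F is invariant under run relabeling and improves with runs", {
  set.seed(8)
  n <- 12
  truth <- matrix(runif(n * n, 0, 0.5), n, n)
  truth <- (truth + t(truth)) / 2
  make_runs <- function(k, samples = 40L) {
    lapply(seq_len(k), function(r) {
      cts <- matrix(rbinom(n * n, samples, truth), n, n)
      cts[lower.tri(cts)] <- t(cts)[lower.tri(cts)]
      fake_run(cts, samples)
    })
  }
  runs <- make_runs(6)
  f_fwd <- f_profile(contact_frequency(runs))$F
  f_rev <- f_profile(contact_frequency(rev(runs)))$F
  expect_equal(f_fwd, f_rev)
  ## averaging more runs tracks the true profile more closely
  f_true <- switchfold:::f_from_g(truth)
  err <- function(k) {
    mean(abs(f_profile(contact_frequency(make_runs(k)))$F - f_true))
  }
  expect_lt(mean(replicate(5, err(20))), mean(replicate(5, err(5))))
})

test_that("short-range attraction between one residue type drives peaks", {
  ## synthetic table with a deep short-range well for F-F pairs:
  ## F positions should dominate the F profile
  tab <- ref_table()
  idx <- match("F", switchfold:::AA20)
  tab$mean[idx, idx, 1:2] <- 5
  tab$sd[idx, idx, 1:2] <- 0.5
  seqq <- "AGKESAGFFKAGESAGKESA"   # F at 8, 9
  p <- coil_params(gamma = 0.03)
  runs <- run_ensemble(seqq, tab, params = p, n_runs = 3, n_sweeps = 800,
                       seeds = 31:33)
  fp <- f_profile(contact_frequency(runs))
  top <- order(-fp$F)[1:4]
  expect_true(any(abs(top - 8) <= 2) || any(abs(top - 9) <= 2))
})

test_that("peak finding honours prominence, plateaus and shoulders", {
  x <- c(0, 1, 0, 5, 5, 5, 0, 2, 0, 0)
  pk <- find_peaks(x, min_prominence = 3)
  expect_identical(pk$peaks, 5L)          # plateau centre
  pk2 <- find_peaks(x, min_prominence = 0.5)
  expect_true(8L %in% pk2$peaks)          # passes the lower bar
  expect_false(2L %in% pk$peaks)          # below the profile mean
})

test_that("packing pairs apply the 5 A heavy-atom rule at the boundary", {
  atoms <- function(resno, resid, x) {
    data.frame(resno = resno, resid = resid,
               elety = c("CA", "CB"), element = "C",
               x = c(x, x), y = c(0, 4), z = 0)
  }
  ## residues 1 and 5 engineered so closest heavy atoms sit at 4.9 A
  at <- rbind(atoms(1, "LEU", 0), atoms(2, "GLY", 3.8),
              atoms(3, "GLY", 7.6), atoms(4, "GLY", 11.4),
              atoms(5, "ILE", -4.9), atoms(6, "SER", 30))
  st <- toy_structure(at)
  rep <- packing_pairs(st)
  expect_identical(nrow(rep), 1L)
  expect_identical(c(rep$i, rep$j), c(1L, 5L))
  expect_equal(rep$min_dist, 4.9)
  expect_true(rep$both_hydrophobic)
  ## nudge beyond the cutoff: excluded
  at2 <- at; at2$x[at2$resno == 5] <- -5.1
  expect_identical(nrow(packing_pairs(toy_structure(at2))), 0L)
})

test_that("C-alpha-only structures fall back to a 6.5 A cutoff", {
  at <- data.frame(resno = 1:6, resid = "ALA", elety = "CA", element = "C",
                   x = c(0, 3.8, 7.6, 11.4, 15.2, 6), y = c(0, 0, 0, 0, 0, 3),
                   z = 0)
  st <- toy_structure(at)
  expect_warning(rep <- packing_pairs(st), "6.5")
  expect_true(all(rep$min_dist <= 6.5))
})

test_that("peak/packing correspondence reports windows both ways", {
  fp <- data.frame(residue = 1:20, F = 0, sd = NA, is_peak = FALSE,
                   is_shoulder = FALSE)
  fp$is_peak[c(5, 15)] <- TRUE
  rep <- data.frame(i = c(4L, 11L), j = c(16L, 18L),
                    min_dist = c(4, 4.5), both_hydrophobic = TRUE)
  corr <- peak_packing_correspondence(fp, rep, window = 3)
  by_res <- corr$by_residue
  expect_true(by_res$within_window[by_res$residue == 4])   # near peak 5
  expect_false(by_res$within_window[by_res$residue == 11]) # 4 from peak 15
  expect_identical(corr$by_peak$n_packing_within,
                   c(1L, 2L))  # 4 near peak 5; 16 and 18 near peak 15
})
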