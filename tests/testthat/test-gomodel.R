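test_that("topology extraction equals a brute-force atom scan", {
  hp <- make_structure("hairpin", 16, seed = 2)
  topo <- extract_topology(hp)
  ## independent all-pairs heavy-atom scan
  expected <- list()
  for (i in 1:13) for (j in (i + 3):16) {
    ai <- hp$atoms[hp$atoms$resno == i, c("x", "y", "z")]
    aj <- hp$atoms[hp$atoms$resno == j, c("x", "y", "z")]
    np <- 0L
    for (a in seq_len(nrow(ai))) for (b in seq_len(nrow(aj))) {
      if (sqrt(sum((ai[a, ] - aj[b, ])^2)) < 4) np <- np + 1L
    }
    if (np > 0L) expected[[paste(i, j)]] <- np
  }
  got <- setNames(topo$contacts$n_atom_pairs,
                  paste(topo$contacts$i, topo$contacts$j))
  expect_identical(got, unlist(expected))
  expect_true(all(abs(topo$contacts$j - topo$contacts$i) >= 3))
})

test_that("scaled contact numbers average to one by construction", {
  topo <- toy_hairpin_topology()
  expect_equal(mean(topo$contacts$Cij), 1)
  bn <- extract_topology(make_structure("bundle3", 30, seed = 4))
  expect_equal(mean(bn$contacts$Cij), 1)
  ## equal atom-pair counts give C = 1 for every contact
  at <- data.frame(resno = rep(1:6, each = 1), resid = "ALA", elety = "CA",
                   element = "C",
                   x = c(0, 3.8, 7.6, 11.4, 15.2, 19), y = 0, z = 0)
  st <- toy_structure(at)
  expect_warning(t2 <- extract_topology(st), "C-alpha")
  if (nrow(t2$contacts)) expect_true(all(t2$contacts$Cij == 1))
})

test_that("structures without long-range contacts yield empty topologies", {
  helix <- make_structure("helix", 8, seed = 1)
  topo <- suppressWarnings(extract_topology(helix, cutoff = 0.5))
  expect_identical(nrow(topo$contacts), 0L)
  expect_error(q_value(topo$xyz, topo), "no native contacts")
  expect_error(fold_simulation(topo), "no native contacts")
})

test_that("orientation factor hits its limits and matches the backend", {
  topo <- toy_hairpin_topology()
  xyz <- topo$xyz
  interior <- topo$contacts[!is.na(topo$contacts$Theta0), ]
  c1 <- interior[1, ]
  ## native orientation: B = 1
  expect_equal(orientation_factor(xyz, c1$i, c1$j, c1$Theta0), 1)
  ## deviation at or beyond a_theta: B = 0
  expect_equal(orientation_factor(xyz, c1$i, c1$j,
                                  c1$Theta0 + 0.6 * pi + 0.1), 0)
  ## terminal residues always give B = 1
  expect_equal(orientation_factor(xyz, 1, 10, 0.3), 1)
  ## R reference and C++ backend agree on random conformations
  set.seed(13)
  for (rep in 1:10) {
    x <- random_chain(16)
    for (c in seq_len(min(5, nrow(interior)))) {
      expect_equal(
        orientation_factor(x, interior$i[c], interior$j[c],
                           interior$Theta0[c]),
        bfactor_cpp(x, interior$i[c], interior$j[c], interior$Theta0[c],
                    0.6 * pi),
        tolerance = 1e-12)
    }
  }
})

test_that("go_energy matches the brute-force oracle on random states", {
  topo <- toy_hairpin_topology()
  p <- go_params()
  set.seed(17)
  for (rep in 1:8) {
    ic <- internal_coords(topo$xyz)
    th <- pmin(pi - 1e-3, pmax(1e-3, ic$theta + rnorm(14, 0, 0.2)))
    ph <- ic$phi + rnorm(13, 0, 0.3)
    x <- chain_from_internal(th, ph)
    expect_equal(go_energy(x, topo, p), brute_go_energy(x, topo, p),
                 tolerance = 1e-8)
  }
})

test_that("the native state sits at the bottom of the contact well", {
  topo <- toy_hairpin_topology()
  p <- go_params()
  e_native <- go_energy(topo$xyz, topo, p)
  ## angle and dihedral terms vanish and every contact contributes
  ## -eps * C_ij * B; B = 1 at the native orientation
  expect_equal(e_native, -p$eps * sum(topo$contacts$Cij), tolerance = 0.05)
  ## single native pair at r = r0, C = 1, native orientation: exactly -eps
  ct <- topo$contacts
  one <- topo
  keep <- which(ct$i == 2 & !is.na(ct$Theta0))[1]
  one$contacts <- ct[keep, ]
  one$contacts$Cij <- 1
  e_all <- go_energy(topo$xyz, one, go_params(rep_eps = 0))
  expect_equal(e_all, -1, tolerance = 1e-9)
})

test_that("Q counts formed native contacts", {
  topo <- toy_hairpin_topology()
  expect_equal(q_value(topo$xyz, topo), 1)
  expect_equal(q_value(extended_chain(16), topo), 0)
  ## constructed state with exactly half the contacts formed
  fake <- list(contacts = data.frame(i = c(1, 1, 2, 2), j = c(4, 5, 5, 6),
                                     r0 = c(5, 5, 100, 100)))
  xyz <- cbind(seq(0, by = 3.8, length.out = 6), 0, 0)
  expect_equal(q_value(xyz, fake), 0.5)
})

test_that("folding simulations are deterministic and keep honest books", {
  topo <- toy_hairpin_topology()
  p <- go_params(temperature = 0.5)
  t1 <- fold_simulation(topo, p, n_sweeps = 500, seed = 3, stride = 10)
  t2 <- fold_simulation(topo, p, n_sweeps = 500, seed = 3, stride = 10)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$flags, t2$flags)
  expect_equal(t1$energy, t1$energy_full, tolerance = 1e-6)
  expect_true(all(t1$samples$Q >= 0 & t1$samples$Q <= 1))
})

test_that("constructed two-basin Q series locates the known barrier", {
  ## deterministic histogram: two deep basins joined by a bridge whose
  ## occupancy dips at Q = 0.5 -- the known barrier
  mids <- seq(0.10, 0.85, by = 0.05)
  counts <- c(900, 700, 400, 200, 120, 60, 30, 15, 8, 15, 30, 60, 120, 400,
              700, 900)
  q <- rep(mids, times = counts)
  nc <- 10L
  set.seed(30)
  flags <- matrix(rep(q, nc) > runif(length(q) * nc), ncol = nc)
  traj <- structure(list(samples = data.frame(sweep = seq_along(q), E = 0,
                                              Q = q),
                         flags = flags,
                         contacts = data.frame(i = 1:nc, j = 21:30)),
                    class = "go_trajectory")
  ts <- transition_state_map(traj, bin_width = 0.05)
  expect_equal(ts$q_star, 0.5, tolerance = 0.06)  # barrier bin centre
  expect_identical(nrow(ts$map), nc)
  expect_true(all(grepl("^[0-9]+-[0-9]+$", ts$map$band)))
})

test_that("an all-folded trajectory has no barrier to report", {
  q <- rep(1, 500)
  traj <- structure(list(samples = data.frame(sweep = 1:500, E = 0, Q = q),
                         flags = matrix(TRUE, 500, 3),
                         contacts = data.frame(i = 1:3, j = 7:9)),
                    class = "go_trajectory")
  expect_error(transition_state_map(traj), "no barrier")
})

test_that("TSV writers emit the documented columns", {
  topo <- toy_hairpin_topology()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_topology(topo, f)
  expect_identical(strsplit(readLines(f, n = 1), "\t")[[1]],
                   c("i", "j", "r0", "contact_number", "Cij", "Theta0"))
  tr <- fold_simulation(topo, go_params(temperature = 0.4), n_sweeps = 100,
                        seed = 1, stride = 10)
  write_trajectory(tr, f)
  expect_identical(strsplit(readLines(f, n = 1), "\t")[[1]],
                   c("sweep", "E", "Q"))
})
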