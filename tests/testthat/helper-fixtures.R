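## Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

## completed average-distance table from the synthetic reference set
ref_table <- function() {
  if (is.null(.fixture_env$tab)) {
    .fixture_env$tab <- fill_missing(build_table(make_reference_set(6, seed = 1)))
  }
  .fixture_env$tab
}

toy_hairpin_topology <- function() {
  if (is.null(.fixture_env$topo)) {
    .fixture_env$topo <- extract_topology(make_structure("hairpin", 16, seed = 2))
  }
  .fixture_env$topo
}

## flat (null) potential matrices for an n-bead chain
flat_potential <- function(n) {
  list(rbar = matrix(5, n, n), sigma = matrix(1e6, n, n))
}

## a minimal structure3d straight from an atom table
toy_structure <- function(atoms) {
  switchfold:::structure_from_atoms(atoms, chain = "A", model = 1L,
                                    source = "synthetic:toy")
}

## fabricate a sim_run for contact_frequency tests
fake_run <- function(counts, n_samples) {
  structure(list(counts = counts, n_samples = n_samples, acceptance = 0.5,
                 seed = 0L, n = nrow(counts)), class = "sim_run")
}

## brute-force F profile: independent double-loop oracle
brute_f <- function(g) {
  n <- nrow(g)
  d_of_m <- sapply(1:(n - 1), function(m) {
    v <- c()
    for (i in 1:n) for (j in 1:n) {
      if (abs(i - j) == m && i < j) v <- c(v, g[i, j])
    }
    mean(v)
  })
  f <- numeric(n)
  for (u in 1:n) {
    s <- 0
    for (v in 1:n) {
      if (v == u) next
      s <- s + max(0, g[u, v] - d_of_m[abs(u - v)])
    }
    f[u] <- s / (n - 1)
  }
  f
}

## brute-force Go energy oracle in plain R
brute_go_energy <- function(xyz, topo, params) {
  n <- nrow(xyz)
  ic <- internal_coords(xyz)
  E <- sum(params$K_theta * (ic$theta - topo$theta0[2:(n - 1)])^2)
  dphi <- ic$phi - topo$phi0[2:(n - 2)]
  E <- E + sum(params$K_phi1 * (1 - cos(dphi)) +
                 params$K_phi3 * (1 - cos(3 * dphi)))
  ct <- topo$contacts
  for (c in seq_len(nrow(ct))) {
    i <- ct$i[c]; j <- ct$j[c]
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    x <- ct$r0[c] / r
    u <- 5 * x^12 - 6 * x^10
    B <- orientation_factor(xyz, i, j, ct$Theta0[c], params$a_theta)
    E <- E + params$eps * ct$Cij[c] * B * u
  }
  nat <- matrix(FALSE, n, n)
  nat[cbind(ct$i, ct$j)] <- TRUE
  nat[cbind(ct$j, ct$i)] <- TRUE
  for (i in 1:(n - 3)) for (j in (i + 3):n) {
    if (nat[i, j]) next
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    if (r2 < 9 * params$rep_sigma^2) {
      E <- E + params$rep_eps * (params$rep_sigma^2 / r2)^6
    }
  }
  E
}
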