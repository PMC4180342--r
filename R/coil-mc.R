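## Metropolis Monte Carlo sampling of random C-alpha chains under the
## average-distance potential. The chain is a bead model with fixed 3.8 A
## virtual bonds; moves perturb one residue's bond angle theta and
## dihedral phi (each within -gamma*pi .. gamma*pi, each with its own
## Metropolis judgment) and pivot the downstream segment rigidly.

BOND_LENGTH <- 3.8

#' Coil-potential parameters
#'
#' Parameters of the average-distance potential and its sampler. For a
#' residue pair at separation `k` and distance `r`, the pair energy is the
#' hard-core constant `eps_hc` when the distance is below `r_cut`, else the
#' Gaussian-well log-likelihood `kT * (r - rbar)^2 / (2 * sigma^2)` with
#' `rbar`, `sigma` taken from the statistics table at bin `bin_of(k)`
#' (constant terms set the zero point). Only the ratio `eps_hc / kT`
#' affects Metropolis sampling; the quadratic term's `kT` cancels.
#'
#' @param r_cut Hard-core radius in angstrom (default 1.9).
#' @param eps_hc Hard-core energy in kcal/mol (default 50).
#' @param kT Thermal energy in kcal/mol.
#' @param gamma Move amplitude as a fraction of pi, in (0, 1].
#' @return List of class `"coil_params"`.
#' @export
coil_params <- function(r_cut = 1.9, eps_hc = 50, kT = 0.6, gamma = 0.15) {
  stopifnot(r_cut >= 0, eps_hc >= 0, kT > 0, gamma > 0, gamma <= 1)
  out <- list(r_cut = r_cut, eps_hc = eps_hc, kT = kT, gamma = gamma)
  class(out) <- "coil_params"
  out
}

#' Pair energy under the average-distance potential
#'
#' @param a,b One-letter residue types.
#' @param k Sequence separation (`>= 1`).
#' @param r Distance in angstrom (`> 0`).
#' @param table A completed `"avg_dist_table"`.
#' @param params A `"coil_params"` object.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' tab <- build_table(make_structure("helix", 30, seed = 1))
#' tab <- fill_missing(tab)
#' pair_energy("A", "A", 3, 1.0, tab, coil_params())  # hard core: 50
pair_energy <- function(a, b, k, r, table, params = coil_params()) {
  stopifnot(k >= 1, r > 0)
  if (r < params$r_cut) return(params$eps_hc)
  cell <- table_lookup(table, a, b, k)
  params$kT * (r - cell$mean)^2 / (2 * cell$sd^2)
}

## ---- internal-coordinate chain construction ----

#' Build a chain from internal coordinates
#'
#' Places `length(theta) + 2` beads with exact `bond`-length virtual
#' bonds, bond angles `theta[i]` at interior beads and dihedrals `phi[i]`
#' about interior bonds (standard NeRF placement).
#'
#' @param theta Bond angles in (0, pi); one per interior bead (N - 2).
#' @param phi Dihedrals in (-pi, pi]; length N - 3.
#' @param bond Bond length in angstrom.
#' @return N x 3 coordinate matrix.
#' @export
chain_from_internal <- function(theta, phi, bond = BOND_LENGTH) {
  n <- length(theta) + 2L
  stopifnot(length(phi) == n - 3L, all(theta > 0 & theta < pi))
  x <- matrix(0, n, 3L)
  x[2L, ] <- c(bond, 0, 0)
  ## third bead in the xy-plane at angle theta[1]
  x[3L, ] <- x[2L, ] + bond * c(-cos(theta[1L]), sin(theta[1L]), 0)
  if (n >= 4L) {
    for (kk in 3L:(n - 1L)) {
      A <- x[kk - 2L, ]; B <- x[kk - 1L, ]; C <- x[kk, ]
      th <- theta[kk - 1L]; ph <- phi[kk - 2L]
      u <- C - B; u <- u / sqrt(sum(u^2))
      nv <- c((B - A)[2L] * u[3L] - (B - A)[3L] * u[2L],
              (B - A)[3L] * u[1L] - (B - A)[1L] * u[3L],
              (B - A)[1L] * u[2L] - (B - A)[2L] * u[1L])
      nv <- nv / sqrt(sum(nv^2))
      mv <- c(nv[2L] * u[3L] - nv[3L] * u[2L],
              nv[3L] * u[1L] - nv[1L] * u[3L],
              nv[1L] * u[2L] - nv[2L] * u[1L])
      x[kk + 1L, ] <- C + bond * (-u * cos(th) + mv * sin(th) * cos(ph) +
                                    nv * sin(th) * sin(ph))
    }
  }
  x
}

#' Internal coordinates of a chain
#'
#' @param xyz N x 3 coordinate matrix.
#' @return List with `theta` (bond angles at beads 2..N-1) and `phi`
#'   (dihedrals at beads 2..N-2), plus `bonds` (consecutive distances).
#' @export
internal_coords <- function(xyz) {
  n <- nrow(xyz)
  stopifnot(n >= 3L)
  theta <- vapply(2L:(n - 1L), function(i) {
    u <- xyz[i - 1L, ] - xyz[i, ]; v <- xyz[i + 1L, ] - xyz[i, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }, numeric(1L))
  phi <- if (n >= 4L) {
    vapply(2L:(n - 2L), function(i) {
      dihedral_r(xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ])
    }, numeric(1L))
  } else numeric(0L)
  bonds <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                           xyz[-n, , drop = FALSE])^2))
  list(theta = theta, phi = phi, bonds = bonds)
}

## signed dihedral of four points, (-pi, pi]
dihedral_r <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  n2 <- c(b2[2L] * b3[3L] - b2[3L] * b3[2L],
          b2[3L] * b3[1L] - b2[1L] * b3[3L],
          b2[1L] * b3[2L] - b2[2L] * b3[1L])
  atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2))
}

#' Random chain conformation
#'
#' Draws bond angles and dihedrals uniformly from their full domains
#' (theta in (0, pi), phi in (-pi, pi]) — the "totally randomized"
#' starting conformation of a simulation run.
#'
#' @param n Number of beads.
#' @param bond Bond length in angstrom.
#' @return N x 3 coordinate matrix.
#' @export
random_chain <- function(n, bond = BOND_LENGTH) {
  chain_from_internal(runif(n - 2L, 1e-3, pi - 1e-3),
                      runif(n - 3L, -pi, pi), bond = bond)
}

## ---- sampling ----

#' Run Monte Carlo sweeps on a chain
#'
#' Low-level sampler: each sweep visits residues sequentially, perturbing
#' theta then phi with separate Metropolis judgments. With
#' `record_contacts = TRUE`, contact events (C-alpha distance below
#' `contact_cut`) are counted every sweep after `burn_in`, for residues
#' outside the `pad`-residue terminal padding.
#'
#' @param xyz Starting N x 3 coordinates (exact 3.8 A bonds).
#' @param rbar,sigma N x N per-pair mean/spread matrices (from the
#'   internal table expansion); pass flat matrices for a null potential.
#' @param params A `"coil_params"`.
#' @param n_sweeps Number of sweeps.
#' @param burn_in Sweeps discarded before contact recording.
#' @param contact_cut Contact distance in angstrom (default 10).
#' @param pad Terminal residues excluded from recording.
#' @param record_contacts,record_angles Recording switches.
#' @return List: final `xyz`, `acceptance`, contact `counts` (core
#'   residues only), `n_samples`, incremental `energy` and a from-scratch
#'   `energy_full`, plus per-sweep `theta_trace`/`phi_trace` when
#'   requested.
#' @export
coil_sweeps <- function(xyz, rbar, sigma, params = coil_params(),
                        n_sweeps = 1L, burn_in = 0L, contact_cut = 10,
                        pad = 0L, record_contacts = FALSE,
                        record_angles = FALSE) {
  n <- nrow(xyz)
  stopifnot(nrow(rbar) == n, nrow(sigma) == n)
  coil_mc_cpp(xyz, rbar, sigma, params$r_cut, params$eps_hc, params$kT,
              params$gamma, as.integer(n_sweeps), as.integer(burn_in),
              contact_cut, as.integer(pad), record_contacts, record_angles)
}

#' Tune the move amplitude (and temperature) for ~0.5 acceptance
#'
#' Adjusts `gamma`, then `kT` if `gamma` alone cannot get there, until a
#' probe run's Metropolis acceptance ratio falls in \[0.4, 0.6\]. If the
#' bounded search fails, the closest parameters found are returned with a
#' warning.
#'
#' @param sequence One-letter sequence the probe runs on.
#' @param table Completed `"avg_dist_table"`.
#' @param params Starting `"coil_params"`.
#' @param probe_sweeps Probe run length (>= 100).
#' @param pad Gly padding applied to each terminus for the probe.
#' @return Tuned `"coil_params"` with attribute `"acceptance"`.
#' @export
autotune <- function(sequence, table, params = coil_params(),
                     probe_sweeps = 200L, pad = 10L) {
  stopifnot(probe_sweeps >= 100L)
  padded <- paste0(strrep("G", pad), sequence, strrep("G", pad))
  pp <- pair_param_matrices(table, padded)
  n <- nchar(padded)
  probe <- function(p) {
    coil_sweeps(random_chain(n), pp$rbar, pp$sigma, p,
                n_sweeps = probe_sweeps)$acceptance
  }
  best <- params; best_acc <- probe(params)
  for (iter in seq_len(20L)) {
    if (best_acc >= 0.4 && best_acc <= 0.6) break
    if (best_acc < 0.4) {
      ## too many rejections: smaller moves, then warmer (the quadratic
      ## term scales with kT, so temperature only softens the hard core)
      if (best$gamma > 0.0011) {
        best$gamma <- max(0.001, best$gamma / 1.6)
      } else {
        best$kT <- best$kT * 1.6
      }
    } else {
      if (best$gamma < 0.99) {
        best$gamma <- min(1, best$gamma * 1.5)
      } else {
        best$kT <- best$kT / 1.5
      }
    }
    best_acc <- probe(best)
  }
  if (best_acc < 0.4 || best_acc > 0.6) {
    warning("autotune could not reach acceptance in [0.4, 0.6]; ",
            "closest achieved ", round(best_acc, 3))
  }
  attr(best, "acceptance") <- best_acc
  best
}

#' Run an ensemble of coil simulations for a sequence
#'
#' Pads the sequence with `pad` Gly residues at each terminus, starts each
#' run from a fresh random conformation, relaxes it, and records contact
#' events every sweep after a burn-in. Runs are independent given their
#' seeds; the same seed reproduces a run's contact record bit for bit.
#' Padding residues participate in the energy but are excluded from all
#' recorded contacts, so reported indices are 1..nchar(sequence).
#'
#' @param sequence One-letter amino acid sequence.
#' @param table Completed `"avg_dist_table"`.
#' @param params `"coil_params"`; autotuned from the sequence when `NULL`.
#' @param n_runs Number of independent runs (default 10).
#' @param n_sweeps Sweeps per run (default 60000).
#' @param seeds Integer seeds, one per run.
#' @param pad Gly padding per terminus (default 10).
#' @param contact_cut Contact distance in angstrom (default 10).
#' @param burn_frac Fraction of sweeps discarded as burn-in (default 0.1).
#' @param relax_sweeps Un-recorded relaxation sweeps after the random
#'   start (default 100).
#' @return List of class `"sim_ensemble"`; each element is a `"sim_run"`
#'   with `counts`, `n_samples`, `acceptance`, `seed` and `n`.
#' @export
run_ensemble <- function(sequence, table, params = NULL, n_runs = 10L,
                         n_sweeps = 60000L, seeds = NULL, pad = 10L,
                         contact_cut = 10, burn_frac = 0.1,
                         relax_sweeps = 100L) {
  sequence <- toupper(sequence)
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  if (is.null(params)) {
    set.seed(seeds[1L])
    params <- autotune(sequence, table, probe_sweeps = 200L, pad = pad)
  }
  padded <- paste0(strrep("G", pad), sequence, strrep("G", pad))
  pp <- pair_param_matrices(table, padded)
  n <- nchar(padded)
  burn <- as.integer(ceiling(burn_frac * n_sweeps))
  runs <- lapply(seq_len(n_runs), function(r) {
    set.seed(seeds[r])
    start <- random_chain(n)
    relaxed <- coil_sweeps(start, pp$rbar, pp$sigma, params,
                           n_sweeps = relax_sweeps)$xyz
    res <- coil_sweeps(relaxed, pp$rbar, pp$sigma, params,
                       n_sweeps = n_sweeps, burn_in = burn,
                       contact_cut = contact_cut, pad = pad,
                       record_contacts = TRUE)
    out <- list(counts = res$counts, n_samples = res$n_samples,
                acceptance = res$acceptance, seed = seeds[r],
                n = nchar(sequence))
    class(out) <- "sim_run"
    out
  })
  attr(runs, "params") <- params
  attr(runs, "sequence") <- sequence
  class(runs) <- "sim_ensemble"
  runs
}

#' @export
print.sim_ensemble <- function(x, ...) {
  acc <- vapply(x, `[[`, numeric(1L), "acceptance")
  cat("coil MC ensemble: ", length(x), " run(s), ", x[[1L]]$n,
      " residues, mean acceptance ", round(mean(acc), 3), "\n", sep = "")
  invisible(x)
}
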