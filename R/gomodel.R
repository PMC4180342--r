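## Orientation-dependent C-alpha Go model. Native topology is extracted
## from a heavy-atom structure (contact = any heavy-atom pair within 4 A,
## |i - j| >= 3); each contact carries a scaled contact number C_ij
## (atom-pair count divided by the ensemble mean, so mean C = 1) and a
## native orientation Theta0 of the two residues' h-vectors. The energy
## couples bond-angle and dihedral restraints with a 12-10 native well
## modulated by C_ij and the orientation factor B_ij, plus a repulsive
## wall for non-native pairs.

#' Extract the native topology of a structure
#'
#' @param structure A `"structure3d"` with heavy atoms; for C-alpha-only
#'   input a C-alpha distance cutoff of 6.5 angstrom is used with a
#'   warning (contact number 1 for every contact).
#' @param cutoff Heavy-atom contact cutoff in angstrom (default 4).
#' @param min_sep Minimum sequence separation for a contact (default 3).
#' @return Object of class `"native_topology"`: list with `contacts`
#'   (data frame `i`, `j`, `r0`, `n_atom_pairs`, `Cij`, `Theta0`),
#'   `theta0`, `phi0` (native internal coordinates, padded with `NA` at
#'   chain ends), `xyz` (native C-alpha coordinates) and `n`.
#' @export
extract_topology <- function(structure, cutoff = 4, min_sep = 3L) {
  stopifnot(inherits(structure, "structure3d"))
  xyz <- ca_coords(structure)
  n <- nrow(xyz)
  ca_only <- all(structure$atoms$elety == "CA")
  if (ca_only) {
    warning("C-alpha-only structure: contacts from a 6.5 A C-alpha cutoff")
  }
  rows <- list()
  coords <- if (!ca_only) {
    lapply(structure$resno, function(r) {
      as.matrix(structure$atoms[structure$atoms$resno == r,
                                c("x", "y", "z"), drop = FALSE])
    })
  }
  for (i in seq_len(n - 1L)) {
    jmax <- n
    jmin <- i + min_sep
    if (jmin > jmax) next
    for (j in jmin:jmax) {
      if (ca_only) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d <= 6.5) {
          rows[[length(rows) + 1L]] <- data.frame(i = i, j = j,
                                                  n_atom_pairs = 1L)
        }
      } else {
        np <- sum(cross_dist(coords[[i]], coords[[j]]) < cutoff)
        if (np > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(i = i, j = j,
                                                  n_atom_pairs = np)
        }
      }
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), n_atom_pairs = integer(0))
  if (nrow(contacts)) {
    contacts$r0 <- sqrt(rowSums((xyz[contacts$i, , drop = FALSE] -
                                   xyz[contacts$j, , drop = FALSE])^2))
    contacts$Cij <- contacts$n_atom_pairs / mean(contacts$n_atom_pairs)
    contacts$Theta0 <- vapply(seq_len(nrow(contacts)), function(c) {
      hv_angle(xyz, contacts$i[c], contacts$j[c])
    }, numeric(1L))
    contacts <- contacts[, c("i", "j", "r0", "n_atom_pairs", "Cij", "Theta0")]
  }
  ic <- internal_coords(xyz)
  topo <- list(contacts = contacts,
               theta0 = c(NA, ic$theta, NA),
               phi0 = c(NA, ic$phi, NA, NA),
               xyz = xyz, n = n, model = structure$model)
  class(topo) <- "native_topology"
  topo
}

## angle between h-vectors of residues i and j (NA for terminal residues)
hv_angle <- function(xyz, i, j) {
  n <- nrow(xyz)
  if (i == 1L || i == n || j == 1L || j == n) return(NA_real_)
  hi <- (xyz[i - 1L, ] - xyz[i, ]) + (xyz[i + 1L, ] - xyz[i, ])
  hj <- (xyz[j - 1L, ] - xyz[j, ]) + (xyz[j + 1L, ] - xyz[j, ])
  ni <- sqrt(sum(hi^2)); nj <- sqrt(sum(hj^2))
  if (ni < 1e-10 || nj < 1e-10) return(NA_real_)
  acos(max(-1, min(1, sum(hi * hj) / (ni * nj))))
}

#' @export
print.native_topology <- function(x, ...) {
  cat("native topology: ", x$n, " residues, ", nrow(x$contacts),
      " native contact(s)", sep = "")
  if (nrow(x$contacts)) {
    cat(", mean C_ij = ", format(mean(x$contacts$Cij)), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Go-model parameters
#'
#' Stiffnesses and well depths in units of the native-contact depth
#' `eps`; the temperature is in the same energy unit.
#'
#' @param K_theta Bond-angle stiffness (default 20).
#' @param K_phi1,K_phi3 Dihedral stiffnesses (defaults 1 and 0.5).
#' @param eps Native-contact well depth (default 1).
#' @param a_theta Orientation-factor width in radians (default `0.6 * pi`).
#' @param rep_sigma Non-native repulsion radius in angstrom (default 4).
#' @param rep_eps Repulsion scale (default 1).
#' @param temperature Metropolis temperature (default 1).
#' @param gamma Move amplitude as a fraction of pi (default 0.1).
#' @return List of class `"go_params"`.
#' @export
go_params <- function(K_theta = 20, K_phi1 = 1, K_phi3 = 0.5, eps = 1,
                      a_theta = 0.6 * pi, rep_sigma = 4, rep_eps = 1,
                      temperature = 1, gamma = 0.1) {
  stopifnot(K_theta >= 0, K_phi1 >= 0, K_phi3 >= 0, eps > 0,
            a_theta > 0, a_theta < pi, temperature > 0)
  out <- list(K_theta = K_theta, K_phi1 = K_phi1, K_phi3 = K_phi3,
              eps = eps, a_theta = a_theta, rep_sigma = rep_sigma,
              rep_eps = rep_eps, temperature = temperature, gamma = gamma)
  class(out) <- "go_params"
  out
}

#' Orientation factor of a residue pair
#'
#' Compares the current angle between the h-vectors of residues `i` and
#' `j` (`h_i = r_{i,i-1} + r_{i,i+1}`) with its native value:
#' `B = (1 + cos(pi * min(|Theta - Theta0|, a_theta) / a_theta)) / 2`,
#' equal to 1 at the native orientation and decaying to 0 at deviation
#' `a_theta`. Terminal residues have no h-vector, so `B = 1` there; a
#' degenerate (near-zero) h-vector also yields `B = 1` with a warning.
#'
#' @param xyz Current N x 3 C-alpha coordinates.
#' @param i,j Residue indices (1-based).
#' @param theta0_ij Native h-vector angle for the pair.
#' @param a_theta Width in radians.
#' @return `B` in \[0, 1\].
#' @export
orientation_factor <- function(xyz, i, j, theta0_ij, a_theta = 0.6 * pi) {
  n <- nrow(xyz)
  if (i == 1L || i == n || j == 1L || j == n) return(1)
  th <- hv_angle(xyz, i, j)
  if (is.na(th)) {
    warning("degenerate h-vector at pair (", i, ",", j, "); B = 1")
    return(1)
  }
  dv <- min(abs(th - theta0_ij), a_theta)
  0.5 * (1 + cos(pi * dv / a_theta))
}

## marshal topology columns for the C++ backend (0-based indices)
topo_args <- function(topo) {
  ct <- topo$contacts
  if (nrow(ct) == 0L) stop("topology has no native contacts")
  list(ci = as.integer(ct$i - 1L), cj = as.integer(ct$j - 1L),
       r0 = ct$r0, Cij = ct$Cij,
       Theta0 = ifelse(is.na(ct$Theta0), 0, ct$Theta0),
       theta0 = ifelse(is.na(topo$theta0), 0, topo$theta0),
       phi0 = ifelse(is.na(topo$phi0), 0, topo$phi0))
}

#' Total Go-model energy of a conformation
#'
#' @param xyz N x 3 C-alpha coordinates.
#' @param topo A `"native_topology"` of the same length.
#' @param params A `"go_params"`.
#' @return Energy in units of `eps`.
#' @export
go_energy <- function(xyz, topo, params = go_params()) {
  stopifnot(nrow(xyz) == topo$n)
  a <- topo_args(topo)
  go_energy_cpp(xyz, a$ci, a$cj, a$r0, a$Cij, a$Theta0, a$theta0, a$phi0,
                params$K_theta, params$K_phi1, params$K_phi3, params$eps,
                params$a_theta, params$rep_sigma, params$rep_eps)
}

#' Fraction of native contacts formed (Q value)
#'
#' A native contact counts as formed when its C-alpha distance is below
#' `ratio * r0`.
#'
#' @param xyz N x 3 C-alpha coordinates.
#' @param topo A `"native_topology"` (non-empty).
#' @param ratio Formation ratio (default 1.2).
#' @return Q in \[0, 1\].
#' @export
q_value <- function(xyz, topo, ratio = 1.2) {
  ct <- topo$contacts
  if (nrow(ct) == 0L) stop("topology has no native contacts")
  d <- sqrt(rowSums((xyz[ct$i, , drop = FALSE] -
                       xyz[ct$j, , drop = FALSE])^2))
  mean(d < ratio * ct$r0)
}

#' Extended starting chain
#'
#' Near-straight zigzag with exact 3.8 angstrom bonds (bond angle 120
#' degrees, all-trans dihedrals); no native contact of a compact fold is
#' formed in it.
#'
#' @param n Number of beads.
#' @return N x 3 coordinate matrix.
#' @export
extended_chain <- function(n) {
  chain_from_internal(rep(2 * pi / 3, n - 2L), rep(pi, n - 3L))
}

#' Metropolis folding simulation under the Go model
#'
#' Runs pivot-move Monte Carlo from an extended (or native) start and
#' samples energy, Q and per-contact formation flags at a fixed stride.
#'
#' @param topo A `"native_topology"`.
#' @param params A `"go_params"` (temperature matters most).
#' @param n_sweeps Number of sweeps.
#' @param seed Integer seed.
#' @param stride Sampling stride in sweeps.
#' @param start `"extended"` or `"native"`, or an N x 3 matrix.
#' @param q_ratio Contact-formation ratio for Q (default 1.2).
#' @return Object of class `"go_trajectory"`: list with `samples` (data
#'   frame `sweep`, `E`, `Q`), `flags` (samples x contacts logical
#'   matrix), `acceptance`, `xyz` (final), `temperature`, `seed`.
#' @export
fold_simulation <- function(topo, params = go_params(), n_sweeps = 20000L,
                            seed = 1L, stride = 10L, start = "extended",
                            q_ratio = 1.2) {
  a <- topo_args(topo)
  x0 <- if (is.matrix(start)) start
  else if (identical(start, "native")) topo$xyz
  else extended_chain(topo$n)
  set.seed(seed)
  res <- go_mc_cpp(x0, a$ci, a$cj, a$r0, a$Cij, a$Theta0, a$theta0, a$phi0,
                   params$K_theta, params$K_phi1, params$K_phi3, params$eps,
                   params$a_theta, params$rep_sigma, params$rep_eps,
                   params$temperature, params$gamma, as.integer(n_sweeps),
                   as.integer(stride), q_ratio)
  out <- list(samples = data.frame(sweep = res$sweep, E = res$E, Q = res$Q),
              flags = res$flags, acceptance = res$acceptance,
              xyz = res$xyz, energy = res$energy,
              energy_full = res$energy_full,
              temperature = params$temperature, seed = seed,
              contacts = topo$contacts[, c("i", "j")])
  class(out) <- "go_trajectory"
  out
}

#' @export
print.go_trajectory <- function(x, ...) {
  cat("Go trajectory: ", nrow(x$samples), " samples at T = ",
      x$temperature, ", final Q = ",
      round(x$samples$Q[nrow(x$samples)], 3), ", acceptance ",
      round(x$acceptance, 3), "\n", sep = "")
  invisible(x)
}

#' Locate the folding temperature by bisection
#'
#' Bisects the temperature until runs started half-way (from the native
#' state) spend a roughly even share of their samples in the folded basin
#' (`Q > q_mid`), i.e. until both basins are populated. The result is the
#' temperature at which transition-state statistics are collected.
#'
#' @param topo A `"native_topology"`.
#' @param params A `"go_params"` (its temperature field is ignored).
#' @param t_lo,t_hi Bracketing temperatures.
#' @param n_sweeps Sweeps per probe run.
#' @param seed Integer seed.
#' @param q_mid Q separating the basins (default 0.5).
#' @param target Folded-fraction window accepted as "even" (default
#'   c(0.3, 0.7)).
#' @param max_iter Bisection budget.
#' @return Temperature (numeric) with attribute `"folded_fraction"`.
#' @export
find_folding_temperature <- function(topo, params = go_params(),
                                     t_lo = 0.5, t_hi = 3, n_sweeps = 5000L,
                                     seed = 1L, q_mid = 0.5,
                                     target = c(0.3, 0.7), max_iter = 12L) {
  frac_folded <- function(temp, s) {
    p <- params
    p$temperature <- temp
    tr <- fold_simulation(topo, p, n_sweeps = n_sweeps, seed = s,
                          stride = 5L, start = "native")
    q <- tr$samples$Q
    mean(q[-seq_len(length(q) %/% 5)] > q_mid)  # drop first 20%
  }
  lo <- t_lo; hi <- t_hi
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f <- frac_folded(mid, seed + it)
    if (f >= target[1L] && f <= target[2L]) {
      attr(mid, "folded_fraction") <- f
      return(mid)
    }
    if (f > target[2L]) lo <- mid else hi <- mid
  }
  attr(mid, "folded_fraction") <- f
  warning("bisection did not settle inside the target window; returning T = ",
          round(mid, 3))
  mid
}

#' Transition-state ensemble contact map
#'
#' Pools Q samples from one or more trajectories, builds the free-energy
#' profile `F(Q) = -log P(Q)`, locates the interior barrier `Q*` between
#' the unfolded and folded basins, and counts, per native contact, how
#' often it is formed among samples with `|Q - Q*| <= bin_width`. Counts
#' are banded for display (e.g. "80-100").
#'
#' @param trajectories A `"go_trajectory"` or list of them (ideally at a
#'   temperature where both basins are visited).
#' @param bin_width Q histogram bin width (default 0.05).
#' @param band_size Width of the display count bands (default 20).
#' @param smooth_window Odd moving-average window (in occupied bins) used
#'   when locating basins and barrier; small topologies have ragged,
#'   parity-striped histograms and a light smoothing stabilises the
#'   barrier call (1 = no smoothing). The reported free-energy profile is
#'   always the raw one.
#' @return List of class `"ts_map"`: `q_star`, `free_energy` (data frame
#'   `q`, `count`, `F`), `map` (data frame `i`, `j`, `count`, `band`),
#'   `n_ensemble`.
#' @export
transition_state_map <- function(trajectories, bin_width = 0.05,
                                 band_size = 20L, smooth_window = 3L) {
  if (inherits(trajectories, "go_trajectory")) {
    trajectories <- list(trajectories)
  }
  q <- unlist(lapply(trajectories, function(t) t$samples$Q))
  flags <- do.call(rbind, lapply(trajectories, `[[`, "flags"))
  contacts <- trajectories[[1L]]$contacts
  ## bins centred on multiples of bin_width, so the discrete Q levels of
  ## small topologies (k / n_contacts) never sit on a bin edge
  breaks <- seq(-bin_width / 2, 1 + bin_width, by = bin_width)
  bin <- findInterval(q, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  mids <- head(breaks, -1L) + bin_width / 2
  occupied <- counts > 0L
  fe <- rep(NA_real_, length(counts))
  fe[occupied] <- -log(counts[occupied] / sum(counts))
  ## minima of (lightly smoothed) F over occupied bins
  occ_idx <- which(occupied)
  fo <- fe[occ_idx]
  k <- length(occ_idx)
  if (smooth_window > 1L && k >= smooth_window) {
    half <- smooth_window %/% 2L
    fo <- vapply(seq_len(k), function(t) {
      mean(fe[occ_idx][max(1L, t - half):min(k, t + half)])
    }, numeric(1L))
  }
  fes <- fe
  fes[occ_idx] <- fo
  is_min <- vapply(seq_len(k), function(t) {
    (t == 1L || fo[t] < fo[t - 1L]) && (t == k || fo[t] <= fo[t + 1L])
  }, logical(1L))
  minima <- occ_idx[is_min]
  if (length(minima) < 2L) {
    stop("no barrier at this temperature: free-energy profile is unimodal")
  }
  ## unfolded and folded basins: the pair of well-separated local minima
  ## (at least `min_separation` apart in Q) with the largest combined
  ## occupancy; spur minima inside one basin never qualify
  min_separation <- 0.3
  best <- NULL; best_occ <- -Inf
  for (a in seq_along(minima)) {
    for (b in seq_along(minima)) {
      if (b <= a) next
      if ((mids[minima[b]] - mids[minima[a]]) < min_separation) next
      occ2 <- counts[minima[a]] + counts[minima[b]]
      if (occ2 > best_occ) {
        best_occ <- occ2
        best <- c(minima[a], minima[b])
      }
    }
  }
  if (is.null(best)) {
    stop("no barrier at this temperature: basins are not separated")
  }
  lo <- best[1L]; hi <- best[2L]
  interior <- occ_idx[occ_idx > lo & occ_idx < hi]
  if (length(interior) == 0L) {
    stop("no barrier at this temperature: basins are adjacent")
  }
  barrier <- interior[which.max(fes[interior])]
  q_star <- mids[barrier]
  sel <- abs(q - q_star) <= bin_width
  cts <- if (any(sel)) colSums(flags[sel, , drop = FALSE]) else
    rep(0L, nrow(contacts))
  band_lo <- (cts %/% band_size) * band_size
  map <- data.frame(i = contacts$i, j = contacts$j, count = as.integer(cts),
                    band = paste0(band_lo, "-", band_lo + band_size))
  out <- list(q_star = q_star,
              free_energy = data.frame(q = mids, count = counts, F = fe),
              map = map, n_ensemble = sum(sel))
  class(out) <- "ts_map"
  out
}

#' Write topology / trajectory / TS-map TSV files
#'
#' Topology: `i, j, r0, contact_number, C_ij, Theta0`. Trajectory
#' samples: `sweep, E, Q`. Transition-state map: `i, j, count, band`.
#'
#' @param x The object to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topology <- function(x, path) {
  df <- x$contacts
  names(df)[names(df) == "n_atom_pairs"] <- "contact_number"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
write_trajectory <- function(x, path) {
  write.table(x$samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
write_ts_map <- function(x, path) {
  write.table(x$map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
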