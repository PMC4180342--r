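## Contact-frequency matrices and the per-residue F profile. A residue's
## F value measures its excess contact frequency over the
## separation-dependent baseline:
##   D(m)     = mean of g(i, j) over all pairs with |i - j| = m
##   q(u, v)  = max(0, g(u, v) - D(|u - v|))
##   F(u)     = sum_{v != u} q(u, v) / (N - 1)
## Peaks of F mark residues forming many inter-residue contacts —
## putative folding-initiation (hydrophobic collapse) sites, read like
## experimental phi values.

#' Contact-frequency matrix from an ensemble of runs
#'
#' Pools each run's contact counts into a per-run probability matrix and
#' averages the matrices across runs.
#'
#' @param runs A `"sim_ensemble"` (or list of `"sim_run"` objects).
#' @return N x N symmetric matrix of class `"contact_freq"` with values in
#'   \[0, 1\]; attribute `"per_run"` holds the per-run matrices.
#' @export
contact_frequency <- function(runs) {
  if (inherits(runs, "sim_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L)
  per_run <- lapply(runs, function(r) {
    if (r$n_samples == 0L) stop("run has zero sampled conformations")
    r$counts / r$n_samples
  })
  g <- Reduce(`+`, per_run) / length(per_run)
  attr(g, "per_run") <- per_run
  class(g) <- c("contact_freq", class(g))
  g
}

## Core formula; takes a bare symmetric matrix, returns the F vector.
f_from_g <- function(g) {
  n <- nrow(g)
  d_of_m <- vapply(seq_len(n - 1L), function(m) {
    idx <- cbind(seq_len(n - m), seq_len(n - m) + m)
    mean(g[idx])
  }, numeric(1L))
  sep <- abs(row(g) - col(g))
  baseline <- matrix(0, n, n)
  nz <- sep > 0L
  baseline[nz] <- d_of_m[sep[nz]]
  q <- g - baseline
  q[q < 0] <- 0
  diag(q) <- 0
  rowSums(q) / (n - 1L)
}

#' Per-residue F profile from a contact-frequency matrix
#'
#' Subtracts the separation-dependent baseline `D(m)` from `g`, keeps the
#' positive part, and averages each residue's excess over its partners.
#' When `g` carries per-run matrices (see [contact_frequency()]) the
#' inter-run standard deviation of F is reported as the error bar.
#'
#' @param g Symmetric contact-frequency matrix (values in \[0, 1\]).
#' @param min_prominence Passed to [find_peaks()].
#' @return Data frame of class `"f_profile"`: `residue`, `F`, `sd`,
#'   `is_peak`, `is_shoulder`.
#' @export
f_profile <- function(g, min_prominence = NULL) {
  g <- unclass(g)
  n <- nrow(g)
  if (n < 3L) stop("need at least 3 residues for an F profile")
  stopifnot(isTRUE(all.equal(g, t(g), tolerance = 1e-8)))
  fv <- f_from_g(g)
  per_run <- attr(g, "per_run")
  sd_f <- if (!is.null(per_run) && length(per_run) > 1L) {
    apply(vapply(per_run, f_from_g, numeric(n)), 1L, sd)
  } else {
    rep(NA_real_, n)
  }
  pk <- find_peaks(fv, min_prominence = min_prominence)
  out <- data.frame(residue = seq_len(n), F = fv, sd = sd_f,
                    is_peak = seq_len(n) %in% pk$peaks,
                    is_shoulder = seq_len(n) %in% pk$shoulders)
  class(out) <- c("f_profile", class(out))
  out
}

#' Locate peaks (and shoulders) of a per-residue profile
#'
#' A peak is a local maximum lying above the profile mean whose
#' prominence (height above the higher of the two flanking saddles)
#' reaches `min_prominence`; plateaus count as a single peak at their
#' centre. A shoulder is a non-peak position above the profile mean whose
#' value exceeds the mean of its two neighbours while the profile is
#' still rising or falling through it.
#'
#' @param x Numeric profile (length >= 3).
#' @param min_prominence Minimum prominence; default `0.5 * sd(x)`.
#' @return List with integer vectors `peaks` and `shoulders`.
#' @export
find_peaks <- function(x, min_prominence = NULL) {
  n <- length(x)
  stopifnot(n >= 3L)
  if (is.null(min_prominence)) min_prominence <- 0.5 * sd(x)
  if (!is.finite(min_prominence)) min_prominence <- 0
  mu <- mean(x)
  cand <- integer(0L)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L  # plateau
      if (j < n && x[j + 1L] < x[j]) {
        cand <- c(cand, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  prominence <- vapply(cand, function(p) {
    left <- if (p > 1L) min(x[1L:p]) else x[p]
    right <- if (p < n) min(x[p:n]) else x[p]
    ## saddle toward the nearest higher ground on each side
    lsad <- sad_toward(x, p, -1L)
    rsad <- sad_toward(x, p, +1L)
    x[p] - max(lsad, rsad, min(left, right))
  }, numeric(1L))
  peaks <- cand[x[cand] > mu & prominence >= min_prominence]
  shoulders <- setdiff(which(vapply(2L:(n - 1L), function(i) {
    x[i] > mu && x[i] > mean(c(x[i - 1L], x[i + 1L]))
  }, logical(1L))) + 1L, c(peaks, cand))
  list(peaks = peaks, shoulders = shoulders)
}

## lowest point between p and the first position higher than x[p] in the
## given direction (or the profile end).
sad_toward <- function(x, p, dir) {
  i <- p + dir
  lo <- x[p]
  while (i >= 1L && i <= length(x)) {
    if (x[i] > x[p]) return(lo)
    lo <- min(lo, x[i])
    i <- i + dir
  }
  lo
}

#' Native packing pairs of a structure
#'
#' Residue pairs (|i - j| >= `min_sep`) whose closest heavy atoms lie
#' within `cutoff` angstrom. For C-alpha-only structures a C-alpha cutoff
#' of 6.5 angstrom is used instead, with a warning.
#'
#' @param structure A `"structure3d"`.
#' @param cutoff Heavy-atom distance cutoff in angstrom (default 5).
#' @param min_sep Minimum sequence separation (default 3).
#' @param hydrophobic Hydrophobic residue set.
#' @return Data frame of class `"packing_report"`: `i`, `j`, `min_dist`,
#'   `both_hydrophobic`; attribute `"mode"` records `"heavy"` or `"ca"`.
#' @export
packing_pairs <- function(structure, cutoff = 5, min_sep = 3L,
                          hydrophobic = hydrophobic_residues()) {
  stopifnot(inherits(structure, "structure3d"))
  ca_only <- all(structure$atoms$elety == "CA")
  mode <- "heavy"
  if (ca_only) {
    warning("C-alpha-only structure: falling back to a 6.5 A C-alpha cutoff")
    cutoff <- 6.5
    mode <- "ca"
  }
  n <- length(structure$resno)
  coords <- lapply(structure$resno, function(r) {
    as.matrix(structure$atoms[structure$atoms$resno == r,
                              c("x", "y", "z"), drop = FALSE])
  })
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + min_sep):n) {
      if (j > n) break
      d <- min(cross_dist(coords[[i]], coords[[j]]))
      if (d <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          i = i, j = j, min_dist = d,
          both_hydrophobic = structure$sequence[i] %in% hydrophobic &&
            structure$sequence[j] %in% hydrophobic)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), min_dist = numeric(0),
               both_hydrophobic = logical(0))
  attr(out, "mode") <- mode
  class(out) <- c("packing_report", class(out))
  out
}

## all pairwise distances between two coordinate sets
cross_dist <- function(a, b) {
  sqrt(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b))
}

#' Correspondence between F-profile peaks and native packing
#'
#' For every residue in a packing pair, reports the nearest F peak and
#' whether it lies within `window` residues; for every peak, lists the
#' packing residues within the window.
#'
#' @param profile An `"f_profile"`.
#' @param report A `"packing_report"` for the same protein.
#' @param window Residue window (default 3).
#' @return List with data frames `by_residue` (`residue`, `nearest_peak`,
#'   `delta`, `within_window`) and `by_peak` (`peak`, `n_packing_within`,
#'   `partners`).
#' @export
peak_packing_correspondence <- function(profile, report, window = 3L) {
  peaks <- profile$residue[profile$is_peak]
  pk_res <- sort(unique(c(report$i, report$j)))
  by_residue <- if (length(pk_res) && length(peaks)) {
    nearest <- vapply(pk_res, function(r) peaks[which.min(abs(peaks - r))],
                      numeric(1L))
    data.frame(residue = pk_res, nearest_peak = nearest,
               delta = abs(pk_res - nearest),
               within_window = abs(pk_res - nearest) <= window)
  } else {
    data.frame(residue = integer(0), nearest_peak = numeric(0),
               delta = numeric(0), within_window = logical(0))
  }
  by_peak <- data.frame(
    peak = peaks,
    n_packing_within = vapply(peaks, function(p) {
      sum(abs(pk_res - p) <= window)
    }, integer(1L)),
    partners = vapply(peaks, function(p) {
      paste(pk_res[abs(pk_res - p) <= window], collapse = ",")
    }, character(1L)))
  list(by_residue = by_residue, by_peak = by_peak)
}

#' Write an F profile as TSV
#'
#' Columns `residue`, `F`, `sd`, `is_peak` with a header line.
#'
#' @param profile An `"f_profile"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_f_profile <- function(profile, path) {
  write.table(profile[, c("residue", "F", "sd", "is_peak")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
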