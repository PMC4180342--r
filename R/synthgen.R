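## Synthetic inputs for every pipeline stage: toy structures with exact
## 3.8 A virtual bonds and pseudo-heavy side-chain atoms, chimeric
## sequences, and alignments with controlled per-column conservation.
## The structures are geometric idealisations (helix rise 1.5 A/residue,
## pseudo-extended strands); the two pseudo-atoms per residue are the
## minimal, deliberately non-physical decoration that lets heavy-atom
## rules (4 A contacts, 5 A packing) run on synthetic input.

#' Generate a toy structure
#'
#' Kinds: `"helix"` (ideal alpha-helix), `"hairpin"` (two pseudo-extended
#' strands joined by a turn), `"bundle3"` (three-helix bundle) and
#' `"hairpin_helix"` (hairpin packed against a helix). Consecutive
#' C-alpha distances are exactly 3.8 angstrom; two pseudo-heavy atoms per
#' residue are placed along the outward side-chain direction. Generation
#' is deterministic given `seed` (the sequence is sampled; coordinates
#' are deterministic per kind and length).
#'
#' @param kind Structure kind.
#' @param length Number of residues (>= 6).
#' @param seed Integer seed for the sequence sample.
#' @param sequence Optional one-letter sequence overriding the sample.
#' @return A `"structure3d"` object.
#' @export
make_structure <- function(kind = c("helix", "hairpin", "bundle3",
                                    "hairpin_helix"),
                           length, seed = 1L, sequence = NULL) {
  kind <- match.arg(kind)
  stopifnot(length >= 6L)
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- paste(sample(AA20, length, replace = TRUE), collapse = "")
  }
  stopifnot(nchar(sequence) == length)
  xyz <- switch(kind,
                helix = helix_path(length),
                hairpin = retrace(hairpin_path(length)),
                bundle3 = retrace(bundle3_path(length)),
                hairpin_helix = retrace(hairpin_helix_path(length)))
  build_synthetic_structure(xyz, sequence, kind)
}

## ideal helix with exact 3.8 A bonds: rise 1.5 A/residue, 100 deg turn,
## radius solved from the bond-length constraint
helix_path <- function(n, phase = 0, origin = c(0, 0, 0), flip = FALSE) {
  rise <- 1.5
  dtheta <- 100 * pi / 180
  radius <- sqrt(BOND_LENGTH^2 - rise^2) / (2 * sin(dtheta / 2))
  k <- seq_len(n) - 1L
  z <- k * rise
  if (flip) z <- -z
  cbind(radius * cos(phase + k * dtheta) + origin[1L],
        radius * sin(phase + k * dtheta) + origin[2L],
        z + origin[3L])
}

## planar zigzag hairpin built from unit bond headings (exact bonds)
hairpin_path <- function(n) {
  psi <- acos(3.3 / BOND_LENGTH)            # zigzag half-angle
  s <- (n - 2L) %/% 2L                      # residues per strand
  headings <- c(
    rep(c(pi / 2 - psi, pi / 2 + psi), length.out = s - 1L),
    pi / 4, -pi / 4,                        # two turn bonds
    rep(c(-pi / 2 + psi, -pi / 2 - psi), length.out = n - s - 2L))
  pts <- matrix(0, n, 3L)
  for (k in seq_len(n - 1L)) {
    pts[k + 1L, ] <- pts[k, ] +
      BOND_LENGTH * c(cos(headings[k]), sin(headings[k]), 0)
  }
  pts
}

bundle3_path <- function(n) {
  per <- n %/% 3L
  h1 <- helix_path(per)
  h2 <- helix_path(per, phase = pi, origin = c(9, 0, (per - 1L) * 1.5),
                   flip = TRUE)
  h3 <- helix_path(n - 2L * per, phase = pi / 2, origin = c(4.5, 8, 0))
  rbind(h1, h2, h3)
}

hairpin_helix_path <- function(n) {
  nh <- n %/% 3L                 # helix residues
  hp <- hairpin_path(n - nh)
  width <- max(hp[, 1L]) / 2
  hx <- helix_path(nh, origin = c(width, max(hp[, 2L]) * 0.25, 5.5))
  ## helix axis along +z, sheet in the z = 0 plane; re-aim the helix to
  ## run alongside the sheet instead
  hx <- cbind(hx[, 1L], hx[, 3L] + max(hp[, 2L]) * 0.25, hx[, 2L] + 5.5)
  rbind(hp, hx)
}

## Re-trace a raw path with exact bond lengths: each bead steps 3.8 A
## toward the next raw waypoint, so the trace follows the designed shape
## while satisfying the bond constraint exactly.
retrace <- function(raw) {
  n <- nrow(raw)
  out <- raw
  for (k in seq_len(n - 1L)) {
    u <- raw[k + 1L, ] - out[k, ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) u <- c(1, 0, 0) else u <- u / nu
    out[k + 1L, ] <- out[k, ] + BOND_LENGTH * u
  }
  out
}

## decorate C-alpha trace with two pseudo side-chain atoms pointing away
## from the local chain direction
build_synthetic_structure <- function(xyz, sequence, kind) {
  n <- nrow(xyz)
  letters1 <- strsplit(sequence, "")[[1L]]
  u <- matrix(0, n, 3L)
  for (i in 2L:(n - 1L)) {
    b <- (xyz[i - 1L, ] - xyz[i, ]) + (xyz[i + 1L, ] - xyz[i, ])
    nb <- sqrt(sum(b^2))
    u[i, ] <- if (nb > 1e-8) -b / nb else c(0, 0, 1)
  }
  u[1L, ] <- u[2L, ]
  u[n, ] <- u[n - 1L, ]
  rows <- lapply(seq_len(n), function(i) {
    base <- xyz[i, ]
    data.frame(resno = i,
               resid = bio3d::aa123(letters1[i]),
               elety = c("CA", "CB", "CG"),
               element = "C",
               x = c(base[1L], base[1L] + 1.5 * u[i, 1L],
                     base[1L] + 2.8 * u[i, 1L]),
               y = c(base[2L], base[2L] + 1.5 * u[i, 2L],
                     base[2L] + 2.8 * u[i, 2L]),
               z = c(base[3L], base[3L] + 1.5 * u[i, 3L],
                     base[3L] + 2.8 * u[i, 3L]),
               stringsAsFactors = FALSE)
  })
  st <- structure_from_atoms(do.call(rbind, rows), chain = "A", model = 1L,
                             source = paste0("synthetic:", kind))
  st
}

#' Compose a chimeric sequence from two parents
#'
#' Copies segments alternately from the two parents. `crossovers` are the
#' 1-based positions at which a new segment (from the other parent)
#' begins; the first segment comes from `start`. Optional point mutations
#' are applied last.
#'
#' @param parent_a,parent_b Equal-length one-letter strings.
#' @param crossovers Strictly increasing positions in `2..length`.
#' @param point_mutations Named character vector, names = positions.
#' @param start `"A"` or `"B"`; parent of the first segment.
#' @return One-letter chimera string.
#' @export
#' @examples
#' make_chimera("AAAA", "CCCC", crossovers = 3)        # "AACC"
make_chimera <- function(parent_a, parent_b, crossovers = integer(0L),
                         point_mutations = NULL, start = "A") {
  a <- strsplit(toupper(parent_a), "")[[1L]]
  b <- strsplit(toupper(parent_b), "")[[1L]]
  if (length(a) != length(b)) stop("parents must have equal length")
  n <- length(a)
  crossovers <- as.integer(crossovers)
  if (length(crossovers)) {
    if (any(crossovers < 2L | crossovers > n)) {
      stop("crossover positions must lie in 2..", n)
    }
    if (is.unsorted(crossovers, strictly = TRUE)) {
      stop("crossovers must be strictly increasing")
    }
  }
  from_a <- identical(start, "A")
  out <- character(n)
  seg <- 0L
  for (i in seq_len(n)) {
    if (seg < length(crossovers) && i == crossovers[seg + 1L]) {
      from_a <- !from_a
      seg <- seg + 1L
    }
    out[i] <- if (from_a) a[i] else b[i]
  }
  if (!is.null(point_mutations)) {
    pos <- as.integer(names(point_mutations))
    stopifnot(all(pos >= 1L & pos <= n))
    out[pos] <- toupper(unname(point_mutations))
  }
  paste(out, collapse = "")
}

#' Generate an alignment with planned per-column conservation
#'
#' Each column's modal residue is the planned consensus and its fraction
#' matches the plan to within `1/rows` (fractions of the form `k/rows`
#' are realised exactly). Substitutions are drawn as distinct letters
#' cycling through `variant_pool`.
#'
#' @param rows Number of sequences (>= 2).
#' @param length Alignment length; ignored when `conservation_plan` has
#'   names.
#' @param conservation_plan Numeric vector of target modal fractions, one
#'   per column (recycled).
#' @param seed Integer seed.
#' @param consensus Optional character vector of consensus letters (one
#'   per column); sampled otherwise.
#' @param variant_pool Letters used for substitutions (default the
#'   hydrophobic set, so "+" columns are constructible).
#' @return An `"alignment"` (named character vector).
#' @export
make_alignment <- function(rows, length, conservation_plan = 1,
                           seed = 1L, consensus = NULL,
                           variant_pool = hydrophobic_residues()) {
  stopifnot(rows >= 2L)
  set.seed(seed)
  plan <- rep_len(conservation_plan, length)
  if (any(plan < 1 / rows - 1e-9)) {
    stop("infeasible plan: a modal fraction below 1/rows")
  }
  if (is.null(consensus)) {
    consensus <- sample(AA20, length, replace = TRUE)
  } else {
    stopifnot(length(consensus) == length)
  }
  mat <- matrix("", rows, length)
  for (j in seq_len(length)) {
    n_match <- max(1L, round(plan[j] * rows))
    n_var <- rows - n_match
    pool <- setdiff(variant_pool, consensus[j])
    if (n_var > 0L && ceiling(n_var / length(pool)) >= n_match) {
      stop("infeasible plan at column ", j,
           ": variants would outnumber the consensus")
    }
    col <- c(rep(consensus[j], n_match),
             if (n_var > 0L) rep_len(pool, n_var))
    mat[, j] <- sample(col)  # shuffle rows
  }
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- paste0("row", seq_len(rows))
  class(out) <- "alignment"
  out
}

#' Synthetic reference structure set
#'
#' A mixed bag of helices, hairpins and bundles for building the
#' average-distance statistics table without any download. The longest
#' members are extended (helical) so the pooled mean distance grows with
#' the separation bin, as it does in the reference statistics compiled
#' from real globular proteins; compact kinds (hairpin, bundle, mixed)
#' populate the short and medium bins.
#'
#' @param n_structures Number of structures (default 6).
#' @param seed Integer seed.
#' @return List of `"structure3d"` objects.
#' @export
make_reference_set <- function(n_structures = 6L, seed = 1L) {
  kinds <- rep_len(c("helix", "bundle3", "hairpin",
                     "helix", "bundle3", "hairpin_helix"), n_structures)
  lengths <- rep_len(c(30L, 36L, 24L, 54L, 48L, 42L), n_structures)
  lapply(seq_len(n_structures), function(i) {
    make_structure(kinds[i], lengths[i], seed = seed * 1000L + i)
  })
}

#' Synthetic chameleon demo system
#'
#' Emulates the study system: two ~60%-identical parent sequences of
#' length 56 (a 3-alpha "GA-like" and a 4-beta+alpha "GB-like" parent),
#' two chimeric 56-residue queries differing at a single site (98%
#' identity), homolog alignments for each fold with controlled
#' conservation, native-like toy structures for both folds, and a
#' reference structure set for the statistics table. Everything is
#' deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param switch_site Site at which the two queries differ (default 45).
#' @return List with `parents`, `queries`, `alignments`, `structures`
#'   and `reference_set`.
#' @export
make_demo_system <- function(seed = 1L, switch_site = 45L) {
  set.seed(seed)
  n <- 56L
  parent_a <- paste(sample(AA20, n, replace = TRUE), collapse = "")
  ## parent B: ~40% of sites mutated
  pa <- strsplit(parent_a, "")[[1L]]
  pb <- pa
  mut <- sort(sample(n, size = round(0.4 * n)))
  pb[mut] <- vapply(pb[mut], function(r) sample(setdiff(AA20, r), 1L),
                    character(1L))
  parent_b <- paste(pb, collapse = "")
  ## chimeric queries: alternate parent segments every ~12 residues,
  ## then force the single switch site
  cross <- seq(12L, n - 4L, by = 12L)
  core <- make_chimera(parent_a, parent_b, crossovers = cross, start = "A")
  query_ga <- make_chimera(core, core,
                           point_mutations = setNames("L", switch_site))
  query_gb <- make_chimera(core, core,
                           point_mutations = setNames("Y", switch_site))
  ## homolog alignments: mostly well-conserved columns around each query,
  ## hydrophobic variants so "+" columns occur
  plan_a <- rep_len(c(1, 6 / 7, 1, 5 / 7), n)
  aln_a <- make_alignment(7L, n, plan_a, seed = seed + 1L,
                          consensus = strsplit(query_ga, "")[[1L]])
  plan_b <- rep_len(c(1, 0.9, 0.8, 1), n)
  aln_b <- make_alignment(20L, n, plan_b, seed = seed + 2L,
                          consensus = strsplit(query_gb, "")[[1L]])
  list(parents = c(A = parent_a, B = parent_b),
       queries = c(GA98 = query_ga, GB98 = query_gb),
       alignments = list(`3a` = aln_a, `4b+a` = aln_b),
       structures = list(
         `3a` = make_structure("bundle3", n, sequence = query_ga),
         `4b+a` = make_structure("hairpin_helix", n, sequence = query_gb)),
       reference_set = make_reference_set(6L, seed = seed),
       switch_site = switch_site)
}
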