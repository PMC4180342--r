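## Local sequence tendency of a chimeric sequence: per-site attribution
## to the two parent sequences, +/-1 scoring, Gaussian-kernel smoothing,
## and extrema calls. A large positive value of the smoothed track means
## the local sequence descends from parent A (by default the 3-alpha GA
## parent), a large negative value from parent B (the 4-beta+alpha GB
## parent); the `flip` switch negates the convention.

#' Attribute each site of a chimera to its parents
#'
#' Site labels: `"A"` if the query matches parent A only, `"B"` for
#' parent B only, `"both"` where the parents agree and the query matches,
#' `"neither"` where the query matches no parent.
#'
#' @param query,parent_a,parent_b Equal-length aligned one-letter strings.
#' @return Object of class `"parent_attribution"`: character vector of
#'   labels with the three sequences kept as attributes.
#' @export
attribute_sites <- function(query, parent_a, parent_b) {
  qs <- strsplit(toupper(query), "")[[1L]]
  as_ <- strsplit(toupper(parent_a), "")[[1L]]
  bs <- strsplit(toupper(parent_b), "")[[1L]]
  if (length(qs) != length(as_) || length(qs) != length(bs)) {
    stop("query and parents must be aligned to equal length")
  }
  lab <- ifelse(qs == as_ & qs == bs, "both",
                ifelse(qs == as_, "A",
                       ifelse(qs == bs, "B", "neither")))
  structure(lab, class = "parent_attribution",
            query = query, parent_a = parent_a, parent_b = parent_b)
}

#' Smoothed local sequence tendency
#'
#' Scores each site +1 when it descends from parent A, -1 from parent B
#' and 0 when both or neither, then smooths with a normalised
#' (Nadaraya-Watson) Gaussian kernel of bandwidth `h` residues, so a
#' homogeneous block reads exactly +/-1. Peaks and valleys are local
#' extrema of the smoothed track.
#'
#' @param attribution A `"parent_attribution"`.
#' @param h Gaussian kernel bandwidth (standard deviation) in residues
#'   (default 3.5).
#' @param flip Negate the sign convention.
#' @return Data frame of class `"tendency_profile"`: `site`, `score`,
#'   `t`, `is_peak`, `is_valley`.
#' @export
tendency <- function(attribution, h = 3.5, flip = FALSE) {
  stopifnot(inherits(attribution, "parent_attribution"), h > 0)
  s <- ifelse(attribution == "A", 1, ifelse(attribution == "B", -1, 0))
  if (flip) s <- -s
  n <- length(s)
  sites <- seq_len(n)
  w <- outer(sites, sites, function(x, i) dnorm(x - i, sd = h))
  ## numerator and denominator share the same summation order, so a
  ## constant score vector smooths to exactly +/-1
  t_sm <- as.numeric(w %*% s) / as.numeric(w %*% rep(1, n))
  is_peak <- is_valley <- rep(FALSE, n)
  if (any(s != 0)) {
    for (i in 2L:(n - 1L)) {
      if (t_sm[i] > t_sm[i - 1L] && t_sm[i] >= t_sm[i + 1L] && t_sm[i] > 0) {
        is_peak[i] <- TRUE
      }
      if (t_sm[i] < t_sm[i - 1L] && t_sm[i] <= t_sm[i + 1L] && t_sm[i] < 0) {
        is_valley[i] <- TRUE
      }
    }
  }
  out <- data.frame(site = sites, score = s, t = t_sm,
                    is_peak = is_peak, is_valley = is_valley)
  attr(out, "h") <- h
  attr(out, "flip") <- flip
  class(out) <- c("tendency_profile", class(out))
  out
}

#' Overlay conserved sites on a tendency profile
#'
#' For each extremum of the tendency track, counts the conserved sites of
#' each fold lying within `window` residues — the visual of conserved
#' hydrophobic residues clustering at tendency peaks and valleys.
#'
#' @param profile A `"tendency_profile"`.
#' @param conserved_a,conserved_b Integer site lists (e.g. from
#'   [conserved_hydrophobic_sites()]) for the two folds.
#' @param window Residue window (default 3).
#' @return Data frame: `site`, `kind` ("peak"/"valley"), `t`,
#'   `n_conserved_a`, `n_conserved_b`.
#' @export
overlay_conserved <- function(profile, conserved_a, conserved_b,
                              window = 3L) {
  ext <- which(profile$is_peak | profile$is_valley)
  data.frame(
    site = ext,
    kind = ifelse(profile$is_peak[ext], "peak", "valley"),
    t = profile$t[ext],
    n_conserved_a = vapply(ext, function(e) {
      sum(abs(conserved_a - e) <= window)
    }, integer(1L)),
    n_conserved_b = vapply(ext, function(e) {
      sum(abs(conserved_b - e) <= window)
    }, integer(1L)))
}

#' Write a tendency profile as TSV
#'
#' @param profile A `"tendency_profile"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tendency <- function(profile, path) {
  df <- profile
  df$extremum <- ifelse(df$is_peak, "peak",
                        ifelse(df$is_valley, "valley", ""))
  write.table(df[, c("site", "score", "t", "extremum")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
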