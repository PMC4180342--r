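## Conservation analysis of multiple alignments: per-column consensus and
## conservation marks ("*" = perfectly conserved, "+" = at least 85%
## conserved with every variant hydrophobic), conserved-hydrophobic site
## extraction, and the fold classifier that combines fold-specific
## conserved sites with F-profile peaks.

#' Conservation marks for an alignment
#'
#' Per column: the modal (consensus) residue, its fraction (gaps count as
#' mismatches and never as consensus), and a mark — `"*"` when the column
#' is perfectly conserved, `"+"` when the consensus fraction reaches
#' `plus_threshold` and every variant residue is hydrophobic (so one
#' substitution among 7 rows reports as 6/7 ~ 0.857, an "85% conserved"
#' column).
#'
#' @param alignment An `"alignment"` (named character vector, equal
#'   lengths) from [read_fasta()] with `alignment = TRUE`.
#' @param hydrophobic Hydrophobic residue set.
#' @param plus_threshold Minimum consensus fraction for `"+"`.
#' @return Data frame of class `"conservation_profile"`: `column`,
#'   `consensus`, `fraction`, `mark`, `hydrophobic`.
#' @export
conservation_marks <- function(alignment,
                               hydrophobic = hydrophobic_residues(),
                               plus_threshold = 0.85) {
  stopifnot(length(alignment) >= 2L)
  mat <- do.call(rbind, strsplit(toupper(unclass(alignment)), ""))
  n_rows <- nrow(mat)
  n_cols <- ncol(mat)
  res <- data.frame(column = seq_len(n_cols), consensus = NA_character_,
                    fraction = NA_real_, mark = "", hydrophobic = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_cols)) {
    col <- mat[, j]
    residues <- col[col != "-"]
    if (length(residues) == 0L) next
    tab <- sort(table(residues), decreasing = TRUE)
    cons <- names(tab)[1L]
    frac <- as.numeric(tab[1L]) / n_rows  # gaps count as mismatches
    variants <- setdiff(unique(residues), cons)
    mark <- ""
    if (frac == 1) {
      mark <- "*"
    } else if (frac >= plus_threshold && !any(col == "-") &&
               length(variants) > 0L && all(variants %in% hydrophobic) &&
               cons %in% hydrophobic) {
      mark <- "+"
    }
    res$consensus[j] <- cons
    res$fraction[j] <- frac
    res$mark[j] <- mark
    res$hydrophobic[j] <- cons %in% hydrophobic
  }
  class(res) <- c("conservation_profile", class(res))
  res
}

#' Conserved hydrophobic sites of a conservation profile
#'
#' Columns marked `"*"` or `"+"` whose consensus residue is hydrophobic.
#'
#' @param profile A `"conservation_profile"`.
#' @return Integer vector of column positions.
#' @export
conserved_hydrophobic_sites <- function(profile) {
  profile$column[profile$mark %in% c("*", "+") & profile$hydrophobic]
}

#' Build a fold profile from a conservation profile
#'
#' Collects a fold's conserved sites (marked columns) with their required
#' residue; `"+"` columns require only the hydrophobic class.
#'
#' @param label Fold label (e.g. `"3a"` or `"4b+a"`).
#' @param profile A `"conservation_profile"` for that fold's homologs.
#' @return Object of class `"fold_profile"`: list with `label` and
#'   `sites` (data frame `position`, `residue`, `perfect`,
#'   `hydrophobic_class`).
#' @export
fold_profile <- function(label, profile) {
  keep <- profile$mark %in% c("*", "+")
  sites <- data.frame(position = profile$column[keep],
                      residue = profile$consensus[keep],
                      perfect = profile$mark[keep] == "*",
                      hydrophobic_class = profile$mark[keep] == "+",
                      stringsAsFactors = FALSE)
  structure(list(label = label, sites = sites), class = "fold_profile")
}

#' Classify a query sequence against fold profiles
#'
#' Implements the fold-discrimination recipe: for each fold, score the
#' weighted fraction of its conserved sites matched by the query.
#' A site matches when the query holds the required residue (or, for a
#' hydrophobic-class site, any hydrophobic residue). Sites lying within
#' `window` residues of an F-profile peak carry double weight — the
#' conservation of residues around folding-initiation sites is what
#' discriminates the folds. A mismatch at a perfectly conserved site
#' vetoes the fold (score forced below every non-vetoed fold).
#'
#' @param query One-letter sequence aligned to the profiles' coordinates.
#' @param fold_profiles List of `"fold_profile"` objects.
#' @param f_peaks Integer positions of F-profile peaks (may be empty).
#' @param window Peak window for double weighting (default 3).
#' @param hydrophobic Hydrophobic residue set.
#' @return Data frame of class `"fold_classification"` ranked by score:
#'   `fold`, `score`, `vetoed`, `n_sites`, `n_matched`; attribute
#'   `"evidence"` holds one per-site data frame per fold.
#' @export
classify_fold <- function(query, fold_profiles, f_peaks = integer(0L),
                          window = 3L,
                          hydrophobic = hydrophobic_residues()) {
  if (length(fold_profiles) == 0L) stop("no fold profiles supplied")
  qs <- strsplit(toupper(query), "")[[1L]]
  evidence <- list()
  rows <- lapply(fold_profiles, function(fp) {
    st <- fp$sites
    if (any(st$position > length(qs))) {
      stop("fold profile '", fp$label, "' has sites beyond the query length")
    }
    qres <- qs[st$position]
    matched <- ifelse(st$hydrophobic_class,
                      qres %in% hydrophobic, qres == st$residue)
    near_peak <- if (length(f_peaks)) {
      vapply(st$position, function(p) any(abs(f_peaks - p) <= window),
             logical(1L))
    } else rep(FALSE, nrow(st))
    weight <- ifelse(near_peak, 2, 1)
    score <- if (nrow(st)) sum(weight * matched) / sum(weight) else 0
    vetoed <- any(st$perfect & !matched)
    evidence[[fp$label]] <<- data.frame(
      position = st$position, required = st$residue,
      query = qres, matched = matched, perfect = st$perfect,
      near_peak = near_peak, weight = weight,
      contribution = weight * matched / max(sum(weight), 1))
    data.frame(fold = fp$label, score = score, vetoed = vetoed,
               n_sites = nrow(st), n_matched = sum(matched),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank_score <- ifelse(out$vetoed, out$score - 1, out$score)
  out <- out[order(-out$rank_score), ]
  out$rank_score <- NULL
  rownames(out) <- NULL
  attr(out, "evidence") <- evidence
  class(out) <- c("fold_classification", class(out))
  out
}

#' Write a fold classification report as JSON
#'
#' Includes the ranked scores and the per-site evidence rows.
#'
#' @param classification A `"fold_classification"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(classification, path) {
  payload <- list(ranking = as.data.frame(classification),
                  evidence = attr(classification, "evidence"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
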