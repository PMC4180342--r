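## Sequence, alignment and structure I/O plus residue-level conventions.
## All residue indexing is 1-based in chain order; structure objects also
## retain the author residue numbering from the source file.

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a named character vector of one-letter
#' sequences. Residues are uppercased; gap characters (`-` and `.`) are
#' stripped unless `alignment = TRUE`, in which case `.` is normalised to
#' `-` and all rows must have equal length.
#'
#' @param path Path to a FASTA file.
#' @param alignment Logical; keep gap columns and validate equal lengths.
#' @return Named character vector of sequences. When `alignment = TRUE`
#'   the result has class `"alignment"`.
#' @export
read_fasta <- function(path, alignment = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("malformed FASTA: first non-blank line (line 1) is not a header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header at line ", which(hdr)[!nzchar(ids)][1L])
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1L),
                 collapse = "")
  if (length(seqs) != length(ids)) {
    stop("malformed FASTA: record with no sequence lines in ", path)
  }
  seqs <- toupper(gsub("\\s", "", unname(seqs)))
  if (alignment) {
    seqs <- gsub("\\.", "-", seqs)
  } else {
    seqs <- gsub("[-.]", "", seqs)
  }
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X-]"), seqs)
  if (any(bad)) {
    stop("non-amino-acid characters in record '", ids[bad][1L], "'")
  }
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  names(seqs) <- ids
  if (alignment) {
    if (length(seqs) < 2L) stop("an alignment needs at least 2 rows")
    if (length(unique(nchar(seqs))) != 1L) {
      stop("alignment rows have unequal lengths")
    }
    class(seqs) <- "alignment"
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (an `"alignment"` is
#'   accepted unchanged).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a protein structure from a PDB file
#'
#' Wraps [bio3d::read.pdb()]. Hydrogens are dropped, the highest-occupancy
#' alternate location is kept, and residues lacking a C-alpha atom are
#' skipped with a warning. For NMR-style multi-model files `model` selects
#' the MODEL block (default the first); the chosen model is recorded so
#' every structure-derived quantity can report it.
#'
#' @param path Path to a PDB file.
#' @param model Model index (1-based).
#' @param chain Optional chain identifier; default the first chain present.
#' @return An object of class `"structure"`: a list with elements `atoms`
#'   (data frame: `resno`, `resid`, `elety`, `element`, `x`, `y`, `z`),
#'   `sequence` (one-letter vector, length N), `resno` (author residue
#'   numbers, length N), `chain`, `model` and `source`.
#' @export
read_pdb <- function(path, model = 1L, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records in ", path)
  n_models <- max(1L, nrow(pdb$xyz))
  if (model > n_models) {
    stop("model ", model, " requested but file has ", n_models, " model(s)")
  }
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  ## drop hydrogens (element symbol H or D, or H-leading atom names)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("^[0-9]", "", at$elety), 1L, 1L)
  }
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(elem %in% c("H", "D"))]
  ## altloc: keep blank or highest occupancy per (resno, elety)
  if (any(at$alt != "", na.rm = TRUE)) {
    key <- paste(at$resno, at$insert, at$elety)
    occ <- if (!is.null(at$o)) at$o else rep(1, nrow(at))
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  structure_from_atoms(
    data.frame(resno = at$resno, resid = at$resid, elety = at$elety,
               element = substr(gsub("^[0-9]", "", at$elety), 1L, 1L),
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    chain = chain[1L], model = as.integer(model), source = path
  )
}

## Assemble a validated "structure" object from an atom table, preserving
## residue order of first appearance. Residues without a CA are skipped.
structure_from_atoms <- function(atoms, chain = "A", model = 1L,
                                 source = NA_character_) {
  stopifnot(all(c("resno", "resid", "elety", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  resno <- unique(atoms$resno)
  has_ca <- vapply(resno, function(r) {
    any(atoms$elety[atoms$resno == r] == "CA")
  }, logical(1L))
  if (any(!has_ca)) {
    warning("skipping ", sum(!has_ca), " residue(s) without a C-alpha atom")
    atoms <- atoms[atoms$resno %in% resno[has_ca], , drop = FALSE]
    resno <- resno[has_ca]
  }
  if (length(resno) == 0L) stop("structure has no residues with C-alpha atoms")
  resid3 <- vapply(resno, function(r) atoms$resid[atoms$resno == r][1L],
                   character(1L))
  seq1 <- suppressWarnings(bio3d::aa321(resid3))
  seq1[is.na(seq1) | !(seq1 %in% c(AA20, "X"))] <- "X"
  out <- list(atoms = atoms, sequence = unname(seq1),
              resno = resno, chain = chain, model = model, source = source)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat("C-alpha structure: ", length(x$resno), " residues, ",
      nrow(x$atoms), " heavy atoms (chain ", x$chain,
      ", model ", x$model, ")\n", sep = "")
  cat(" sequence: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' C-alpha coordinates of a structure
#'
#' @param structure A `"structure3d"` object.
#' @return N x 3 numeric matrix of C-alpha coordinates in residue order.
#' @export
ca_coords <- function(structure) {
  stopifnot(inherits(structure, "structure3d"))
  idx <- vapply(structure$resno, function(r) {
    which(structure$atoms$resno == r & structure$atoms$elety == "CA")[1L]
  }, integer(1L))
  as.matrix(structure$atoms[idx, c("x", "y", "z")])
}

#' Write a structure to a PDB file
#'
#' @param structure A `"structure3d"` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms
  resid3 <- vapply(at$resid, function(r) {
    if (nchar(r) == 1L) bio3d::aa123(r) else r
  }, character(1L))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = resid3, elety = at$elety,
    chain = rep(structure$chain, nrow(at)), eleno = seq_len(nrow(at))
  )
  invisible(path)
}

#' Percent sequence identity of two aligned sequences
#'
#' Computes `100 * identical / compared` over aligned columns, rounded to
#' the nearest integer so one substitution in 56 residues reports as 98.
#' Columns with a gap in either row are excluded from the denominator.
#'
#' @param a,b Character scalars (aligned, equal length; `-` marks gaps).
#' @return Integer percentage.
#' @export
#' @examples
#' percent_identity(strrep("A", 56), paste0(strrep("A", 55), "G"))  # 98
percent_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences must be pre-aligned to equal length (got ",
         nchar(a), " and ", nchar(b), ")")
  }
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no gap-free columns to compare")
  as.integer(round(100 * sum(ca[keep] == cb[keep]) / sum(keep)))
}

## Map a structure's one-letter sequence, with X excluded from type-pair
## statistics downstream.
residue_letters <- function(structure) structure$sequence
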