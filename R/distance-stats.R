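## Inter-residue average-distance statistics: per residue-type pair (A,B)
## and sequence-separation range bin M, the mean and spread of the
## C-alpha--C-alpha distance observed in a set of reference structures.
## These statistics parameterise the coil potential.

#' Separation range bin
#'
#' Maps a sequence separation `k = |i - j|` to its range bin M:
#' M = 1 for 1 <= k <= 8, M = 2 for 9 <= k <= 20, and then one bin per
#' decade (21-30, 31-40, ...).
#'
#' @param k Integer vector of separations, `k >= 1`.
#' @return Integer vector of bins.
#' @export
#' @examples
#' bin_of(c(1, 8, 9, 20, 21, 41))  # 1 1 2 2 3 5
bin_of <- function(k) {
  k <- as.integer(k)
  if (any(k < 1L)) stop("separation k must be >= 1")
  ifelse(k <= 8L, 1L, ifelse(k <= 20L, 2L, 3L + (k - 21L) %/% 10L))
}

#' Build the average-distance statistics table
#'
#' Accumulates, over all residue pairs of all input structures, the mean
#' and standard deviation of the C-alpha distance per unordered
#' residue-type pair and range bin. Residue type `X` is excluded from the
#' statistics. Cells never observed have `n = 0` and `NA` mean/sd.
#'
#' @param structures List of `"structure3d"` objects (at least one).
#' @param max_bin Largest bin to tabulate; default covers the longest
#'   input chain.
#' @return An object of class `"avg_dist_table"`: list with 20 x 20 x M
#'   arrays `mean`, `sd`, `n`, plus `max_bin` and `sources`.
#' @export
build_table <- function(structures, max_bin = NULL) {
  if (inherits(structures, "structure3d")) structures <- list(structures)
  if (length(structures) == 0L) stop("need at least one reference structure")
  stopifnot(all(vapply(structures, inherits, logical(1L), "structure3d")))
  if (is.null(max_bin)) {
    nmax <- max(vapply(structures, function(s) length(s$resno), integer(1L)))
    max_bin <- if (nmax < 2L) 1L else bin_of(nmax - 1L)
  }
  dims <- c(20L, 20L, max_bin)
  dn <- list(AA20, AA20, NULL)
  s1 <- array(0, dims, dimnames = dn)   # sum of r
  s2 <- array(0, dims, dimnames = dn)   # sum of r^2
  n  <- array(0L, dims, dimnames = dn)
  for (st in structures) {
    xyz <- ca_coords(st)
    seq1 <- st$sequence
    N <- nrow(xyz)
    if (N < 2L) next
    ai <- match(seq1, AA20)  # NA for X
    for (i in seq_len(N - 1L)) {
      if (is.na(ai[i])) next
      j <- (i + 1L):N
      ok <- !is.na(ai[j])
      if (!any(ok)) next
      j <- j[ok]
      d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
      m <- pmin(bin_of(j - i), max_bin)
      for (t in seq_along(j)) {
        a <- ai[i]; b <- ai[j[t]]
        lo <- min(a, b); hi <- max(a, b)
        s1[lo, hi, m[t]] <- s1[lo, hi, m[t]] + d[t]
        s2[lo, hi, m[t]] <- s2[lo, hi, m[t]] + d[t]^2
        n[lo, hi, m[t]] <- n[lo, hi, m[t]] + 1L
      }
    }
  }
  ## symmetrise: accumulate into upper triangle, mirror afterwards
  for (m in seq_len(max_bin)) {
    s1[, , m] <- s1[, , m] + t(s1[, , m]) - diag(diag(s1[, , m]))
    s2[, , m] <- s2[, , m] + t(s2[, , m]) - diag(diag(s2[, , m]))
    n[, , m]  <- n[, , m]  + t(n[, , m])  - diag(diag(n[, , m]))
  }
  mean_r <- ifelse(n > 0L, s1 / pmax(n, 1L), NA_real_)
  var_r <- ifelse(n > 1L, (s2 - s1^2 / pmax(n, 1L)) / pmax(n - 1L, 1L), NA_real_)
  var_r[var_r < 0] <- 0
  sd_r <- sqrt(var_r)
  sd_r[n == 1L] <- 0
  out <- list(mean = mean_r, sd = sd_r, n = n, max_bin = max_bin,
              sources = vapply(structures, function(s) {
                if (is.na(s$source)) "synthetic" else s$source
              }, character(1L)))
  class(out) <- "avg_dist_table"
  out
}

#' @export
print.avg_dist_table <- function(x, ...) {
  filled <- sum(x$n > 0L)
  cat("average-distance table: ", x$max_bin, " range bin(s), ",
      filled, "/", length(x$n), " cells populated, ",
      length(x$sources), " source structure(s)\n", sep = "")
  invisible(x)
}

#' Impute empty cells of an average-distance table
#'
#' Cells with no observations are filled from the residue-type-pooled mean
#' and spread for the same range bin (`policy = "pooled"`). A minimum
#' spread (default 0.5 angstrom) is enforced everywhere so sparse cells
#' cannot produce a singular potential.
#'
#' @param table An `"avg_dist_table"`.
#' @param policy Imputation policy; only `"pooled"` is implemented.
#' @param sd_floor Minimum allowed spread in angstrom.
#' @return The completed table; imputed cells keep `n = 0`.
#' @export
fill_missing <- function(table, policy = "pooled", sd_floor = 0.5) {
  stopifnot(inherits(table, "avg_dist_table"))
  policy <- match.arg(policy, "pooled")
  if (all(table$n == 0L)) stop("table has no populated cells to pool from")
  for (m in seq_len(table$max_bin)) {
    nm <- table$n[, , m]
    if (all(nm == 0L)) {
      ## empty bin: reuse the last populated bin below it
      src <- max(which(vapply(seq_len(m - 1L), function(mm) {
        any(table$n[, , mm] > 0L)
      }, logical(1L))))
      table$mean[, , m] <- table$mean[, , src]
      table$sd[, , m] <- table$sd[, , src]
      next
    }
    pooled_mean <- sum(table$mean[, , m] * nm, na.rm = TRUE) / sum(nm)
    pooled_sd <- sqrt(sum(table$sd[, , m]^2 * nm, na.rm = TRUE) / sum(nm))
    miss <- nm == 0L
    mu <- table$mean[, , m]; sg <- table$sd[, , m]
    mu[miss] <- pooled_mean
    sg[miss] <- pooled_sd
    table$mean[, , m] <- mu
    table$sd[, , m] <- sg
  }
  table$sd <- pmax(table$sd, sd_floor)
  table
}

#' Look up mean/spread for a residue-type pair and separation
#'
#' Separations beyond the table's largest bin reuse the last bin.
#'
#' @param table An `"avg_dist_table"` (complete, see [fill_missing()]).
#' @param a,b One-letter residue types.
#' @param k Sequence separation.
#' @return List with `mean` and `sd` (angstrom).
#' @export
table_lookup <- function(table, a, b, k) {
  m <- min(bin_of(k), table$max_bin)
  ia <- match(a, AA20); ib <- match(b, AA20)
  if (is.na(ia) || is.na(ib)) stop("residue type outside the 20 standard letters")
  if (is.na(table$mean[ia, ib, m])) {
    stop("empty statistics cell (", a, ",", b, ",M=", m,
         "); run fill_missing() first")
  }
  list(mean = table$mean[ia, ib, m], sd = table$sd[ia, ib, m])
}

#' Write / read an average-distance table as TSV
#'
#' The interchange format between the statistics builder and the coil
#' sampler: columns `A`, `B`, `M`, `mean_A`, `sd_A`, `n` with a header
#' line, one row per unordered pair and bin.
#'
#' @param table An `"avg_dist_table"`.
#' @param path File path.
#' @return `write_dist_table` returns `path` invisibly; `read_dist_table`
#'   returns an `"avg_dist_table"`.
#' @export
write_dist_table <- function(table, path) {
  stopifnot(inherits(table, "avg_dist_table"))
  rows <- list()
  for (m in seq_len(table$max_bin)) {
    for (a in seq_len(20L)) for (b in a:20L) {
      rows[[length(rows) + 1L]] <- data.frame(
        A = AA20[a], B = AA20[b], M = m,
        mean_A = table$mean[a, b, m], sd_A = table$sd[a, b, m],
        n = table$n[a, b, m])
    }
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_table
#' @export
read_dist_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("A", "B", "M", "mean_A", "sd_A", "n") %in% names(df)))
  max_bin <- max(df$M)
  dn <- list(AA20, AA20, NULL)
  out <- list(mean = array(NA_real_, c(20L, 20L, max_bin), dn),
              sd = array(NA_real_, c(20L, 20L, max_bin), dn),
              n = array(0L, c(20L, 20L, max_bin), dn),
              max_bin = max_bin, sources = character(0L))
  ia <- match(df$A, AA20); ib <- match(df$B, AA20)
  for (r in seq_len(nrow(df))) {
    a <- ia[r]; b <- ib[r]; m <- df$M[r]
    out$mean[a, b, m] <- out$mean[b, a, m] <- df$mean_A[r]
    out$sd[a, b, m] <- out$sd[b, a, m] <- df$sd_A[r]
    out$n[a, b, m] <- out$n[b, a, m] <- df$n[r]
  }
  class(out) <- "avg_dist_table"
  out
}

## Per-pair parameter matrices for one sequence: NxN matrices of the
## table's mean and sd at each pair's separation bin. 'X' residues take
## the bin's pooled values (the fill_missing() imputation applied to a
## virtual pair).
pair_param_matrices <- function(table, sequence) {
  stopifnot(inherits(table, "avg_dist_table"))
  if (anyNA(table$mean)) stop("table has empty cells; run fill_missing() first")
  letters1 <- strsplit(sequence, "")[[1L]]
  N <- length(letters1)
  ai <- match(letters1, AA20)
  rbar <- matrix(0, N, N)
  sg <- matrix(1, N, N)
  pooled <- lapply(seq_len(table$max_bin), function(m) {
    w <- pmax(table$n[, , m], 1L)
    list(mean = sum(table$mean[, , m] * w) / sum(w),
         sd = sqrt(sum(table$sd[, , m]^2 * w) / sum(w)))
  })
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    m <- min(bin_of(j - i), table$max_bin)
    if (is.na(ai[i]) || is.na(ai[j])) {
      rbar[i, j] <- rbar[j, i] <- pooled[[m]]$mean
      sg[i, j] <- sg[j, i] <- pooled[[m]]$sd
    } else {
      rbar[i, j] <- rbar[j, i] <- table$mean[ai[i], ai[j], m]
      sg[i, j] <- sg[j, i] <- table$sd[ai[i], ai[j], m]
    }
  }
  list(rbar = rbar, sigma = sg)
}
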