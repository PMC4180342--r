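## End-to-end orchestration: statistics table -> coil Monte Carlo ->
## F profile -> sequence tendency -> conservation -> fold classification.
## Configured by a plain list or a YAML file; every stage writes its TSV
## into the output directory and the whole run is summarised in a JSON
## manifest with input/output checksums.

#' Default pipeline configuration
#'
#' Returns the configuration skeleton accepted by [run_pipeline()], with
#' a synthetic demo system filled in. Fields: `query` (sequence string or
#' FASTA path), `parents` (character vector `A`/`B` or FASTA path with
#' two records), `alignments` (named list of aligned-FASTA paths or
#' alignment objects, one per fold), `table` (TSV path, or `NULL` to
#' build from `reference` structures), `coil` (list: `n_runs`,
#' `n_sweeps`, `pad`, `seed`), `classify` (list: `window`).
#'
#' @param seed Integer seed for the demo system.
#' @param n_runs,n_sweeps Coil Monte Carlo budget.
#' @return Configuration list.
#' @export
demo_config <- function(seed = 1L, n_runs = 4L, n_sweeps = 1500L) {
  demo <- make_demo_system(seed)
  list(query = unname(demo$queries["GA98"]),
       parents = demo$parents,
       alignments = demo$alignments,
       table = NULL,
       reference = demo$reference_set,
       coil = list(n_runs = n_runs, n_sweeps = n_sweeps, pad = 10L,
                   seed = seed),
       classify = list(window = 3L))
}

#' Run the fold-discrimination pipeline
#'
#' Executes every sequence-side stage for one query: builds (or loads)
#' the average-distance table, samples random coil conformations and
#' derives the F profile, computes the sequence tendency against the two
#' parents, marks conservation on each fold's alignment, and classifies
#' the query against the fold profiles with F-peak weighting. All inputs
#' are validated before any compute starts.
#'
#' @param config Configuration list (see [demo_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list, also written as `manifest.json`):
#'   config snapshot, seeds, stage outputs and md5 checksums.
#' @export
run_pipeline <- function(config, out_dir = tempfile("switchfold_run_")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  ## ---- validate everything up front ----
  query <- resolve_sequence(config$query, "query")
  parents <- config$parents
  if (is.character(parents) && length(parents) == 1L && file.exists(parents)) {
    parents <- read_fasta(parents)
  }
  if (length(parents) != 2L) {
    stop("config$parents must supply two sequences (or a FASTA with two records)")
  }
  alignments <- lapply(config$alignments, function(a) {
    if (is.character(a) && length(a) == 1L && file.exists(a)) {
      read_fasta(a, alignment = TRUE)
    } else if (inherits(a, "alignment")) a
    else stop("config$alignments entries must be paths or alignment objects")
  })
  if (length(alignments) < 1L) stop("config$alignments must name >= 1 fold")
  coil <- modifyList(list(n_runs = 10L, n_sweeps = 60000L, pad = 10L,
                          seed = 1L), config$coil %||% list())
  window <- (config$classify %||% list())$window %||% 3L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- stage 1: statistics table ----
  tab <- if (!is.null(config$table)) {
    read_dist_table(config$table)
  } else {
    refs <- config$reference %||% make_reference_set(seed = coil$seed)
    fill_missing(build_table(refs))
  }
  if (anyNA(tab$mean)) tab <- fill_missing(tab)
  write_dist_table(tab, file.path(out_dir, "distance_table.tsv"))

  ## ---- stage 2: coil MC + F profile ----
  seeds <- coil$seed * 1000L + seq_len(coil$n_runs)
  runs <- run_ensemble(query, tab, n_runs = coil$n_runs,
                       n_sweeps = coil$n_sweeps, seeds = seeds,
                       pad = coil$pad)
  g <- contact_frequency(runs)
  fprof <- f_profile(g)
  write_f_profile(fprof, file.path(out_dir, "f_profile.tsv"))

  ## ---- stage 3: sequence tendency ----
  att <- attribute_sites(query, parents[[1L]], parents[[2L]])
  tend <- tendency(att)
  write_tendency(tend, file.path(out_dir, "tendency.tsv"))

  ## ---- stage 4: conservation + fold profiles ----
  profiles <- lapply(names(alignments), function(lbl) {
    cons <- conservation_marks(alignments[[lbl]])
    write.table(cons, file.path(out_dir, paste0("conservation_",
                                                sanitise(lbl), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fold_profile(lbl, cons)
  })

  ## ---- stage 5: classification ----
  peaks <- fprof$residue[fprof$is_peak]
  cls <- classify_fold(query, profiles, f_peaks = peaks, window = window)
  write_classification(cls, file.path(out_dir, "classification.json"))

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("switchfold")),
    seeds = seeds,
    acceptance = vapply(runs, `[[`, numeric(1L), "acceptance"),
    coil = coil,
    f_peaks = peaks,
    top_fold = cls$fold[1L],
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$out_dir <- out_dir
  manifest$classification <- cls
  manifest$f_profile <- fprof
  manifest$tendency <- tend
  invisible(manifest)
}

resolve_sequence <- function(x, what) {
  if (is.null(x)) stop("config$", what, " is missing")
  if (file.exists(x)) {
    seqs <- read_fasta(x)
    return(unname(seqs[[1L]]))
  }
  if (!grepl(paste0("^[", paste(AA20, collapse = ""), "X]+$"), toupper(x))) {
    stop("config$", what, " is neither a file nor a valid sequence")
  }
  toupper(x)
}

sanitise <- function(x) gsub("[^A-Za-z0-9_]+", "_", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
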