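#' Normalise a set of parsed arrays end to end
#'
#' Runs the full pipeline on in-memory [array_table]s: within-array
#' preprocessing (background correction, exclusions, reference-channel
#' detection, block-by-block median centering, duplicate averaging),
#' all-pairs cyclic loess normalisation with antisymmetric averaging, and
#' the final per-array median correction.  Stage snapshots are kept for
#' diagnostics: raw (uncentred) spot log-ratios, the step-4/5 feature
#' vectors, the matrix after pairwise averaging, and the final matrix.
#'
#' @param arrays List of [array_table]s (>= 2).  Duplicate array IDs get
#'   numeric suffixes with a warning.
#' @param preprocess A [preprocess_config].
#' @param cyclic A [cyclic_config].
#' @param verbose Emit per-array progress messages.
#' @return An object of class `cycloess_run`: a list with `matrix` (the
#'   final features x arrays log2-ratio matrix, `NA` where a feature took
#'   part in no comparison for that array), `vectors`, `arrays` (with
#'   exclusion bookkeeping), `exclusions` (per-array tally data frame),
#'   `stages` (named list of per-stage, per-array value collections),
#'   `pairs` (pairwise fit log) and `n_fits`.
#' @export
normalise_arrays <- function(arrays,
                             preprocess = preprocess_config(),
                             cyclic = cyclic_config(),
                             verbose = FALSE) {
  stopifnot(length(arrays) >= 2L,
            all(vapply(arrays, inherits, logical(1L), "array_table")))
  ids <- vapply(arrays, `[[`, character(1L), "array_id")
  if (anyDuplicated(ids)) {
    warning("duplicate array IDs; adding numeric suffixes: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- make.unique(ids, sep = "_")
    for (i in seq_along(arrays)) arrays[[i]]$array_id <- ids[i]
  }

  pp <- lapply(arrays, function(arr) {
    if (verbose)
      message("preprocessing array '", arr$array_id, "' (",
              nrow(arr$spots), " spots)")
    preprocess_array(arr, preprocess)
  })
  vectors <- lapply(pp, `[[`, "vector")

  mat <- cyclic_normalise(vectors, cyclic)
  pairs <- attr(mat, "pairs")
  n_fits <- attr(mat, "n_fits")
  mat7 <- mat
  if (cyclic$do_final_centering) mat <- center_arrays(mat)

  tally <- do.call(rbind, lapply(pp, function(p) {
    sp <- p$array$spots
    data.frame(array_id = p$array$array_id,
               n_spots = nrow(sp),
               software_flag = sum(sp$exclusion_reason == "software_flag"),
               empty_name = sum(sp$exclusion_reason == "empty_name"),
               background_filter =
                 sum(sp$exclusion_reason == "background_filter"),
               nonpositive_intensity =
                 sum(sp$exclusion_reason == "nonpositive_intensity"),
               n_used = sum(!sp$excluded),
               n_features = length(p$vector$values),
               stringsAsFactors = FALSE)
  }))
  rownames(tally) <- NULL

  stages <- list(
    raw_log_ratios = stats::setNames(
      lapply(pp, function(p)
        stats::setNames(p$raw_ratios$ratio, p$raw_ratios$feature_id)),
      vapply(pp, function(p) p$array$array_id, character(1L))),
    block_centred = stats::setNames(
      lapply(vectors, `[[`, "values"),
      vapply(vectors, `[[`, character(1L), "array_id")),
    cyclic_loess = mat7,
    final = mat)

  structure(list(matrix = mat, vectors = vectors,
                 arrays = lapply(pp, `[[`, "array"),
                 exclusions = tally, stages = stages,
                 pairs = pairs, n_fits = n_fits,
                 preprocess = preprocess, cyclic = cyclic),
            class = "cycloess_run")
}

#' @export
print.cycloess_run <- function(x, ...) {
  cat(sprintf("cycloess_run: %d arrays, %d features, %d pairwise fits\n",
              ncol(x$matrix), nrow(x$matrix), x$n_fits))
  cat(sprintf("  missing cells: %d of %d\n",
              sum(is.na(x$matrix)), length(x$matrix)))
  cat("  exclusions per array:\n")
  print(x$exclusions, row.names = FALSE)
  invisible(x)
}

#' Run the full normalisation pipeline on microarray files
#'
#' Reads any mixture of GenePix and BlueFuse files (formats are detected
#' per file; array IDs default to file basenames), normalises them with
#' [normalise_arrays()], and optionally writes the expression matrix and
#' tab-separated diagnostic summaries.  The matrix is written atomically
#' (via a temporary file in the destination directory), so a failure never
#' leaves a partial output behind.
#'
#' @param input_paths Character vector of file paths and/or glob patterns
#'   resolving to >= 2 array files.
#' @param output_path Destination for the tab-separated expression matrix
#'   (`NA` for missing cells); `NULL` skips writing.
#' @param preprocess A [preprocess_config].
#' @param cyclic A [cyclic_config].
#' @param emit_diagnostics Write per-stage boxplot statistics, per-array
#'   distribution summaries and the pairwise fit log as TSV files.
#' @param diagnostics_dir Directory for the diagnostic TSVs (created if
#'   needed); required when `emit_diagnostics` is `TRUE`.
#' @param verbose Emit progress messages.
#' @return The `cycloess_run` (invisibly when `output_path` is given).
#' @export
run_pipeline <- function(input_paths,
                         output_path = NULL,
                         preprocess = preprocess_config(),
                         cyclic = cyclic_config(),
                         emit_diagnostics = FALSE,
                         diagnostics_dir = NULL,
                         verbose = FALSE) {
  files <- unlist(lapply(input_paths, function(p)
    if (file.exists(p)) p else Sys.glob(p)))
  if (length(files) < 2L)
    stop("need at least 2 input files; got ",
         length(files), " from: ", paste(input_paths, collapse = ", "))
  arrays <- lapply(files, function(f) {
    if (verbose) message("reading ", f)
    read_array(f)
  })
  run <- normalise_arrays(arrays, preprocess, cyclic, verbose = verbose)

  if (!is.null(output_path)) {
    tmp <- tempfile("matrix_", tmpdir = dirname(output_path))
    on.exit(unlink(tmp), add = TRUE)
    write_expression_matrix(run$matrix, tmp)
    if (!file.rename(tmp, output_path))
      stop("could not write output to ", output_path)
  }
  if (emit_diagnostics) {
    if (is.null(diagnostics_dir))
      stop("emit_diagnostics = TRUE requires diagnostics_dir")
    write_diagnostics(run, diagnostics_dir)
  }
  invisible(run)
}

#' Write diagnostic summaries of a pipeline run as TSV files
#'
#' Emits `boxplot_stats.tsv` (Tukey statistics per array for each pipeline
#' stage), `distribution_stats.tsv` (per-array sd and skewness per stage),
#' `pairs.tsv` (the pairwise fit log) and `exclusions.tsv`.
#'
#' @param run A `cycloess_run` from [normalise_arrays()]/[run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the directory.
#' @export
write_diagnostics <- function(run, dir) {
  stopifnot(inherits(run, "cycloess_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  box <- do.call(rbind, lapply(names(run$stages), function(st)
    boxplot_stats(run$stages[[st]], stage = st)))
  dist <- do.call(rbind, lapply(names(run$stages), function(st) {
    d <- distribution_stats(run$stages[[st]])
    d$stage <- st
    d
  }))
  utils::write.table(box, file.path(dir, "boxplot_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dist, file.path(dir, "distribution_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$exclusions, file.path(dir, "exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
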