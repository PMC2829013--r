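#' Within-array preprocessing configuration
#'
#' @param k_sd Width of the background filter in background standard
#'   deviations.  A GenePix spot is excluded when, in either channel, the
#'   raw median foreground lies below median background + `k_sd` x
#'   background SD; the default 3 corresponds to keeping only spots whose
#'   intensity exceeds background at ~99.73% confidence.
#' @param auto_reference Detect the reference channel automatically from
#'   the channel medians (the common-reference gDNA channel is assumed to
#'   have the higher median, which also resolves dye swaps).  When
#'   `FALSE`, `fixed_reference_channel` must be given.
#' @param fixed_reference_channel 1 or 2; used when `auto_reference` is
#'   `FALSE`.
#' @param empty_name_patterns Feature-name patterns marking blank/control
#'   spots.  A pattern ending in `-` matches as a prefix (`"ctrl-"`
#'   matches `"ctrl-spike7"`), otherwise it must match exactly.  Matching
#'   is case-sensitive; the empty name `""` always matches.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(k_sd = 3,
                              auto_reference = TRUE,
                              fixed_reference_channel = NULL,
                              empty_name_patterns = c("EMPTY", "empty",
                                                      "ctrl-", "Ctrl-")) {
  stopifnot(is.numeric(k_sd), length(k_sd) == 1L, k_sd > 0,
            isTRUE(auto_reference) || isFALSE(auto_reference))
  if (!auto_reference) {
    if (is.null(fixed_reference_channel) ||
        !fixed_reference_channel %in% c(1L, 2L))
      stop("auto_reference = FALSE requires fixed_reference_channel (1 or 2)")
    fixed_reference_channel <- as.integer(fixed_reference_channel)
  }
  structure(list(k_sd = k_sd, auto_reference = auto_reference,
                 fixed_reference_channel = fixed_reference_channel,
                 empty_name_patterns = as.character(empty_name_patterns)),
            class = "preprocess_config")
}

#' Background-correct an array (step 1)
#'
#' For GenePix arrays the median background is subtracted from the median
#' foreground in both channels; the raw foregrounds are kept (columns
#' `raw_fg1`/`raw_fg2`) because the background filter compares the raw
#' quantities.  Corrected intensities may be non-positive; such spots are
#' excluded later, when log-ratios are computed.  BlueFuse arrays pass
#' through unchanged, as the BlueFuse software background-corrects
#' internally.
#'
#' @param array An [array_table].
#' @return The corrected [array_table].
#' @export
background_correct <- function(array) {
  stopifnot(inherits(array, "array_table"))
  if (array$background_corrected) return(array)
  sp <- array$spots
  sp$raw_fg1 <- sp$fg1
  sp$raw_fg2 <- sp$fg2
  if (array$format == "genepix") {
    sp$fg1 <- sp$fg1 - sp$bg1
    sp$fg2 <- sp$fg2 - sp$bg2
  }
  array$spots <- sp
  array$background_corrected <- TRUE
  array
}

# does feature_id denote a blank/control spot?
is_empty_name <- function(ids, patterns) {
  hit <- ids == ""
  for (p in patterns) {
    if (endsWith(p, "-")) hit <- hit | startsWith(ids, p)
    else hit <- hit | ids == p
  }
  hit
}

#' Flag spots for exclusion (steps 1-2)
#'
#' A spot is excluded when any of the following holds, with the first
#' matching reason recorded:
#' * `software_flag`: GenePix flag -50, -75 or -100 ('not found',
#'   'absent', 'bad'), or BlueFuse quality letter `E` (the lowest grade);
#' * `empty_name`: the feature name matches an empty/control pattern;
#' * `background_filter` (GenePix only): in either channel the raw median
#'   foreground is below median background + `k_sd` x background SD.
#'
#' Exclusion decisions are recomputed from scratch on each call.  For
#' GenePix arrays, [background_correct()] must have been applied first so
#' the raw foregrounds are available alongside the retained backgrounds.
#'
#' @param array An [array_table], background-corrected if GenePix.
#' @param config A [preprocess_config].
#' @return The [array_table] with `excluded`/`exclusion_reason` set.
#' @export
apply_exclusions <- function(array, config = preprocess_config()) {
  stopifnot(inherits(array, "array_table"),
            inherits(config, "preprocess_config"))
  sp <- array$spots
  if (array$format == "genepix") {
    if (!array$background_corrected)
      stop("apply background_correct() before apply_exclusions() ",
           "on GenePix arrays")
    flagnum <- suppressWarnings(as.numeric(sp$flag))
    software <- !is.na(flagnum) & flagnum %in% c(-50, -75, -100)
    weak <- (sp$raw_fg1 < sp$bg1 + config$k_sd * sp$bg_sd1) |
            (sp$raw_fg2 < sp$bg2 + config$k_sd * sp$bg_sd2)
  } else {
    software <- sp$flag == "E"
    weak <- FALSE
  }
  empty <- is_empty_name(sp$feature_id, config$empty_name_patterns)
  reason <- rep("none", nrow(sp))
  reason[weak]     <- "background_filter"
  reason[empty]    <- "empty_name"
  reason[software] <- "software_flag"
  sp$exclusion_reason <- reason
  sp$excluded <- reason != "none"
  array$spots <- sp
  array
}

#' Assign signal and reference channel roles (step 3)
#'
#' With the common-reference design the reference (gDNA) channel has the
#' higher median intensity on every array, so comparing the per-channel
#' medians of the background-corrected intensities over non-excluded spots
#' identifies the reference channel — and thereby handles dye swaps
#' automatically.  An exact tie violates that assumption and raises an
#' error asking for `fixed_reference_channel`.
#'
#' @inheritParams apply_exclusions
#' @return The [array_table] with `signal_channel` and `reference_channel`
#'   set.
#' @export
detect_reference_channel <- function(array, config = preprocess_config()) {
  stopifnot(inherits(array, "array_table"),
            inherits(config, "preprocess_config"))
  if (!config$auto_reference) {
    ref <- config$fixed_reference_channel
  } else {
    keep <- !array$spots$excluded
    if (!any(keep))
      stop("array '", array$array_id, "' has no non-excluded spots")
    med1 <- stats::median(array$spots$fg1[keep])
    med2 <- stats::median(array$spots$fg2[keep])
    if (med1 == med2)
      stop("channel medians tie exactly on array '", array$array_id,
           "'; the higher-median reference assumption is violated - set ",
           "auto_reference = FALSE and fixed_reference_channel explicitly")
    ref <- if (med1 > med2) 1L else 2L
  }
  array$reference_channel <- ref
  array$signal_channel <- if (ref == 1L) 2L else 1L
  array
}

#' Compute spot-level log2 signal/reference ratios (step 4, first half)
#'
#' For every non-excluded spot with positive corrected intensity in both
#' channels the value `log2(signal / reference)` is computed.  Spots with
#' a non-positive corrected intensity in either channel are excluded with
#' reason `nonpositive_intensity`.
#'
#' @param array An [array_table] with channel roles assigned.
#' @return A list with `array` (updated exclusions) and `ratios`, a data
#'   frame with columns `feature_id`, `block` and `ratio`.
#' @export
compute_log_ratios <- function(array) {
  stopifnot(inherits(array, "array_table"))
  if (is.na(array$signal_channel))
    stop("channel roles not assigned; run detect_reference_channel() first")
  sp <- array$spots
  sig <- if (array$signal_channel == 1L) sp$fg1 else sp$fg2
  ref <- if (array$signal_channel == 1L) sp$fg2 else sp$fg1
  nonpos <- !sp$excluded & (sig <= 0 | ref <= 0)
  sp$excluded[nonpos] <- TRUE
  sp$exclusion_reason[nonpos] <- "nonpositive_intensity"
  keep <- !sp$excluded
  array$spots <- sp
  list(array = array,
       ratios = data.frame(feature_id = sp$feature_id[keep],
                           block = sp$block[keep],
                           ratio = log2(sig[keep] / ref[keep]),
                           stringsAsFactors = FALSE))
}

#' Centre each block's median log-ratio at zero (step 4, second half)
#'
#' Within every sub-array (block — the print-tip group recorded in the
#' file itself) the block median is subtracted from each spot's log-ratio,
#' under the assumption that the majority of genes are unchanging.  After
#' centering, every occupied block has median exactly 0; a single-spot
#' block centres to 0.
#'
#' @param ratios Data frame as returned by [compute_log_ratios()].
#' @return The data frame with centred `ratio` values.
#' @export
center_blocks <- function(ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("block", "ratio") %in% names(ratios)))
  if (!nrow(ratios)) return(ratios)
  ratios$ratio <- ratios$ratio -
    stats::ave(ratios$ratio, ratios$block, FUN = stats::median)
  ratios
}

#' Average duplicate features (step 5)
#'
#' Where the same sequence is spotted more than once on an array, the
#' arithmetic mean of its (centred) log-ratios is taken so each feature
#' appears exactly once per array.  Features whose every spot was excluded
#' are simply absent.
#'
#' @param ratios Data frame of centred ratios ([center_blocks()]).
#' @param array_id Identifier carried into the result.
#' @return A `feature_vector`: list with `array_id` and `values`, a named
#'   numeric vector keyed by feature ID (sorted).
#' @export
average_duplicates <- function(ratios, array_id) {
  stopifnot(is.data.frame(ratios),
            all(c("feature_id", "ratio") %in% names(ratios)))
  means <- tapply(ratios$ratio, ratios$feature_id, mean)
  feature_vector(array_id, stats::setNames(as.numeric(means), names(means)))
}

#' Construct a feature vector
#'
#' One array's preprocessed expression values: a map from feature ID to
#' the block-centred, duplicate-averaged log2 signal/reference ratio.
#'
#' @param array_id Array identifier.
#' @param values Named finite numeric vector, one entry per feature.
#' @return An object of class `feature_vector`.
#' @export
feature_vector <- function(array_id, values) {
  stopifnot(is.character(array_id), length(array_id) == 1L,
            is.numeric(values))
  if (length(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
      stop("feature_vector values must be named by feature ID")
    if (anyDuplicated(names(values)))
      stop("duplicate feature IDs in feature_vector")
    if (any(!is.finite(values)))
      stop("feature_vector values must be finite")
  }
  structure(list(array_id = array_id, values = values),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector '%s': %d features\n",
              x$array_id, length(x$values)))
  invisible(x)
}

#' Run the full within-array preprocessing (steps 1-5) on one array
#'
#' Background correction, exclusion flagging, reference-channel detection,
#' log-ratio computation with block-by-block median centering, and
#' duplicate averaging.
#'
#' @inheritParams apply_exclusions
#' @return A list: `vector` (the [feature_vector]), `array` (the
#'   [array_table] with final exclusion bookkeeping), `raw_ratios`
#'   (spot-level log-ratios before block centering) and `centred_ratios`.
#' @export
preprocess_array <- function(array, config = preprocess_config()) {
  array <- background_correct(array)
  array <- apply_exclusions(array, config)
  array <- detect_reference_channel(array, config)
  lr <- compute_log_ratios(array)
  centred <- center_blocks(lr$ratios)
  list(vector = average_duplicates(centred, array$array_id),
       array = lr$array,
       raw_ratios = lr$ratios,
       centred_ratios = centred)
}
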