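#' Construct an array table
#'
#' An `array_table` holds the spot-level data of one scanned two-colour
#' array together with its metadata: the source format, the channel-role
#' assignment (which channel carries the biological signal and which the
#' common reference), and whether background correction has been applied.
#'
#' The `spots` data frame has one row per physical spot with columns
#' `block`, `column`, `row` (1-based integers), `feature_id` (character,
#' whitespace-stripped), `fg1`/`fg2` (foreground intensities, channel 1
#' and 2), `bg1`/`bg2`/`bg_sd1`/`bg_sd2` (median background and background
#' standard deviation per channel; `NA` for BlueFuse, whose software
#' background-corrects internally), `flag` (the vendor flag or quality
#' code, verbatim, as character), `excluded` (logical) and
#' `exclusion_reason` (one of `"none"`, `"software_flag"`, `"empty_name"`,
#' `"background_filter"`, `"nonpositive_intensity"`).
#'
#' @param array_id Character scalar identifying the array (by convention
#'   the source file name without extension).
#' @param format `"genepix"` or `"bluefuse"`.
#' @param spots Data frame of spot records (see Details).
#' @return An object of class `array_table`.
#' @export
array_table <- function(array_id, format, spots) {
  format <- match.arg(format, c("genepix", "bluefuse"))
  stopifnot(is.character(array_id), length(array_id) == 1L, nzchar(array_id))
  needed <- c("block", "column", "row", "feature_id", "fg1", "fg2", "flag")
  missing_cols <- setdiff(needed, names(spots))
  if (length(missing_cols))
    stop("spot table lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (cc in c("bg1", "bg2", "bg_sd1", "bg_sd2"))
    if (is.null(spots[[cc]])) spots[[cc]] <- NA_real_
  for (cc in c("block", "column", "row")) spots[[cc]] <- as.integer(spots[[cc]])
  for (cc in c("fg1", "fg2", "bg1", "bg2", "bg_sd1", "bg_sd2"))
    spots[[cc]] <- as.numeric(spots[[cc]])
  if (any(spots$block < 1L) || any(spots$column < 1L) || any(spots$row < 1L))
    stop("block, column and row coordinates must be >= 1")
  key <- paste(spots$block, spots$column, spots$row)
  if (anyDuplicated(key))
    stop("duplicated (block, column, row) coordinates in array '", array_id,
         "': ", key[duplicated(key)][1L])
  if (is.null(spots$excluded)) spots$excluded <- FALSE
  if (is.null(spots$exclusion_reason)) spots$exclusion_reason <- "none"
  spots$flag <- as.character(spots$flag)
  spots$feature_id <- trimws(as.character(spots$feature_id))
  rownames(spots) <- NULL
  structure(
    list(array_id = array_id, format = format, spots = spots,
         signal_channel = NA_integer_, reference_channel = NA_integer_,
         background_corrected = FALSE),
    class = "array_table")
}

#' @export
print.array_table <- function(x, ...) {
  cat(sprintf("array_table '%s' (%s): %d spots, %d blocks\n",
              x$array_id, x$format, nrow(x$spots),
              length(unique(x$spots$block))))
  if (!is.na(x$reference_channel))
    cat(sprintf("  signal channel %d, reference channel %d\n",
                x$signal_channel, x$reference_channel))
  if (any(x$spots$excluded)) {
    tab <- table(x$spots$exclusion_reason[x$spots$excluded])
    cat("  excluded:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

# first matching column name, case-insensitive; NA if none
find_column <- function(cols, candidates) {
  for (cand in candidates) {
    hit <- which(tolower(cols) == tolower(cand))
    if (length(hit)) return(cols[hit[1L]])
  }
  NA_character_
}

# coerce a character column to numeric; informative error on failure
as_numeric_column <- function(v, colname, file) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !(is.na(v) | trimws(v) == ""))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s' at data row %d of %s",
                 v[bad[1L]], colname, bad[1L], file))
  out
}
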