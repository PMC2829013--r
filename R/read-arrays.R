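#' Detect the format of a microarray image-analysis file
#'
#' Recognises GenePix result files (GPR) by their ATF signature or by a
#' header line carrying `Block` plus `F<wavelength> Median` columns, and
#' BlueFuse output by a header line carrying the `AMPCH1`/`AMPCH2` and
#' `BLOCK`/`SUBGRIDCOL`/`SUBGRIDROW` columns.
#'
#' @param file Path to the file.
#' @return `"genepix"` or `"bluefuse"`.
#' @export
detect_array_format <- function(file) {
  lines <- readLines(file, n = 200L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("unrecognised array file format: ", file, " (file is empty)")
  if (grepl("^ATF", lines[1L])) return("genepix")
  for (ln in lines) {
    fields <- toupper(gsub('"', "", strsplit(ln, "\t", fixed = TRUE)[[1L]]))
    if (all(c("AMPCH1", "AMPCH2", "SUBGRIDROW") %in% fields))
      return("bluefuse")
    if ("BLOCK" %in% fields &&
        (any(grepl("^F.+ MEDIAN$", fields)) || "FLAGS" %in% fields))
      return("genepix")
  }
  stop("unrecognised array file format: ", file,
       " (first header line: '", substr(lines[1L], 1L, 120L), "')")
}

#' Read a GenePix result (GPR) file
#'
#' Parses the Axon Text File dialect: an optional `ATF` preamble (two
#' count lines, then that many optional header records), followed by a
#' tab-delimited spot table.  Only the coordinates (`Block`, `Column`,
#' `Row`), the feature name, the median foreground, median background and
#' background-SD columns for the first two wavelengths found in header
#' order, and the `Flags` column are read, so no gene-array-layout (.gal)
#' file is ever needed.  Channel 1 is the first wavelength encountered in
#' the header (e.g. `F635 Median` before `F532 Median` makes channel 1 the
#' 635 nm channel).  No exclusion decisions are taken at this stage; flags
#' are preserved verbatim.
#'
#' @param file Path to the GPR file.
#' @param array_id Array identifier; defaults to the file name without
#'   extension.
#' @return An [array_table] with `format = "genepix"`.
#' @export
read_genepix <- function(file, array_id = NULL) {
  if (is.null(array_id)) array_id <- tools::file_path_sans_ext(basename(file))
  lines <- readLines(file, warn = FALSE)
  if (!length(lines)) stop("empty GenePix file: ", file)
  if (grepl("^ATF", lines[1L])) {
    counts <- suppressWarnings(
      as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]))
    if (length(counts) < 2L || anyNA(counts[1:2]))
      stop("malformed ATF count line in ", file)
    header_idx <- 2L + counts[1L] + 1L
  } else {
    header_idx <- which(vapply(lines, function(ln)
      "Block" %in% gsub('"', "", strsplit(ln, "\t", fixed = TRUE)[[1L]]),
      logical(1L)))[1L]
    if (is.na(header_idx))
      stop("no GenePix column header (with 'Block') found in ", file)
  }
  tab <- utils::read.delim(
    text = paste(lines[header_idx:length(lines)], collapse = "\n"),
    check.names = FALSE, colClasses = "character", quote = "\"",
    stringsAsFactors = FALSE)
  cols <- names(tab)

  fg_cols <- grep("^F(.+) Median$", cols, value = TRUE)
  wavelengths <- sub("^F(.+) Median$", "\\1", fg_cols)
  missing_cols <- character(0)
  for (base in c("Block", "Column", "Row", "Flags"))
    if (is.na(find_column(cols, base))) missing_cols <- c(missing_cols, base)
  name_col <- find_column(cols, c("Name", "ID", "Gene"))
  if (is.na(name_col)) missing_cols <- c(missing_cols, "Name/ID")
  if (length(fg_cols) < 2L)
    missing_cols <- c(missing_cols, "two 'F<wavelength> Median' columns")
  wavelengths <- wavelengths[1:min(2L, length(wavelengths))]
  for (wl in wavelengths)
    for (pat in c("B%s Median", "B%s SD")) {
      cn <- sprintf(pat, wl)
      if (is.na(find_column(cols, cn))) missing_cols <- c(missing_cols, cn)
    }
  if (length(missing_cols))
    stop("GenePix file ", file, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))

  getn <- function(cn) as_numeric_column(tab[[find_column(cols, cn)]], cn, file)
  spots <- data.frame(
    block  = as.integer(getn("Block")),
    column = as.integer(getn("Column")),
    row    = as.integer(getn("Row")),
    feature_id = tab[[name_col]],
    fg1 = getn(sprintf("F%s Median", wavelengths[1L])),
    fg2 = getn(sprintf("F%s Median", wavelengths[2L])),
    bg1 = getn(sprintf("B%s Median", wavelengths[1L])),
    bg2 = getn(sprintf("B%s Median", wavelengths[2L])),
    bg_sd1 = getn(sprintf("B%s SD", wavelengths[1L])),
    bg_sd2 = getn(sprintf("B%s SD", wavelengths[2L])),
    flag = tab[[find_column(cols, "Flags")]],
    stringsAsFactors = FALSE)
  array_table(array_id, "genepix", spots)
}

#' Read a BlueFuse result file
#'
#' Parses tab-delimited BlueFuse image-analysis output.  An optional
#' `key<TAB>value` preamble is skipped; the data table starts at the first
#' line whose fields include `BLOCK`.  The `AMPCH1` and `AMPCH2` amplitude
#' columns are read along with `BLOCK`, `SUBGRIDCOL` and `SUBGRIDROW`; the
#' feature name is taken from the first of `NAME`/`ID`/`GENE` and the spot
#' quality letter (A-E) from the first of `FLAG`/`CONFIDENCE`/`QUALITY`.
#' BlueFuse software background-corrects internally, so the background
#' fields of the resulting spot table are absent (`NA`).  Quality letters
#' are preserved verbatim; exclusion happens downstream.
#'
#' @inheritParams read_genepix
#' @return An [array_table] with `format = "bluefuse"`.
#' @export
read_bluefuse <- function(file, array_id = NULL) {
  if (is.null(array_id)) array_id <- tools::file_path_sans_ext(basename(file))
  lines <- readLines(file, warn = FALSE)
  if (!length(lines)) stop("empty BlueFuse file: ", file)
  header_idx <- which(vapply(lines, function(ln)
    "BLOCK" %in% toupper(gsub('"', "", strsplit(ln, "\t", fixed = TRUE)[[1L]])),
    logical(1L)))[1L]
  if (is.na(header_idx))
    stop("no BlueFuse column header (with 'BLOCK') found in ", file)
  tab <- utils::read.delim(
    text = paste(lines[header_idx:length(lines)], collapse = "\n"),
    check.names = FALSE, colClasses = "character", quote = "\"",
    stringsAsFactors = FALSE)
  cols <- names(tab)

  missing_cols <- setdiff(
    c("BLOCK", "SUBGRIDCOL", "SUBGRIDROW", "AMPCH1", "AMPCH2"),
    toupper(cols))
  name_col <- find_column(cols, c("NAME", "ID", "GENE"))
  if (is.na(name_col)) missing_cols <- c(missing_cols, "NAME/ID/GENE")
  qual_col <- find_column(cols, c("FLAG", "CONFIDENCE", "QUALITY"))
  if (is.na(qual_col)) missing_cols <- c(missing_cols, "FLAG/CONFIDENCE/QUALITY")
  if (length(missing_cols))
    stop("BlueFuse file ", file, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))

  getn <- function(cn) as_numeric_column(tab[[find_column(cols, cn)]], cn, file)
  spots <- data.frame(
    block  = as.integer(getn("BLOCK")),
    column = as.integer(getn("SUBGRIDCOL")),
    row    = as.integer(getn("SUBGRIDROW")),
    feature_id = tab[[name_col]],
    fg1 = getn("AMPCH1"),
    fg2 = getn("AMPCH2"),
    flag = tab[[qual_col]],
    stringsAsFactors = FALSE)
  array_table(array_id, "bluefuse", spots)
}

#' Read a microarray file of either supported format
#'
#' Dispatches on [detect_array_format()].
#'
#' @inheritParams read_genepix
#' @return An [array_table].
#' @export
read_array <- function(file, array_id = NULL) {
  switch(detect_array_format(file),
         genepix  = read_genepix(file, array_id),
         bluefuse = read_bluefuse(file, array_id))
}
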