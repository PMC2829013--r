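# values-per-array input used by the summary functions: a named list of
# numeric vectors, or a features x arrays matrix (NAs dropped per array)
as_value_list <- function(values) {
  if (is.matrix(values)) {
    out <- lapply(seq_len(ncol(values)), function(j) {
      v <- values[, j]
      v[!is.na(v)]
    })
    names(out) <- colnames(values)
    return(out)
  }
  if (is.list(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
      stop("per-array value lists must be named by array ID")
    return(lapply(values, function(v) v[!is.na(v)]))
  }
  stop("expected a named list of numeric vectors or a matrix")
}

#' Tukey boxplot statistics per array
#'
#' For each array the median, the quartiles (linear interpolation of order
#' statistics, i.e. `quantile(type = 7)`), the whiskers (most extreme data
#' points within 1.5 x IQR of the quartiles) and the outliers (exactly the
#' points beyond the whiskers) are computed.  These are the numbers behind
#' the per-stage M-value-versus-array boxplot diagnostics.
#'
#' @param values Named list of numeric vectors (one per array) or a
#'   features x arrays matrix; `NA`s are ignored.
#' @param stage Optional stage label stored alongside the statistics.
#' @return Data frame with one row per array (`array_id`, `stage`, `n`,
#'   `median`, `q1`, `q3`, `lower_whisker`, `upper_whisker`,
#'   `n_outliers`), with attribute `outliers`: a named list of the outlier
#'   values (named by feature where names are available).
#' @export
boxplot_stats <- function(values, stage = NA_character_) {
  vals <- as_value_list(values)
  out_list <- list()
  rows <- lapply(names(vals), function(id) {
    v <- vals[[id]]
    if (!length(v)) stop("array '", id, "' has no non-missing values")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    in_fence <- v >= q[1L] - 1.5 * iqr & v <= q[3L] + 1.5 * iqr
    out_list[[id]] <<- v[!in_fence]
    data.frame(array_id = id, stage = stage, n = length(v),
               median = q[2L], q1 = q[1L], q3 = q[3L],
               lower_whisker = min(v[in_fence]),
               upper_whisker = max(v[in_fence]),
               n_outliers = sum(!in_fence),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "outliers") <- out_list
  res
}

#' MA-plot coordinates for a pair of arrays
#'
#' Over the features shared by the two arrays: `M = L_a - L_b` and
#' `A = (L_a + L_b) / 2`, where L is each array's log2 signal/reference
#' ratio.  Because `log2 sqrt(xy) = (log2 x + log2 y) / 2`, this A equals
#' the mean log intensity computed from the underlying intensity ratios.
#' These are exactly the quantities fed to [pairwise_normalise()], so
#' before/after MA-plots come from the same machinery.
#'
#' @param va,vb [feature_vector]s.
#' @return Data frame with columns `feature_id`, `A`, `M`.
#' @export
ma_plot_data <- function(va, vb) {
  stopifnot(inherits(va, "feature_vector"), inherits(vb, "feature_vector"))
  shared <- intersect(names(va$values), names(vb$values))
  if (!length(shared))
    stop("arrays '", va$array_id, "' and '", vb$array_id,
         "' share no features")
  a <- va$values[shared]
  b <- vb$values[shared]
  data.frame(feature_id = shared, A = unname((a + b) / 2),
             M = unname(a - b), stringsAsFactors = FALSE)
}

# moment-coefficient skewness g1 = m3 / m2^(3/2)
skewness_g1 <- function(v) {
  d <- v - mean(v)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^3) / m2^1.5
}

#' Per-array spread and skewness summaries
#'
#' Sample standard deviation (n - 1 denominator) and moment-coefficient
#' skewness g1 = m3 / m2^(3/2) of each array's non-missing values; the
#' numbers used to judge how comparable the arrays' M-value distributions
#' are before and after normalisation.
#'
#' @inheritParams boxplot_stats
#' @return Data frame with columns `array_id`, `n`, `sd`, `skewness`.
#' @export
distribution_stats <- function(values) {
  vals <- as_value_list(values)
  rows <- lapply(names(vals), function(id) {
    v <- vals[[id]]
    if (length(v) < 3L)
      stop("array '", id, "' has fewer than 3 non-missing values")
    data.frame(array_id = id, n = length(v), sd = stats::sd(v),
               skewness = skewness_g1(v), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Draw an MA-plot with its loess trend
#'
#' @param am Data frame from [ma_plot_data()] (columns `A`, `M`), or a
#'   `pairwise_result`.
#' @param span,robust_iterations Passed to [loess_fit()] for the trend
#'   line.
#' @param ... Further arguments to [graphics::plot()].
#' @return Invisibly, the fitted trend values.
#' @export
plot_ma <- function(am, span = 0.3, robust_iterations = 3L, ...) {
  if (inherits(am, "pairwise_result"))
    am <- data.frame(A = unname(am$A), M = unname(am$M))
  graphics::plot(am$A, am$M, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "A", ylab = "M", ...)
  graphics::abline(h = 0, lty = 2)
  trend <- loess_fit(am$A, am$M, span, robust_iterations)
  o <- order(am$A)
  graphics::lines(am$A[o], trend[o], col = "red", lwd = 2)
  invisible(trend)
}

#' Boxplot panels of M-values by array for each pipeline stage
#'
#' @param stages Named list of stages; each stage is a named list of
#'   per-array numeric vectors (or a matrix).
#' @param ... Further arguments to [graphics::boxplot()].
#' @return Invisibly, `NULL`.
#' @export
plot_stage_boxplots <- function(stages, ...) {
  old <- graphics::par(mfrow = c(length(stages), 1L),
                       mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(stages)) {
    graphics::boxplot(as_value_list(stages[[nm]]), main = nm,
                      ylab = "M", las = 2, ...)
    graphics::abline(h = 0, lty = 2, col = "grey50")
  }
  invisible(NULL)
}
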