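#' Between-array normalisation configuration
#'
#' @param span Fraction of the data included in each local loess estimate
#'   (0 < span <= 1).  Default 0.3, i.e. 30% of the shared features per
#'   local fit.
#' @param do_cyclic_loess Perform the all-pairs MA-plot loess step; when
#'   `FALSE` the preprocessed per-array values are assembled into a matrix
#'   unchanged.
#' @param do_final_centering Subtract each array's median from its column
#'   of the final matrix.
#' @param robust_iterations Number of bisquare re-weighting passes of the
#'   local regression (0 = plain tricube-weighted fit).
#' @param min_pair_size Minimum number of shared features for a pairwise
#'   loess fit; smaller intersections are skipped with a warning and
#'   contribute no comparisons.
#' @return An object of class `cyclic_config`.
#' @export
cyclic_config <- function(span = 0.3,
                          do_cyclic_loess = TRUE,
                          do_final_centering = TRUE,
                          robust_iterations = 3L,
                          min_pair_size = 10L) {
  stopifnot(is.numeric(span), length(span) == 1L, span > 0, span <= 1,
            robust_iterations >= 0L, min_pair_size >= 2L)
  structure(list(span = span,
                 do_cyclic_loess = isTRUE(do_cyclic_loess),
                 do_final_centering = isTRUE(do_final_centering),
                 robust_iterations = as.integer(robust_iterations),
                 min_pair_size = as.integer(min_pair_size)),
            class = "cyclic_config")
}

#' Locally weighted regression trend
#'
#' Degree-1 locally weighted regression (tricube weights over the
#' span-fraction nearest neighbours of each point, with optional bisquare
#' robustifying passes), evaluated at each input `x`.  This is the
#' smoother used on MA-plots; it reproduces any affine trend exactly, and
#' returns the constant `mean(y)` when all `x` coincide.
#'
#' The fit is delegated to [stats::lowess()] (with `delta = 0`, i.e. an
#' exact fit at every point) and mapped back to the input order.  When the
#' plain fit already interpolates the data to within numerical noise the
#' robustifying passes are skipped: with all residuals at rounding level
#' the bisquare weights would be determined by noise alone and can
#' destabilise the fit.
#'
#' @param x,y Numeric vectors of equal length.
#' @param span Neighbourhood fraction in (0, 1].
#' @param robust_iterations Bisquare re-weighting passes (>= 0).
#' @return Numeric vector of fitted values, aligned with `x`.
#' @export
loess_fit <- function(x, y, span = 0.3, robust_iterations = 3L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L, span > 0, span <= 1)
  if (anyNA(x) || anyNA(y)) stop("loess_fit does not accept missing values")
  if (all(x == x[1L])) return(rep(mean(y), n))
  o <- order(x)
  fit <- numeric(n)
  base <- stats::lowess(x, y, f = span, iter = 0L, delta = 0)$y
  fit[o] <- base
  if (robust_iterations > 0L) {
    tol <- 1e-10 * max(1, max(abs(y)))
    if (max(abs(y - fit)) > tol)
      fit[o] <- stats::lowess(x, y, f = span, iter = robust_iterations,
                              delta = 0)$y
  }
  fit
}

#' Loess-normalise one pair of arrays (step 6)
#'
#' Over the features shared by the two arrays, the pairwise M and A values
#' are formed from the per-array log-ratios L = log2(signal/reference):
#' `M = L_a - L_b` (the log-ratio of expression between the two
#' conditions) and `A = (L_a + L_b) / 2` (the mean log intensity).  The
#' loess trend of M on A is subtracted, giving the normalised log2-ratio
#' `N_ab = M - loess(A)`.  The reverse orientation is defined as
#' `N_ba = -N_ab` and is never refitted.
#'
#' @param va,vb [feature_vector]s of the two arrays.
#' @param config A [cyclic_config].
#' @return A `pairwise_result` (list with `array_a`, `array_b`,
#'   `features`, `M`, `A`, `N_ab`), or `NULL` with a warning when fewer
#'   than `min_pair_size` features are shared.
#' @export
pairwise_normalise <- function(va, vb, config = cyclic_config()) {
  stopifnot(inherits(va, "feature_vector"), inherits(vb, "feature_vector"))
  shared <- intersect(names(va$values), names(vb$values))
  if (length(shared) < config$min_pair_size) {
    warning(sprintf(
      "pair (%s, %s) shares only %d feature(s) (< %d); pair skipped",
      va$array_id, vb$array_id, length(shared), config$min_pair_size))
    return(NULL)
  }
  a <- va$values[shared]
  b <- vb$values[shared]
  M <- a - b
  A <- (a + b) / 2
  N <- M - loess_fit(A, M, span = config$span,
                     robust_iterations = config$robust_iterations)
  structure(list(array_a = va$array_id, array_b = vb$array_id,
                 features = shared, M = M, A = A, N_ab = N),
            class = "pairwise_result")
}

#' Cyclic loess normalisation across all array pairs (steps 6-7)
#'
#' Runs [pairwise_normalise()] on every unordered pair of arrays (k arrays
#' give k(k-1)/2 loess fits) and averages, for each array `a` and feature
#' `f`, the normalised log-ratios over all pairs `(a, b)` in which `f` was
#' present on both arrays, using `N_ab = -N_ba` for the reverse
#' orientation.  A cell whose feature took part in no pairwise comparison
#' involving that array (`n = 0`) is `NA` — including features present on
#' the array but shared with no fitted partner.
#'
#' Each pair is fitted once, in canonical orientation (lexicographically
#' smaller array ID first), and per-array contributions are accumulated in
#' sorted-partner order, so the result is invariant — bit for bit — to the
#' order in which the arrays are supplied (columns follow input order;
#' rows are sorted by feature ID).
#'
#' With `do_cyclic_loess = FALSE` the input vectors are assembled into the
#' matrix unchanged (the union of features, absences as `NA`).
#'
#' @param vectors List of [feature_vector]s (>= 2, unique array IDs).
#' @param config A [cyclic_config].
#' @return Numeric matrix (features x arrays) of normalised log2-ratios,
#'   with attributes `pairs` (data frame logging every pair: canonical
#'   IDs, number of shared features, whether it was fitted) and `n_fits`
#'   (count of loess fits performed).
#' @export
cyclic_normalise <- function(vectors, config = cyclic_config()) {
  k <- length(vectors)
  if (k < 2L) stop("cyclic normalisation needs at least 2 arrays")
  stopifnot(all(vapply(vectors, inherits, logical(1L), "feature_vector")))
  ids <- vapply(vectors, `[[`, character(1L), "array_id")
  if (anyDuplicated(ids)) stop("array IDs must be unique")
  feats <- sort(unique(unlist(lapply(vectors,
                                     function(v) names(v$values)))))
  if (!config$do_cyclic_loess) {
    mat <- matrix(NA_real_, length(feats), k, dimnames = list(feats, ids))
    for (i in seq_len(k))
      mat[names(vectors[[i]]$values), i] <- vectors[[i]]$values
    attr(mat, "pairs") <- data.frame(array_a = character(0),
                                     array_b = character(0),
                                     n_shared = integer(0),
                                     fitted = logical(0))
    attr(mat, "n_fits") <- 0L
    return(mat)
  }

  # contrib[[i]][[partner id]] = named N vector oriented ids[i]-over-partner
  contrib <- rep(list(list()), k)
  pair_log <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      canon <- ids[i] <= ids[j]
      first <- if (canon) i else j
      second <- if (canon) j else i
      pr <- withCallingHandlers(
        pairwise_normalise(vectors[[first]], vectors[[second]], config),
        warning = function(w) invokeRestart("muffleWarning"))
      n_shared <- length(intersect(names(vectors[[i]]$values),
                                   names(vectors[[j]]$values)))
      pair_log[[length(pair_log) + 1L]] <-
        data.frame(array_a = ids[first], array_b = ids[second],
                   n_shared = n_shared, fitted = !is.null(pr))
      if (is.null(pr)) {
        message(sprintf(
          "pair (%s, %s) shares only %d feature(s); skipped",
          ids[first], ids[second], n_shared))
        next
      }
      contrib[[first]][[ids[second]]] <- pr$N_ab
      contrib[[second]][[ids[first]]] <- -pr$N_ab
    }
  }

  sums <- matrix(0, length(feats), k, dimnames = list(feats, ids))
  counts <- matrix(0L, length(feats), k, dimnames = list(feats, ids))
  for (i in seq_len(k)) {
    for (partner in sort(names(contrib[[i]]))) {
      N <- contrib[[i]][[partner]]
      f <- names(N)
      sums[f, i] <- sums[f, i] + N
      counts[f, i] <- counts[f, i] + 1L
    }
  }
  mat <- sums / counts
  mat[counts == 0L] <- NA_real_
  pairs <- do.call(rbind, pair_log)
  attr(mat, "pairs") <- pairs
  attr(mat, "n_fits") <- sum(pairs$fitted)
  mat
}

#' Centre each array's median at zero (step 8)
#'
#' Subtracts from every non-missing value of each array (column) the
#' median of that array's non-missing values, so that after the correction
#' each array's median log2-ratio is exactly 0 — the final expression of
#' the majority-unchanged assumption.
#'
#' @param mat Numeric matrix, features x arrays, `NA` allowed.
#' @return The centred matrix (attributes preserved).
#' @export
center_arrays <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  empty <- colSums(!is.na(mat)) == 0L
  if (any(empty))
    stop("array(s) with no non-missing values: ",
         paste(colnames(mat)[empty], collapse = ", "))
  meds <- apply(mat, 2L, stats::median, na.rm = TRUE)
  mat - rep(meds, each = nrow(mat))
}
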