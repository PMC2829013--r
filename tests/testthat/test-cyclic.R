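test_that("identical or constant-offset arrays normalise to zero", {
  v <- make_vectors(2)
  same <- pairwise_normalise(v[[1]], v[[1]])
  # identical arrays: M is identically zero, so is N
  expect_equal(max(abs(same$N_ab)), 0)

  off <- feature_vector("arrB", v[[1]]$values + 0.7)
  pr <- pairwise_normalise(v[[1]], off)
  expect_equal(unname(pr$M), rep(-0.7, 40))
  expect_equal(max(abs(pr$N_ab)), 0, tolerance = 1e-12)
})

test_that("the reverse comparison is the exact negation (antisymmetry)", {
  set.seed(21)
  v <- make_vectors(2, n_features = 120)
  # make the arrays genuinely different
  v[[2]] <- feature_vector("arr02",
                           v[[2]]$values * 1.6 + rnorm(120, 0, 0.3))
  ab <- pairwise_normalise(v[[1]], v[[2]])
  ba <- pairwise_normalise(v[[2]], v[[1]])   # independent refit
  expect_equal(ab$N_ab[ab$features] + ba$N_ab[ab$features],
               setNames(rep(0, 120), ab$features), tolerance = 1e-12)
})

test_that("k arrays trigger exactly k(k-1)/2 pairwise fits", {
  for (k in c(3, 5)) {
    mat <- cyclic_normalise(make_vectors(k))
    expect_identical(attr(mat, "n_fits"), as.integer(k * (k - 1) / 2))
  }
})

test_that("three-array averaging follows the n = 2 / n = 1 / NA rule", {
  set.seed(31)
  feats <- sprintf("f%03d", 1:30)
  La <- feature_vector("a", setNames(rnorm(31), c(feats, "only_ab")))
  Lb <- feature_vector("b", setNames(rnorm(31), c(feats, "only_ab")))
  Lc <- feature_vector("c", setNames(rnorm(30), feats))
  cfg <- cyclic_config()
  mat <- cyclic_normalise(list(La, Lb, Lc), cfg)

  # independent recomputation from single pairwise fits
  Nab <- pairwise_normalise(La, Lb, cfg)$N_ab
  Nac <- pairwise_normalise(La, Lc, cfg)$N_ab
  Nbc <- pairwise_normalise(Lb, Lc, cfg)$N_ab

  f <- feats[1]  # present on all three arrays: n = 2
  expect_equal(mat[f, "a"], unname((Nab[f] + Nac[f]) / 2))
  expect_equal(mat[f, "b"], unname((-Nab[f] + Nbc[f]) / 2))
  expect_equal(mat[f, "c"], unname((-Nac[f] - Nbc[f]) / 2))

  # present only on a and b: n = 1 there, NA on c
  expect_equal(mat["only_ab", "a"], unname(Nab["only_ab"]))
  expect_equal(mat["only_ab", "b"], unname(-Nab["only_ab"]))
  expect_true(is.na(mat["only_ab", "c"]))
})

test_that("cell counts match a brute-force census of shared features", {
  set.seed(17)
  k <- 5
  pool <- sprintf("g%03d", 1:60)
  vectors <- lapply(seq_len(k), function(i) {
    feats <- sort(sample(pool, 40))
    feature_vector(sprintf("arr%d", i),
                   setNames(rnorm(40), feats))
  })
  mat <- cyclic_normalise(vectors)
  present <- sapply(vectors, function(v) pool %in% names(v$values))
  rownames(present) <- pool
  for (i in seq_len(k)) {
    n_bf <- rowSums(present & present[, i])[rownames(mat)] -
      present[rownames(mat), i]
    # a cell is NA exactly when the feature joined no pair for that array
    expect_identical(unname(is.na(mat[, i])), unname(n_bf == 0))
  }
})

test_that("permuting the input arrays permutes columns but not values", {
  set.seed(23)
  v <- make_vectors(4, n_features = 50)
  v <- lapply(v, function(x)
    feature_vector(x$array_id, x$values + rnorm(50, 0, 0.2)))
  m1 <- cyclic_normalise(v)
  perm <- c(3, 1, 4, 2)
  m2 <- cyclic_normalise(v[perm])
  # values and dimnames agree bit-for-bit; only the fit log, whose row
  # order follows the input order, is allowed to differ
  m2s <- m2
  attr(m2s, "pairs") <- NULL
  attr(m2s, "n_fits") <- NULL
  expect_identical(m2s, m1[, colnames(m2)])
})

test_that("pairs sharing too few features are skipped, not fitted", {
  v <- make_vectors(2, n_features = 40)
  lonely <- feature_vector("zz", setNames(rnorm(5), sprintf("q%d", 1:5)))
  expect_warning(pairwise_normalise(v[[1]], lonely), "skipped")
  mat <- suppressMessages(cyclic_normalise(c(v, list(lonely))))
  expect_identical(attr(mat, "n_fits"), 1L)   # only arr01-arr02 fitted
  expect_true(all(is.na(mat[sprintf("q%d", 1:5), c("arr01", "arr02")])))
  expect_true(all(is.na(mat[, "zz"])))        # n = 0 everywhere for zz
})

test_that("disabling cyclic loess assembles the vectors unchanged", {
  v <- make_vectors(3)
  v[[3]] <- feature_vector("arr03", v[[3]]$values[1:20])
  mat <- cyclic_normalise(v, cyclic_config(do_cyclic_loess = FALSE))
  expect_identical(attr(mat, "n_fits"), 0L)
  expect_equal(mat[names(v[[1]]$values), "arr01"], v[[1]]$values)
  expect_true(all(is.na(mat[setdiff(rownames(mat),
                                    names(v[[3]]$values)), "arr03"])))
})

test_that("final centering zeroes each array median and respects NAs", {
  m <- cbind(a = c(1, 2, 3), b = c(0.5, NA, 1.5))
  rownames(m) <- c("f1", "f2", "f3")
  cc <- center_arrays(m)
  expect_equal(unname(cc[, "a"]), c(-1, 0, 1))
  expect_equal(unname(cc[, "b"]), c(-0.5, NA, 0.5))
  expect_identical(center_arrays(cc), cc)       # idempotent
  m2 <- m; m2[, 2] <- NA
  expect_error(center_arrays(m2), "b")

  set.seed(4)
  big <- matrix(rnorm(600, 1, 2), 100, 6,
                dimnames = list(sprintf("g%d", 1:100), letters[1:6]))
  big[sample(600, 30)] <- NA
  meds <- apply(center_arrays(big), 2, median, na.rm = TRUE)
  expect_true(all(abs(meds) < 1e-12))
})

test_that("normalised values vary smoothly with the span setting", {
  sim <- simulate_dataset(sim_config(n_arrays = 2, n_genes = 400,
                                     preset = "problem", seed = 4))
  pp <- lapply(sim$arrays, preprocess_array)
  spans <- seq(0.2, 0.5, 0.1)
  Ns <- sapply(spans, function(s)
    unname(pairwise_normalise(pp[[1]]$vector, pp[[2]]$vector,
                              cyclic_config(span = s))$N_ab))
  for (i in seq_len(length(spans) - 1L)) {
    expect_lt(max(abs(Ns[, i] - Ns[, i + 1])), 0.2)
    expect_gt(cor(Ns[, i], Ns[, i + 1]), 0.99)
  }
})
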