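make_table <- function(df, format = "genepix", id = "arr") {
  if (format == "genepix")
    spots <- data.frame(block = df$block, column = df$column, row = df$row,
                        feature_id = df$name, fg1 = df$f1, fg2 = df$f2,
                        bg1 = df$b1, bg2 = df$b2, bg_sd1 = df$bsd1,
                        bg_sd2 = df$bsd2, flag = df$flag,
                        stringsAsFactors = FALSE)
  else
    spots <- data.frame(block = df$block, column = df$column, row = df$row,
                        feature_id = df$name, fg1 = df$f1, fg2 = df$f2,
                        flag = df$flag, stringsAsFactors = FALSE)
  array_table(id, format, spots)
}

simple_spots <- function(...) {
  base <- data.frame(block = 1L, column = 1L, row = 1L, name = "g1",
                     f1 = 1000, b1 = 100, bsd1 = 10, f2 = 800, b2 = 50,
                     bsd2 = 10, flag = "0", stringsAsFactors = FALSE)
  over <- list(...)
  n <- max(1L, vapply(over, length, integer(1L)))
  out <- base[rep(1L, n), ]
  out$column <- seq_len(n)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  rownames(out) <- NULL
  out
}

test_that("background correction subtracts medians for GenePix only", {
  arr <- background_correct(make_table(simple_spots()))
  expect_equal(arr$spots$fg1, 900)
  expect_equal(arr$spots$fg2, 750)
  expect_equal(arr$spots$raw_fg1, 1000)

  neg <- background_correct(make_table(simple_spots(f1 = 90, f2 = 500)))
  expect_equal(neg$spots$fg1, -10)   # subtraction may go negative
  expect_equal(neg$spots$fg2, 450)

  bf <- make_table(data.frame(block = 1, column = 1, row = 1, name = "g1",
                              f1 = 400, f2 = 300, flag = "A"), "bluefuse")
  expect_equal(background_correct(bf)$spots$fg1, 400)  # pass-through
  # idempotent: correcting twice is the same as once
  expect_identical(background_correct(arr)$spots, arr$spots)
})

test_that("exclusion rules match the vendor flag, name and filter cases", {
  df <- simple_spots(
    name = c("g1", "ctrl-spike7", "g3", "g4", "EMPTY", "EMPTYx", "Ctrl-1"),
    f1   = c(2000, 2000, 2000, 400, 2000, 2000, 2000),
    b1   = c(100, 100, 100, 100, 100, 100, 100),
    bsd1 = c(10, 10, 10, 110, 10, 10, 10),
    flag = c("0", "0", "-75", "0", "0", "0", "0"))
  arr <- apply_exclusions(background_correct(make_table(df)),
                          preprocess_config(k_sd = 3))
  reasons <- arr$spots$exclusion_reason
  expect_identical(reasons[1], "none")
  expect_identical(reasons[2], "empty_name")        # prefix 'ctrl-'
  expect_identical(reasons[3], "software_flag")     # -75 = 'absent'
  expect_identical(reasons[4], "background_filter") # 400 < 100 + 3*110
  expect_identical(reasons[5], "empty_name")        # exact 'EMPTY'
  expect_identical(reasons[6], "none")              # exact match only
  expect_identical(reasons[7], "empty_name")        # prefix 'Ctrl-'
  expect_identical(arr$spots$excluded, reasons != "none")

  bf <- make_table(data.frame(block = 1, column = 1:2, row = 1,
                              name = c("g1", "g2"), f1 = c(100, 100),
                              f2 = c(50, 50), flag = c("E", "A")),
                   "bluefuse")
  bf <- apply_exclusions(background_correct(bf))
  expect_identical(bf$spots$exclusion_reason, c("software_flag", "none"))
})

test_that("raising the background-filter width never un-excludes a spot", {
  set.seed(7)
  df <- gpr_spots(40)
  df$f1 <- round(runif(40, 80, 500))
  df$f2 <- round(runif(40, 80, 500))
  arr <- background_correct(make_table(df))
  prev <- rep(FALSE, 40)
  for (k in c(0.5, 1, 2, 3, 5, 10)) {
    cur <- apply_exclusions(arr, preprocess_config(k_sd = k))$spots$excluded
    expect_true(all(cur[prev]))   # monotone in k_sd
    prev <- cur
  }
})

test_that("reference channel detection follows the higher median and
           handles dye swaps and ties", {
  df <- simple_spots(f1 = c(5100, 5050, 4900), f2 = c(900, 850, 800),
                     name = c("g1", "g2", "g3"), b1 = 0, b2 = 0,
                     bsd1 = 0, bsd2 = 0)
  arr <- detect_reference_channel(
    apply_exclusions(background_correct(make_table(df))))
  expect_identical(arr$reference_channel, 1L)
  expect_identical(arr$signal_channel, 2L)

  swap <- df
  swap[c("f1", "f2")] <- swap[c("f2", "f1")]
  arr2 <- detect_reference_channel(
    apply_exclusions(background_correct(make_table(swap))))
  expect_identical(arr2$reference_channel, 2L)

  tie <- simple_spots(f1 = c(100, 200), f2 = c(200, 100),
                      name = c("g1", "g2"), b1 = 0, b2 = 0,
                      bsd1 = 0, bsd2 = 0)
  expect_error(detect_reference_channel(
    apply_exclusions(background_correct(make_table(tie)))),
    "fixed_reference_channel")

  fixed <- detect_reference_channel(
    apply_exclusions(background_correct(make_table(df))),
    preprocess_config(auto_reference = FALSE, fixed_reference_channel = 2))
  expect_identical(fixed$reference_channel, 2L)
})

test_that("log-ratios are log2(signal/reference) with nonpositive spots
           excluded", {
  # BlueFuse amplitudes are already background-corrected, so a negative
  # amplitude reaches the log-ratio step and is excluded there
  df <- data.frame(block = 1L, column = 1:3, row = 1L,
                   name = c("gA", "gB", "gC"),
                   f1 = c(400, 400, 400), f2 = c(800, 400, -10),
                   flag = "A", stringsAsFactors = FALSE)
  arr <- make_table(df, "bluefuse")
  arr <- background_correct(arr)
  arr <- apply_exclusions(arr)
  arr$signal_channel <- 2L       # signal 800/400/-10, reference 400
  arr$reference_channel <- 1L
  out <- compute_log_ratios(arr)
  expect_equal(out$ratios$ratio, c(1, 0))
  expect_identical(out$array$spots$exclusion_reason[3],
                   "nonpositive_intensity")
})

test_that("block centering zeroes every block median independently", {
  r <- data.frame(feature_id = letters[1:3], block = 1L, ratio = c(1, 2, 3))
  expect_equal(center_blocks(r)$ratio, c(-1, 0, 1))
  expect_equal(center_blocks(data.frame(feature_id = "a", block = 1L,
                                        ratio = 5))$ratio, 0)
  two <- data.frame(feature_id = letters[1:6],
                    block = rep(1:2, each = 3),
                    ratio = c(0, 0, 4, 10, 10, 10))
  expect_equal(center_blocks(two)$ratio, c(0, 0, 4, 0, 0, 0))

  set.seed(5)
  big <- data.frame(feature_id = sprintf("g%d", 1:200),
                    block = sample(1:8, 200, TRUE),
                    ratio = rnorm(200, 2, 3))
  cc <- center_blocks(big)
  meds <- tapply(cc$ratio, cc$block, median)
  expect_true(all(abs(meds) < 1e-12))
})

test_that("duplicate features are averaged to one entry per feature", {
  r <- data.frame(feature_id = c("X", "X", "Y"), block = 1L,
                  ratio = c(1, 3, 0.7))
  fv <- average_duplicates(r, "a1")
  expect_s3_class(fv, "feature_vector")
  expect_equal(fv$values[["X"]], 2)
  expect_equal(fv$values[["Y"]], 0.7)
  expect_identical(length(fv$values), 2L)
})

test_that("fully excluded features are absent from the feature vector", {
  df <- simple_spots(name = c("g1", "gone", "gone"),
                     flag = c("0", "-50", "-100"))
  pp <- preprocess_array(make_table(df))
  expect_false("gone" %in% names(pp$vector$values))
  expect_true("g1" %in% names(pp$vector$values))
})

test_that("swapping the channel columns of an input file leaves the
           preprocessed vectors identical", {
  df <- gpr_spots(24, seed = 11)
  swapped <- df
  swapped[c("f1", "b1", "bsd1", "f2", "b2", "bsd2")] <-
    df[c("f2", "b2", "bsd2", "f1", "b1", "bsd1")]
  v1 <- preprocess_array(read_genepix(
    write_fixture(make_gpr(df), ".gpr"), "a"))$vector
  v2 <- preprocess_array(read_genepix(
    write_fixture(make_gpr(swapped), ".gpr"), "a"))$vector
  expect_identical(v1$values, v2$values)  # bit-for-bit dye-swap invariance
})
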