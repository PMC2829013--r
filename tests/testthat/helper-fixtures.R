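# in-code fixture builders for the two vendor dialects, plus independent
# numerical oracles used against the package's own implementations

# GenePix GPR/ATF text from a spot table.  `df` columns: block, column,
# row, name, f1, b1, bsd1, f2, b2, bsd2, flag; channel 1 is the first
# wavelength in `wavelengths`.
make_gpr <- function(df, wavelengths = c("635", "532"), atf = TRUE,
                     quote_header = TRUE) {
  hdr <- c("Block", "Column", "Row", "Name",
           sprintf("F%s Median", wavelengths[1]),
           sprintf("B%s Median", wavelengths[1]),
           sprintf("B%s SD", wavelengths[1]),
           sprintf("F%s Median", wavelengths[2]),
           sprintf("B%s Median", wavelengths[2]),
           sprintf("B%s SD", wavelengths[2]),
           "Flags")
  if (quote_header) hdr <- sprintf('"%s"', hdr)
  body <- paste(df$block, df$column, df$row, sprintf('"%s"', df$name),
                df$f1, df$b1, df$bsd1, df$f2, df$b2, df$bsd2, df$flag,
                sep = "\t")
  lines <- c(paste(hdr, collapse = "\t"), body)
  if (atf)
    lines <- c("ATF\t1.0", paste(1L, length(hdr), sep = "\t"),
               '"Type=GenePix Results 3"', lines)
  lines
}

# BlueFuse text; `df` columns: block, column, row, name, amp1, amp2, flag
make_bluefuse <- function(df, preamble = TRUE) {
  body <- paste(df$block, df$column, df$row, df$name, df$amp1, df$amp2,
                df$flag, sep = "\t")
  lines <- c(paste(c("BLOCK", "SUBGRIDCOL", "SUBGRIDROW", "NAME",
                     "AMPCH1", "AMPCH2", "FLAG"), collapse = "\t"),
             body)
  if (preamble)
    lines <- c("Software\tBlueFuse fixture", "Version\t0", lines)
  lines
}

write_fixture <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# default spot table for a tiny well-behaved GenePix array
gpr_spots <- function(n = 12, names = sprintf("g%02d", seq_len(n)),
                      seed = 1) {
  set.seed(seed)
  data.frame(block = rep(1:2, length.out = n),
             column = rep(1:3, length.out = n),
             row = rep(seq_len(ceiling(n / 6)), each = 6)[seq_len(n)],
             name = names,
             f1 = round(2000 + 500 * stats::rexp(n)),
             b1 = round(stats::rnorm(n, 100, 5)),
             bsd1 = rep(10, n),
             f2 = round(6000 + 500 * stats::rexp(n)),
             b2 = round(stats::rnorm(n, 110, 5)),
             bsd2 = rep(10, n),
             flag = rep("0", n),
             stringsAsFactors = FALSE)
}

# brute-force pointwise tricube-weighted local linear regression (the
# non-robust loess oracle): span-fraction nearest neighbours of each x,
# tricube weights, degree-1 weighted least squares evaluated at x_i
oracle_loess <- function(x, y, f) {
  n <- length(x)
  ns <- max(2L, min(n, floor(f * n + 1e-7)))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    dmax <- sort(d, partial = ns)[ns]
    keep <- d <= dmax          # all points tied at the boundary included
    w <- (1 - pmin(1, d[keep] / max(dmax, 1e-300))^3)^3
    xx <- x[keep]; yy <- y[keep]
    sw <- sum(w)
    xm <- sum(w * xx) / sw
    ym <- sum(w * yy) / sw
    vx <- sum(w * (xx - xm)^2)
    if (vx <= 1e-12 * sum(w * xx^2)) ym
    else ym + sum(w * (xx - xm) * (yy - ym)) / vx * (x[i] - xm)
  }, numeric(1))
}

# direct-moment skewness oracle
oracle_skewness <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m3 / m2^1.5
}

# deterministic feature vectors sharing a common feature pool
make_vectors <- function(k, n_features = 40, seed = 99,
                         ids = sprintf("arr%02d", seq_len(k))) {
  set.seed(seed)
  feats <- sprintf("f%03d", seq_len(n_features))
  lapply(seq_len(k), function(i)
    feature_vector(ids[i],
                   stats::setNames(stats::rnorm(n_features, 0, 1), feats)))
}
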