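test_that("reference construction takes per-sequence medians over the common set", {
  m <- matrix(c(4, 8,
                2, 0,
                3, 5), ncol = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  ref <- build_reference(m)
  # s2 is absent from sample b and excluded from the common set
  expect_setequal(ref$sequences, c("s1", "s3"))
  expect_equal(unname(ref$ref_copy["s1"]), 6)  # even count: mean of middles

  m3 <- matrix(c(2, 4, 100), nrow = 1,
               dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(build_reference(m3)$ref_copy["s1"]), 4)

  empty <- matrix(c(1, 0, 0, 1), 2,
                  dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(build_reference(empty), "stringency")
})

test_that("a sample identical to the reference fits a=1, b=0, f=1", {
  set.seed(61)
  counts <- round(exp(rnorm(50, log(200), 1))) + 1
  m <- matrix(rep(counts, 2), ncol = 2,
              dimnames = list(sprintf("s%02d", 1:50), c("a", "b")))
  ref <- build_reference(m)
  fit <- fit_sample(setNames(m[, 1], rownames(m)), ref)
  expect_equal(fit$a, 1, tolerance = 1e-12)
  expect_equal(fit$b, 0, tolerance = 1e-12)
  expect_equal(fit$f, 1, tolerance = 1e-12)
})

test_that("a uniformly doubled sample fits a=1, b=1, f=0.5 and corrects back", {
  base <- c(8, 16, 32, 64, 128)
  m <- matrix(c(base, 2 * base), ncol = 2,
              dimnames = list(paste0("s", 1:5), c("a", "b")))
  ref <- build_reference(m)
  fit <- fit_sample(setNames(m[, "b"], rownames(m)), ref)
  # reference median of (x, 2x) is 1.5x; the offset is log2(2/1.5)
  expect_equal(fit$a, 1, tolerance = 1e-12)
  expect_equal(fit$b, log2(2 / 1.5), tolerance = 1e-12)
  expect_equal(fit$f, 1.5 / 2, tolerance = 1e-12)
  corrected <- m[, "b"] * fit$f
  expect_equal(unname(corrected), unname(ref$ref_copy))

  # against an explicitly given reference the offset is a full log2 unit
  ref2 <- list(sequences = paste0("s", 1:5),
               ref_copy = setNames(base, paste0("s", 1:5)))
  fit2 <- fit_sample(setNames(2 * base, paste0("s", 1:5)), ref2)
  expect_equal(fit2$a, 1, tolerance = 1e-12)
  expect_equal(fit2$b, 1, tolerance = 1e-12)
  expect_equal(fit2$f, 0.5, tolerance = 1e-12)
})

test_that("hand-computed OLS on a 5-point fixture matches fit_sample in both x_mid modes", {
  ref <- list(sequences = paste0("s", 1:5),
              ref_copy = setNames(c(10, 20, 40, 80, 160), paste0("s", 1:5)))
  y_counts <- setNames(c(12, 25, 35, 100, 140), paste0("s", 1:5))
  x <- log2(ref$ref_copy)
  y <- log2(y_counts)
  sxx <- sum((x - mean(x))^2)
  a_hand <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b_hand <- mean(y) - a_hand * mean(x)
  for (mode in c("midpoint", "half_range")) {
    fit <- fit_sample(y_counts, ref, xmid_mode = mode)
    expect_equal(fit$a, a_hand, tolerance = 1e-12)
    expect_equal(fit$b, b_hand, tolerance = 1e-12)
    xm <- if (mode == "midpoint") (max(x) + min(x)) / 2 else
      (max(x) - min(x)) / 2
    expect_equal(fit$f, 2^(xm - (a_hand * xm + b_hand)),
                 tolerance = 1e-12)
  }
})

test_that("a log-linear distortion (copy^1.5) recovers slope 1.5 on a noiseless fixture", {
  refv <- 2^seq(4, 10, length.out = 20)
  m <- matrix(c(refv, refv, refv^1.5 / 2^6), ncol = 3,
              dimnames = list(paste0("s", 1:20), c("a", "b", "c")))
  # wide subset window: the distortion itself must not be clipped
  fit <- fit_sample(setNames(m[, "c"], rownames(m)),
                    list(sequences = rownames(m),
                         ref_copy = setNames(refv, rownames(m))),
                    subset_window = 10)
  expect_equal(fit$a, 1.5, tolerance = 1e-10)
})

test_that("scalar-multiple samples recover f = 1/c for any positive c", {
  set.seed(62)
  # scalars must stay within the 4-fold concordance window of their
  # median: step 5 excludes anything farther by construction
  prof <- round(exp(rnorm(200, log(100), 1.2))) + 4
  cs <- c(0.3, 0.5, 1, 2, 3.5)
  m <- sapply(cs, function(c) prof * c)
  rownames(m) <- sprintf("s%03d", seq_along(prof))
  colnames(m) <- paste0("lib", seq_along(cs))
  res <- normalize_matrix(m)
  f <- vapply(res$fits, `[[`, numeric(1), "f")
  expect_equal(unname(f), 1 / cs, tolerance = 1e-9)
  # all samples land on the common profile
  for (j in seq_along(cs)) {
    expect_equal(unname(res$normalized[, j]), unname(prof),
                 tolerance = 1e-9)
  }
})

test_that("normalization is idempotent on noiseless fixtures", {
  set.seed(63)
  prof <- round(exp(rnorm(100, log(80), 1))) + 1
  m <- sapply(c(0.5, 1, 2), function(c) prof * c)
  rownames(m) <- sprintf("s%03d", seq_along(prof))
  colnames(m) <- c("a", "b", "c")
  once <- normalize_matrix(m)$normalized
  twice <- normalize_matrix(once)
  f2 <- vapply(twice$fits, `[[`, numeric(1), "f")
  expect_true(all(abs(log2(f2)) < 1e-6))
})

test_that("wildly discordant sequences are excluded by the subset rule", {
  set.seed(64)
  x <- 2^seq(3, 9, length.out = 80)
  ref <- list(sequences = sprintf("s%02d", 1:80),
              ref_copy = setNames(x, sprintf("s%02d", 1:80)))
  clean <- setNames(x * 2, names(ref$ref_copy))  # uniform doubling
  fit_clean <- fit_sample(clean, ref)
  # corrupt < 25% of sequences by >= 4-fold discordance
  dirty <- clean
  idx <- sample(80, 18)
  dirty[idx] <- dirty[idx] * ifelse(seq_along(idx) %% 2 == 0, 8, 1 / 8)
  fit_dirty <- fit_sample(dirty, ref)
  expect_equal(fit_dirty$a, fit_clean$a, tolerance = 1e-9)
  expect_equal(fit_dirty$b, fit_clean$b, tolerance = 1e-9)
  expect_equal(fit_dirty$n_subset, 80 - 18)
})

test_that("applying factors is linear, keeps zeros and scales column sums", {
  m <- matrix(c(0, 8, 4, 0, 2, 6), ncol = 2,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  fits <- list(a = list(f = 1), b = list(f = 0.5))
  out <- apply_normalization(m, fits)
  expect_equal(out["s2", "a"], 8)
  expect_equal(out["s2", "b"], 1)
  expect_equal(out["s1", "a"], 0)
  expect_equal(colSums(out), colSums(m) * c(a = 1, b = 0.5))
})

test_that("RPM scaling divides by library totals and errors on zero totals", {
  m <- matrix(c(10, 20), ncol = 2,
              dimnames = list("s1", c("a", "b")))
  out <- rpm(m, c(a = 1e6, b = 2e6))
  expect_equal(unname(out["s1", ]), c(10, 10))
  expect_error(rpm(m, c(a = 0, b = 1)), "positive")
  # proportional invariance under uniform count scaling
  expect_equal(rpm(m * 5, c(a = 5e6, b = 1e7)), out)
})
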