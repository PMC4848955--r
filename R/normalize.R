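# Median-reference regression normalization of copy numbers:
# (1) common sequence set across samples, (2) per-sequence median
# reference, (3-5) log2 transform and |delta log2| < 2 subset,
# (6) per-sample OLS against the reference, (7) correction factor from
# the regression at the reference mid value, (8) multiplicative
# correction of all raw counts.

#' Build the median reference set from a raw count matrix
#'
#' @param mat numeric matrix, sequences x samples, raw copy numbers.
#' @return list with `sequences` (rownames of the common set: count
#'   >= 1 in every sample) and `ref_copy` (per-sequence median copy
#'   number across samples; even sample counts use the mean of the two
#'   middle values).
#' @export
build_reference <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  common <- rowSums(mat >= 1) == ncol(mat)
  if (!any(common)) {
    stop("no sequence is present in every sample; ",
         "lower the stringency or check the input libraries")
  }
  sub <- mat[common, , drop = FALSE]
  ref <- apply(sub, 1, median)
  list(sequences = rownames(sub), ref_copy = ref)
}

#' Fit one sample's regression against the reference
#'
#' On the common set, ordinary least squares of the sample's log2 copy
#' numbers on the reference log2 copy numbers is computed over the
#' subset with |delta log2| < `subset_window` (less than 4-fold change
#' from the reference).  The correction factor is read off the fitted
#' line at the reference mid value.
#'
#' @param sample_counts named numeric vector of raw copy numbers (must
#'   cover the reference sequences).
#' @param reference from [build_reference()].
#' @param subset_window half-width of the concordance window on the
#'   log2 scale (default 2).
#' @param xmid_mode `"midpoint"` (default) evaluates the line at the
#'   centre of the reference range, (max(x) + min(x))/2;
#'   `"half_range"` uses the literal (max(x) - min(x))/2, which lies
#'   far outside the data range whenever min(x) > 0 and turns slope
#'   noise into large factor errors -- kept for comparability only.
#' @return list of class `normalization_fit`: `a` (slope), `b`
#'   (intercept), `x_mid`, `y_mid`, `delta_y`, `f` (arithmetic
#'   correction factor \eqn{2^{\Delta y}}), `n_subset`.
#' @export
fit_sample <- function(sample_counts, reference, subset_window = 2,
                       xmid_mode = c("midpoint", "half_range")) {
  xmid_mode <- match.arg(xmid_mode)
  y_raw <- sample_counts[reference$sequences]
  if (anyNA(y_raw) || any(y_raw < 1)) {
    stop("sample is missing reference sequences (reference requires a ",
         "count >= 1 in every sample)")
  }
  x <- log2(reference$ref_copy)
  y <- log2(y_raw)
  sel <- abs(y - x) < subset_window
  if (sum(sel) < 2) stop("fewer than 2 sequences in the concordant subset")
  if (length(unique(x[sel])) < 2) {
    stop("zero variance in reference log2 copy numbers on the subset")
  }
  fit <- lm(y[sel] ~ x[sel])
  a <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  x_mid <- if (xmid_mode == "half_range") {
    (max(x) - min(x)) / 2
  } else {
    (max(x) + min(x)) / 2
  }
  y_mid <- a * x_mid + b
  delta_y <- x_mid - y_mid
  structure(list(a = a, b = b, x_mid = x_mid, y_mid = y_mid,
                 delta_y = delta_y, f = 2^delta_y,
                 n_subset = sum(sel)),
            class = "normalization_fit")
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf("<normalization_fit> a=%.4f b=%.4f f=%.4f (n=%d)\n",
              x$a, x$b, x$f, x$n_subset))
  invisible(x)
}

#' Apply per-sample correction factors to a raw count matrix
#'
#' Every raw count (reference member or not) is multiplied by its
#' sample's factor; zeros stay zero.
#'
#' @param mat raw count matrix, sequences x samples.
#' @param fits named list of [fit_sample()] results (one per column).
#' @return corrected numeric matrix of the same shape.
#' @export
apply_normalization <- function(mat, fits) {
  stopifnot(all(colnames(mat) %in% names(fits)))
  f <- vapply(fits[colnames(mat)], `[[`, numeric(1), "f")
  sweep(mat, 2, f, `*`)
}

#' Normalize a raw count matrix by the median-reference procedure
#'
#' Convenience wrapper running [build_reference()], [fit_sample()] per
#' column and [apply_normalization()].
#'
#' @param mat raw count matrix, sequences x samples.
#' @inheritParams fit_sample
#' @return list with `normalized` (matrix), `fits` (named list) and
#'   `reference`.
#' @export
normalize_matrix <- function(mat, subset_window = 2,
                             xmid_mode = "midpoint") {
  ref <- build_reference(mat)
  fits <- lapply(seq_len(ncol(mat)), function(j) {
    fit_sample(setNames(mat[, j], rownames(mat)), ref,
               subset_window, xmid_mode)
  })
  names(fits) <- colnames(mat)
  list(normalized = apply_normalization(mat, fits), fits = fits,
       reference = ref)
}

#' Export normalization fits as JSON
#'
#' @param fits named list of fits.
#' @param path output path.
#' @export
write_fits_json <- function(fits, path) {
  x <- lapply(names(fits), function(s) {
    f <- fits[[s]]
    list(sample = s, a = f$a, b = f$b, x_mid = f$x_mid,
         delta_y = f$delta_y, f = f$f, n_subset = f$n_subset)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Scale a count matrix to reads per million
#'
#' @param mat count matrix, sequences x samples.
#' @param lib_totals named per-sample clean-read totals (defaults to
#'   column sums).
#' @return matrix of RPM values.
#' @export
rpm <- function(mat, lib_totals = NULL) {
  if (is.null(lib_totals)) lib_totals <- colSums(mat)
  lib_totals <- lib_totals[colnames(mat)]
  if (any(lib_totals <= 0)) stop("library total must be positive")
  sweep(mat, 2, lib_totals, `/`) * 1e6
}
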