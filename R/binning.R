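# Spectral bucketing: fixed-width chemical-shift bins, exclusion regions,
# trapezoidal integration on the native ppm grid, total-integral normalization.

#' Define a spectral binning scheme
#'
#' A binning scheme describes how a processed 1D spectrum is reduced to a
#' feature vector: the ppm range to cover, the fixed bucket width, and the
#' chemical-shift windows to discard (residual water, additive signals, ...).
#'
#' Exclusion regions may be given in either orientation (high-to-low ppm is
#' the common NMR convention); they are normalized to `(low, high)` pairs and
#' clipped to the binning range.
#'
#' @param range_low,range_high Bounds of the binned region, in ppm.
#' @param bin_width Bucket width in ppm (default 0.02).
#' @param exclusion_regions A list of length-2 numeric vectors, each a ppm
#'   interval whose overlapping bins are dropped.
#' @return An object of class `binning_scheme`.
#' @seealso [default_binning_scheme()] for the plasma-CPMG profile used
#'   throughout the package.
#' @export
#' @examples
#' binning_scheme(0, 1, 0.5)
binning_scheme <- function(range_low, range_high, bin_width,
                           exclusion_regions = list()) {
  if (!is.numeric(range_low) || !is.numeric(range_high) ||
      !is.numeric(bin_width)) {
    abort("`range_low`, `range_high` and `bin_width` must be numeric.")
  }
  if (range_low >= range_high) abort("`range_low` must be < `range_high`.")
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  excl <- map(exclusion_regions, function(r) {
    if (length(r) != 2 || !is.numeric(r)) {
      abort("each exclusion region must be a numeric vector of length 2")
    }
    r <- sort(as.numeric(r))
    c(max(r[1], range_low), min(r[2], range_high))
  })
  excl <- excl[map_lgl(excl, function(r) r[2] > r[1])]
  structure(
    list(range_low = as.numeric(range_low),
         range_high = as.numeric(range_high),
         bin_width = as.numeric(bin_width),
         exclusion_regions = excl),
    class = "binning_scheme"
  )
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %.2f-%.2f ppm, width %.3g ppm, %d exclusion region(s)\n",
              x$range_low, x$range_high, x$bin_width,
              length(x$exclusion_regions)))
  invisible(x)
}

#' Default plasma-CPMG binning scheme
#'
#' The profile used for plasma CPMG fingerprinting throughout this package:
#' 0.2--10.00 ppm segmented into 0.02-ppm buckets, discarding the residual
#' water window (4.39--6.00 ppm) and the dextrose/citrate additive windows
#' (3.91--3.71, 3.55--3.23, 2.69--2.51 and 1.19--1.15 ppm). After exclusion
#' 368 of the 490 buckets are retained.
#'
#' @return A [binning_scheme()].
#' @export
#' @examples
#' nrow(retained_bins(default_binning_scheme()))  # 368
default_binning_scheme <- function() {
  binning_scheme(
    range_low = 0.2, range_high = 10.0, bin_width = 0.02,
    exclusion_regions = list(
      c(6.00, 4.39),   # residual water
      c(3.91, 3.71),   # dextrose
      c(3.55, 3.23),   # dextrose
      c(2.69, 2.51),   # citrate
      c(1.19, 1.15)    # citrate
    )
  )
}

#' Enumerate the bins of a scheme
#'
#' Bins are contiguous half-open intervals `[low, high)` tiling
#' `[range_low, range_high)`, with edges on the lattice
#' `range_low + i * bin_width`. Exclusions are not applied here; see
#' [apply_exclusions()].
#'
#' @param scheme A [binning_scheme()].
#' @return A tibble with columns `bin` (index), `low`, `high`, `center` (ppm),
#'   in ascending ppm order.
#' @export
#' @examples
#' make_bins(binning_scheme(0, 1, 0.5))
make_bins <- function(scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  n <- floor((scheme$range_high - scheme$range_low) / scheme$bin_width + 1e-9)
  if (n < 1) abort("scheme yields no bins")
  low <- scheme$range_low + (seq_len(n) - 1) * scheme$bin_width
  high <- scheme$range_low + seq_len(n) * scheme$bin_width
  tibble(bin = seq_len(n), low = low, high = high,
         center = (low + high) / 2)
}

#' Drop bins overlapping exclusion regions
#'
#' A bin is removed iff its interval overlaps an exclusion interval with
#' positive measure; touching at a boundary does not remove it. Bin order is
#' preserved.
#'
#' @param bins A tibble from [make_bins()].
#' @param exclusion_regions List of ppm intervals (either orientation).
#' @return The retained subset of `bins`.
#' @export
apply_exclusions <- function(bins, exclusion_regions) {
  if (length(exclusion_regions) == 0) return(bins)
  drop <- rep(FALSE, nrow(bins))
  for (r in exclusion_regions) {
    r <- sort(as.numeric(r))
    drop <- drop | (bins$low < r[2] & bins$high > r[1])
  }
  bins[!drop, , drop = FALSE]
}

#' Bins retained by a scheme after exclusion
#'
#' @param scheme A [binning_scheme()].
#' @return A tibble of retained bins (see [make_bins()]).
#' @export
retained_bins <- function(scheme) {
  apply_exclusions(make_bins(scheme), scheme$exclusion_regions)
}

#' Integrate a spectrum over a set of bins
#'
#' Computes the trapezoidal area of the piecewise-linear intensity function
#' over each bin interval, on the native ppm grid (no resampling). Spectra
#' stored in descending ppm order are reversed internally. A constant-1
#' spectrum integrates to `bin_width` in every bin.
#'
#' @param ppm Numeric vector of chemical shifts, strictly monotone.
#' @param intensity Numeric vector of intensities, same length, finite.
#' @param bins A tibble of bin intervals ([make_bins()] / [retained_bins()]).
#' @return A numeric vector of bin areas, one per row of `bins`.
#' @export
integrate_bins <- function(ppm, intensity, bins) {
  if (length(ppm) != length(intensity)) {
    abort("`ppm` and `intensity` must have equal length")
  }
  if (length(ppm) < 2) abort("spectrum needs at least 2 points")
  if (anyNA(ppm) || anyNA(intensity) || any(!is.finite(intensity))) {
    abort("spectrum values must be finite")
  }
  d <- diff(ppm)
  if (all(d < 0)) {        # descending axis: common NMR convention
    ppm <- rev(ppm); intensity <- rev(intensity); d <- diff(ppm)
  }
  if (any(d <= 0)) abort("`ppm` must be strictly monotone")
  lo <- min(bins$low); hi <- max(bins$high)
  if (ppm[1] > lo + 1e-12 || ppm[length(ppm)] < hi - 1e-12) {
    abort(sprintf("spectrum range [%.3f, %.3f] does not cover binning range [%.3f, %.3f]",
                  ppm[1], ppm[length(ppm)], lo, hi))
  }
  # exact integral of the linear interpolant: merge the bin edges into the
  # grid, take the cumulative trapezoid, difference at the edges
  edges <- sort(unique(c(bins$low, bins$high)))
  x <- sort(unique(c(ppm, edges)))
  y <- stats::approx(ppm, intensity, xout = x, rule = 2)$y
  ct <- c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
  at <- function(v) ct[match(v, x)]
  areas <- at(bins$high) - at(bins$low)
  if (any(areas < 0)) {
    warn(sprintf("%d bin area(s) are negative (baseline artifacts integrated as-is)",
                 sum(areas < 0)))
  }
  areas
}

#' Bin a set of spectra into a feature matrix
#'
#' @param spectra A tibble in long format with columns `sample_id`, `ppm`,
#'   `intensity` (one processed 1D spectrum per sample), or a named list of
#'   two-column data frames.
#' @param scheme A [binning_scheme()]; exclusions are applied.
#' @return A binned-matrix tibble: column `sample_id`, then one numeric
#'   column per retained bin named `bin_<center>` (centers to 3 decimals,
#'   ascending). Carries attribute `normalized = FALSE`; see
#'   [total_integral_normalize()].
#' @export
bin_spectra <- function(spectra, scheme = default_binning_scheme()) {
  bins <- retained_bins(scheme)
  if (is.data.frame(spectra)) {
    stopifnot(all(c("sample_id", "ppm", "intensity") %in% names(spectra)))
    spectra <- split(spectra[c("ppm", "intensity")], spectra$sample_id)
  }
  if (is.null(names(spectra)) || anyDuplicated(names(spectra))) {
    abort("spectra must carry unique sample ids")
  }
  rows <- map(spectra, function(s) {
    integrate_bins(s[[1]], s[[2]], bins)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- bin_col_names(bins$center)
  out <- bind_cols(tibble(sample_id = names(spectra)), as_tibble(m))
  attr(out, "normalized") <- FALSE
  out
}

bin_col_names <- function(centers) sprintf("bin_%.3f", centers)

#' Bin centers of a binned-matrix tibble
#'
#' Parses the `bin_<ppm>` column names back to numeric centers.
#'
#' @param binned A binned-matrix tibble (see [bin_spectra()]).
#' @return Numeric vector of bin centers (ppm).
#' @export
bin_centers <- function(binned) {
  nm <- grep("^bin_", names(binned), value = TRUE)
  as.numeric(sub("^bin_", "", nm))
}

feature_cols <- function(df) setdiff(names(df), "sample_id")

#' Total-integral normalization
#'
#' Divides each sample's bin vector by its own sum, so every row sums to 1;
#' this removes dilution and overall-scale effects. Idempotent; rows with
#' non-positive total are an error.
#'
#' @param binned A binned-matrix tibble (`sample_id` + numeric feature
#'   columns), or a bare numeric matrix / data frame of features.
#' @return The same shape, row-normalized, with attribute `normalized = TRUE`.
#' @export
#' @examples
#' m <- tibble::tibble(sample_id = "s1", bin_1.250 = 2, bin_1.270 = 2, bin_1.290 = 4)
#' total_integral_normalize(m)
total_integral_normalize <- function(binned) {
  has_id <- is.data.frame(binned) && "sample_id" %in% names(binned)
  x <- if (has_id) as.matrix(binned[feature_cols(binned)]) else as.matrix(binned)
  if (!is.numeric(x)) abort("feature columns must be numeric")
  rs <- rowSums(x)
  if (any(!is.finite(rs)) || any(rs <= 0)) {
    abort("every row must have a positive, finite total integral")
  }
  x <- x / rs
  if (has_id) {
    out <- bind_cols(binned["sample_id"], as_tibble(x))
  } else {
    out <- as_tibble(x)
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Is a binned matrix normalized?
#'
#' Checks the `normalized` attribute if present, otherwise whether all rows
#' sum to 1 within `1e-9`.
#'
#' @param binned A binned-matrix tibble.
#' @return Logical scalar.
#' @export
is_normalized <- function(binned) {
  a <- attr(binned, "normalized")
  if (!is.null(a)) return(isTRUE(a))
  x <- as.matrix(binned[feature_cols(binned)])
  all(abs(rowSums(x) - 1) < 1e-9)
}

#' Read a two-column spectrum file
#'
#' Reads one processed 1D spectrum stored as whitespace- or comma-separated
#' text with two columns (ppm, intensity); lines starting with `#` are
#' skipped.
#'
#' @param path File path.
#' @return A tibble with columns `ppm`, `intensity`.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  sep_comma <- grepl(",", first, fixed = TRUE)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          sep = if (sep_comma) "," else "")
  if (ncol(df) < 2) abort("spectrum file must have two columns: ppm, intensity")
  tibble(ppm = as.numeric(df[[1]]), intensity = as.numeric(df[[2]]))
}
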