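## Peak filtering, normalization + square-root transform, and fixed-grid
## binning of spectra into the network's input vectors.

#' Remove low-intensity peaks and cap the peak count
#'
#' Drops peaks whose intensity is below `rel_threshold` times the maximum
#' peak intensity (default 0.1%), then keeps at most the `max_peaks` highest
#' intensity peaks. m/z order is preserved.
#'
#' @param s an [ms_spectrum] with at least one peak.
#' @param rel_threshold relative intensity threshold in `[0, 1)`.
#' @param max_peaks maximum number of retained peaks.
#' @return filtered `ms_spectrum`.
#' @export
filter_peaks <- function(s, rel_threshold = 0.001, max_peaks = 1000) {
  if (n_peaks(s) == 0) stop2("cannot filter a spectrum with no peaks")
  stopifnot(rel_threshold >= 0, rel_threshold < 1, is_count(max_peaks))
  keep <- s$intensity >= rel_threshold * max(s$intensity)
  mz <- s$mz[keep]; int <- s$intensity[keep]
  if (length(mz) > max_peaks) {
    top <- order(int, decreasing = TRUE)[seq_len(max_peaks)]
    top <- sort(top)                      # preserve m/z order
    mz <- mz[top]; int <- int[top]
  }
  s$mz <- mz
  s$intensity <- int
  s
}

#' Normalize to unit maximum and square-root transform intensities
#'
#' Divides intensities by the maximum intensity (so the base peak becomes
#' 1.0), then replaces each normalized intensity by its square root, damping
#' the dominance of the strongest peaks. Both scales are retained: the
#' post-transform values in `$intensity` and the pre-transform normalized
#' values in `$intensity_raw` (the augmentation stage's low-intensity
#' removal operates on the pre-transform scale).
#'
#' @param s an [ms_spectrum] with at least one peak of positive intensity.
#' @return transformed `ms_spectrum`.
#' @export
normalize_and_transform <- function(s) {
  if (n_peaks(s) == 0) stop2("cannot transform a spectrum with no peaks")
  m <- max(s$intensity)
  if (m <= 0) stop2("cannot transform a spectrum whose intensities are all zero")
  s$intensity_raw <- s$intensity / m
  s$intensity <- sqrt(s$intensity_raw)
  s
}

#' Define a fixed m/z binning grid
#'
#' @param n_bins_total number of equal-width bins (default 10000).
#' @param mz_min,mz_max grid range in Da (defaults 10 and 1000).
#' @param known_bins integer vector of 0-based bin indices occupied in the
#'   training corpus, strictly increasing; defaults to all bins.
#' @param version_tag free-text tag stored with the scheme.
#' @return object of class `binning_scheme`.
#' @export
binning_scheme <- function(n_bins_total = 10000, mz_min = 10.0, mz_max = 1000.0,
                           known_bins = seq_len(n_bins_total) - 1L,
                           version_tag = "specsimnet-0.1") {
  stopifnot(is_count(n_bins_total), mz_max > mz_min)
  known_bins <- as.integer(known_bins)
  if (length(known_bins)) {
    if (any(diff(known_bins) <= 0)) stop2("known_bins must be strictly increasing")
    if (min(known_bins) < 0 || max(known_bins) >= n_bins_total)
      stop2("known_bins out of range [0, n_bins_total)")
  }
  structure(list(n_bins_total = as.integer(n_bins_total),
                 mz_min = mz_min, mz_max = mz_max,
                 known_bins = known_bins, version_tag = version_tag),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %d bins on [%g, %g) Da, %d known (%s)\n",
              x$n_bins_total, x$mz_min, x$mz_max, length(x$known_bins),
              x$version_tag))
  invisible(x)
}

bin_width <- function(scheme) (scheme$mz_max - scheme$mz_min) / scheme$n_bins_total

## 0-based bin index for each m/z; NA outside [mz_min, mz_max)
bin_index <- function(mz, scheme) {
  idx <- floor((mz - scheme$mz_min) / bin_width(scheme))
  idx[mz < scheme$mz_min | mz >= scheme$mz_max] <- NA
  as.integer(idx)
}

#' Fit a binning scheme to a training corpus
#'
#' Determines which bins of the fixed grid receive at least one peak across
#' the (already filtered and transformed) training spectra; only these
#' "known" bins form the model's input vector, all others are removed.
#'
#' @param training_spectra list of [ms_spectrum].
#' @inheritParams binning_scheme
#' @return a [binning_scheme] whose `known_bins` are the occupied bins.
#' @export
fit_binning <- function(training_spectra, n_bins_total = 10000,
                        mz_min = 10.0, mz_max = 1000.0,
                        version_tag = "specsimnet-0.1") {
  base <- binning_scheme(n_bins_total, mz_min, mz_max,
                         known_bins = integer(0), version_tag = version_tag)
  occupied <- logical(n_bins_total)
  for (s in training_spectra) {
    idx <- bin_index(s$mz, base)
    idx <- idx[!is.na(idx)]
    occupied[idx + 1L] <- TRUE
  }
  if (!any(occupied))
    stop2("no training peaks fall inside [", mz_min, ", ", mz_max, ")")
  base$known_bins <- which(occupied) - 1L
  base
}

#' Bin a spectrum onto a scheme's known bins
#'
#' Assigns each peak to bin `floor((mz - mz_min) / width)`; when several
#' peaks share a bin the highest transformed intensity wins. Peaks landing
#' outside `[mz_min, mz_max)` or in bins unknown to the scheme are dropped
#' and their transformed intensity is accumulated into `missing_fraction`
#' (normalized by the spectrum's total transformed intensity).
#' `missing_fraction` is diagnostic only; it never alters scores.
#'
#' @param s a filtered and transformed [ms_spectrum] (see
#'   [normalize_and_transform()]).
#' @param scheme a [binning_scheme].
#' @return object of class `binned_spectrum` with fields `values` (length
#'   `length(scheme$known_bins)`, entries in `[0, 1]`), `raw_values`
#'   (aligned pre-transform normalized intensities), `missing_fraction`,
#'   `source_id`, and `compound_key` (first 14 InChIKey characters, if
#'   available).
#' @export
bin_spectrum <- function(s, scheme) {
  if (is.null(s$intensity_raw))
    s <- normalize_and_transform(s)
  d <- length(scheme$known_bins)
  values <- numeric(d)
  raw_values <- numeric(d)
  idx <- bin_index(s$mz, scheme)
  total <- sum(s$intensity)
  known_pos <- match(idx, scheme$known_bins)   # NA: out of range or unknown
  missing <- if (total > 0) sum(s$intensity[is.na(known_pos)]) / total else 0
  hit <- which(!is.na(known_pos))
  if (length(hit)) {
    ## max-pool transformed intensity per bin; carry the winner's raw value
    o <- hit[order(s$intensity[hit])]          # ascending: last write wins
    values[known_pos[o]] <- s$intensity[o]
    raw_values[known_pos[o]] <- s$intensity_raw[o]
  }
  structure(list(values = values, raw_values = raw_values,
                 missing_fraction = missing,
                 source_id = s$metadata$identifier %||% NA_character_,
                 compound_key = compound_key(s)),
            class = "binned_spectrum")
}

## first 14 InChIKey characters, or NA
compound_key <- function(s) {
  ik <- s$metadata$inchikey
  if (is.null(ik)) NA_character_ else substr(ik, 1, 14)
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf("<binned_spectrum> %s: %d/%d nonzero bins, missing_fraction=%.3g\n",
              x$source_id, sum(x$values > 0), length(x$values),
              x$missing_fraction))
  invisible(x)
}

#' Full preprocessing of raw spectra into binned network inputs
#'
#' Convenience pipeline: [filter_peaks()] -> [normalize_and_transform()] ->
#' [bin_spectrum()] for every spectrum.
#'
#' @param spectra list of [ms_spectrum] (already selected).
#' @param scheme a [binning_scheme]; if `NULL`, one is fitted on `spectra`
#'   with the given grid parameters.
#' @param rel_threshold,max_peaks passed to [filter_peaks()].
#' @param n_bins_total,mz_min,mz_max grid parameters used when fitting.
#' @return list with `binned` (list of `binned_spectrum`) and `scheme`.
#' @export
preprocess_spectra <- function(spectra, scheme = NULL,
                               rel_threshold = 0.001, max_peaks = 1000,
                               n_bins_total = 10000, mz_min = 10.0,
                               mz_max = 1000.0) {
  prepped <- lapply(spectra, function(s)
    normalize_and_transform(filter_peaks(s, rel_threshold, max_peaks)))
  if (is.null(scheme))
    scheme <- fit_binning(prepped, n_bins_total, mz_min, mz_max)
  list(binned = lapply(prepped, bin_spectrum, scheme = scheme),
       scheme = scheme)
}

## JSON (de)serialization of schemes; stored inside model archives.
write_binning_scheme <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

read_binning_scheme <- function(path) {
  x <- jsonlite::fromJSON(path)
  binning_scheme(x$n_bins_total, x$mz_min, x$mz_max, x$known_bins,
                 x$version_tag)
}
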