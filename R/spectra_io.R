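## Reading, validating and selecting annotated MS/MS spectra from the
## standard text library formats (MGF, MSP) and the package's internal JSON
## interchange format.

#' Construct an MS/MS spectrum
#'
#' The ingestion unit of the package: a peak list (m/z in Da, intensities in
#' arbitrary units) plus structure and acquisition metadata. Peaks are stored
#' sorted ascending by m/z.
#'
#' @param mz numeric vector of fragment m/z values (Da), all > 0.
#' @param intensity numeric vector of peak intensities, all >= 0, same length
#'   as `mz`.
#' @param metadata named list; canonical keys are `identifier`, `smiles`,
#'   `inchi`, `inchikey`, `ionmode` (one of `"positive"`, `"negative"`,
#'   `"unknown"`), `precursor_mz`, `title`. Unknown keys are retained.
#' @return an object of class `ms_spectrum` with fields `mz`, `intensity`,
#'   `intensity_raw` (normalized pre-transform intensities, filled by
#'   [normalize_and_transform()]), and `metadata`.
#' @examples
#' s <- ms_spectrum(c(150.1, 75.2), c(10, 100),
#'                  list(identifier = "a", ionmode = "positive"))
#' s$mz  # sorted ascending
#' @export
ms_spectrum <- function(mz, intensity, metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop2("mz and intensity must have equal length")
  if (length(mz) > 0) {
    if (any(!is.finite(mz)) || any(mz <= 0)) stop2("all m/z must be finite and > 0")
    if (any(!is.finite(intensity)) || any(intensity < 0))
      stop2("all intensities must be finite and >= 0")
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  md <- as.list(metadata)
  md$ionmode <- tolower(md$ionmode %||% "unknown")
  if (!md$ionmode %in% c("positive", "negative", "unknown")) md$ionmode <- "unknown"
  if (!is.null(md$inchikey) && !grepl(inchikey_regex(), md$inchikey)) {
    warning("dropping malformed InChIKey '", md$inchikey, "'", call. = FALSE)
    md$inchikey <- NULL
  }
  structure(list(mz = mz, intensity = intensity, intensity_raw = NULL,
                 metadata = md),
            class = "ms_spectrum")
}

inchikey_regex <- function() "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s: %d peaks, ionmode=%s%s\n",
              x$metadata$identifier %||% "?", length(x$mz), x$metadata$ionmode,
              if (!is.null(x$metadata$inchikey))
                paste0(", inchikey=", x$metadata$inchikey) else ""))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s an `ms_spectrum`.
#' @return integer peak count.
#' @export
n_peaks <- function(s) length(s$mz)

## canonical metadata key mapping, case-insensitive
.canonical_keys <- c(
  "pepmass" = "precursor_mz", "precursor_mz" = "precursor_mz",
  "precursormz" = "precursor_mz",
  "ionmode" = "ionmode", "ion_mode" = "ionmode",
  "smiles" = "smiles", "inchi" = "inchi", "inchikey" = "inchikey",
  "inchiaux" = "inchi_aux",
  "title" = "title", "name" = "title", "scans" = "identifier",
  "spectrumid" = "identifier", "spectrum_id" = "identifier",
  "feature_id" = "identifier", "comments" = "comments", "comment" = "comments",
  "charge" = "charge"
)

canonicalize_key <- function(key) {
  k <- tolower(gsub("[ -]", "_", trimws(key)))
  v <- .canonical_keys[k]
  if (length(v) != 1 || is.na(v)) k else unname(v)
}

make_spectrum_record <- function(mz, intensity, meta, n_record, warnings_env) {
  meta$identifier <- meta$identifier %||% paste0("spectrum_", n_record)
  tryCatch(ms_spectrum(mz, intensity, meta),
           error = function(e) {
             warning(sprintf("skipping malformed record %d: %s", n_record,
                             conditionMessage(e)), call. = FALSE)
             if (!is.null(warnings_env)) warnings_env$n_skipped <- warnings_env$n_skipped + 1L
             NULL
           })
}

#' Read annotated MS/MS spectra from MGF, MSP or JSON
#'
#' Parses one of the supported text dialects into a list of [ms_spectrum]
#' objects. Metadata keys are matched case-insensitively and mapped to
#' canonical names (`PEPMASS` -> `precursor_mz`, `NAME`/`TITLE` -> `title`,
#' ...). Records that fail to parse are skipped with a warning; records with
#' zero peaks are retained (they are removed later by the selection step).
#'
#' The JSON dialect is the package's interchange format: an array of objects,
#' each with a `"peaks_json"` list of `[mz, intensity]` pairs and a flat
#' metadata map.
#'
#' @param path path to an existing file.
#' @param format one of `"mgf"`, `"msp"`, `"json"`; default guesses from the
#'   file extension.
#' @return list of `ms_spectrum`.
#' @seealso [write_spectra()] for the inverse, [select_annotated_positive()]
#'   for the selection applied before training.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", msp = "msp", json = "json",
                     stop2("cannot guess format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop2("file not found: ", path)
  switch(format,
         mgf = read_mgf(path),
         msp = read_msp(path),
         json = read_spectra_json(path))
}

read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines, ignore.case = TRUE)
  ends <- grep("^\\s*END IONS\\s*$", lines, ignore.case = TRUE)
  if (length(begins) != length(ends) || any(ends < begins))
    stop2("malformed MGF: unbalanced BEGIN IONS/END IONS blocks")
  env <- new.env(); env$n_skipped <- 0L
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_meta <- grepl("=", block, fixed = TRUE) & !grepl("^[0-9.]", trimws(block))
    meta <- list()
    for (ln in block[is_meta]) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- canonicalize_key(substr(ln, 1, eq - 1))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      if (key == "precursor_mz") val <- as.numeric(strsplit(val, "\\s+")[[1]][1])
      if (nzchar(key) && length(val) && !identical(val, ""))
        meta[[key]] <- meta[[key]] %||% val
    }
    peak_lines <- trimws(block[!is_meta])
    mz <- numeric(0); int <- numeric(0)
    if (length(peak_lines)) {
      parts <- strsplit(peak_lines, "[[:space:],;]+")
      mz <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])), 0)
      int <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])), 0)
      keep <- !is.na(mz) & !is.na(int)
      mz <- mz[keep]; int <- int[keep]
    }
    out[[i]] <- make_spectrum_record(mz, int, meta, i, env)
  }
  if (env$n_skipped > 0L)
    message(env$n_skipped, " malformed MGF record(s) skipped")
  Filter(Negate(is.null), out)
}

read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## records are separated by blank lines; each starts with metadata
  ## "Key: value" lines and contains a "Num Peaks: n" line before the peaks
  starts <- grep("^\\s*Name\\s*:", lines, ignore.case = TRUE)
  if (length(starts) == 0) stop2("malformed MSP: no 'Name:' records found")
  bounds <- c(starts, length(lines) + 1L)
  env <- new.env(); env$n_skipped <- 0L
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    meta <- list()
    np_line <- grep("^\\s*Num ?Peaks\\s*:", block, ignore.case = TRUE)
    meta_lines <- if (length(np_line)) block[seq_len(np_line[1])] else block
    peak_lines <- if (length(np_line) && np_line[1] < length(block))
      block[(np_line[1] + 1L):length(block)] else character(0)
    for (ln in meta_lines) {
      colon <- regexpr(":", ln, fixed = TRUE)
      if (colon < 0) next
      key <- canonicalize_key(substr(ln, 1, colon - 1))
      val <- trimws(substr(ln, colon + 1, nchar(ln)))
      if (key == "comments") {
        ## MSP convention: Comments hold quoted "key=value" annotations
        for (kv in regmatches(val, gregexpr('"[^"]*"', val))[[1]]) {
          kv <- gsub('^"|"$', "", kv)
          eq <- regexpr("=", kv, fixed = TRUE)
          if (eq > 0) {
            k2 <- canonicalize_key(substr(kv, 1, eq - 1))
            meta[[k2]] <- meta[[k2]] %||% trimws(substr(kv, eq + 1, nchar(kv)))
          }
        }
      } else if (nzchar(key) && nzchar(val)) {
        meta[[key]] <- meta[[key]] %||% val
      }
    }
    if (!is.null(meta$precursor_mz))
      meta$precursor_mz <- suppressWarnings(as.numeric(meta$precursor_mz))
    mz <- numeric(0); int <- numeric(0)
    if (length(peak_lines)) {
      parts <- strsplit(trimws(peak_lines), "[[:space:],;]+")
      mz <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])), 0)
      int <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])), 0)
      keep <- !is.na(mz) & !is.na(int)
      mz <- mz[keep]; int <- int[keep]
    }
    out[[i]] <- make_spectrum_record(mz, int, meta, i, env)
  }
  if (env$n_skipped > 0L)
    message(env$n_skipped, " malformed MSP record(s) skipped")
  Filter(Negate(is.null), out)
}

read_spectra_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  env <- new.env(); env$n_skipped <- 0L
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    peaks <- r$peaks_json %||% list()
    mz <- vapply(peaks, function(p) as.numeric(p[[1]]), 0)
    int <- vapply(peaks, function(p) as.numeric(p[[2]]), 0)
    meta <- r[setdiff(names(r), "peaks_json")]
    names(meta) <- vapply(names(meta), canonicalize_key, "")
    out[[i]] <- make_spectrum_record(mz, int, meta, i, env)
  }
  if (env$n_skipped > 0L)
    message(env$n_skipped, " malformed JSON record(s) skipped")
  Filter(Negate(is.null), out)
}

#' Write spectra to MGF, MSP or JSON
#'
#' Inverse of [read_spectra()]. Numeric values are written with 17
#' significant digits so that peak lists survive a write/read round trip
#' bit-for-bit.
#'
#' @param spectra list of [ms_spectrum].
#' @param path output file path.
#' @param format one of `"mgf"`, `"msp"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("mgf", "msp", "json")) {
  format <- match.arg(format)
  fmt_num <- function(x) sprintf("%.17g", x)
  if (format == "json") {
    recs <- lapply(spectra, function(s) {
      c(s$metadata,
        list(peaks_json = unname(Map(function(m, i) c(m, i), s$mz, s$intensity))))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                         pretty = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    md <- s$metadata
    if (format == "mgf") {
      writeLines("BEGIN IONS", con)
      if (!is.null(md$title)) writeLines(paste0("TITLE=", md$title), con)
      if (!is.null(md$precursor_mz))
        writeLines(paste0("PEPMASS=", fmt_num(md$precursor_mz)), con)
      if (!is.null(md$ionmode)) writeLines(paste0("IONMODE=", md$ionmode), con)
      if (!is.null(md$smiles)) writeLines(paste0("SMILES=", md$smiles), con)
      if (!is.null(md[["inchi"]])) writeLines(paste0("INCHI=", md[["inchi"]]), con)
      if (!is.null(md$inchikey)) writeLines(paste0("INCHIKEY=", md$inchikey), con)
      writeLines(paste0("SPECTRUMID=", md$identifier), con)
      if (length(s$mz))
        writeLines(paste(fmt_num(s$mz), fmt_num(s$intensity)), con)
      writeLines(c("END IONS", ""), con)
    } else {
      writeLines(paste0("Name: ", md$title %||% md$identifier), con)
      writeLines(paste0("SPECTRUMID: ", md$identifier), con)
      if (!is.null(md$precursor_mz))
        writeLines(paste0("PrecursorMZ: ", fmt_num(md$precursor_mz)), con)
      if (!is.null(md$ionmode)) writeLines(paste0("Ion_mode: ", md$ionmode), con)
      if (!is.null(md$smiles)) writeLines(paste0("SMILES: ", md$smiles), con)
      if (!is.null(md[["inchi"]])) writeLines(paste0("INCHI: ", md[["inchi"]]), con)
      if (!is.null(md$inchikey)) writeLines(paste0("INCHIKEY: ", md$inchikey), con)
      writeLines(paste0("Num Peaks: ", length(s$mz)), con)
      if (length(s$mz))
        writeLines(paste(fmt_num(s$mz), fmt_num(s$intensity), sep = "\t"), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Select annotated positive-mode spectra suitable for training
#'
#' Keeps only spectra that (1) were acquired in positive ionization mode,
#' (2) carry a layout-valid InChIKey *and* at least one structure string
#' (SMILES or InChI), and (3) have at least `min_peaks` peaks with m/z inside
#' the closed interval `[mz_low, mz_high]`. The defaults reproduce the usual
#' library-cleaning rule of requiring >= 5 peaks between 10 and 1000 Da.
#' The operation is idempotent and preserves input order.
#'
#' @param spectra list of [ms_spectrum].
#' @param min_peaks minimum number of in-range peaks (inclusive threshold).
#' @param mz_low,mz_high closed m/z interval bounds (Da).
#' @return the selected sublist.
#' @export
select_annotated_positive <- function(spectra, min_peaks = 5,
                                      mz_low = 10.0, mz_high = 1000.0) {
  stopifnot(is_count(min_peaks), mz_low < mz_high)
  keep <- vapply(spectra, function(s) {
    md <- s$metadata
    if (!identical(md$ionmode, "positive")) return(FALSE)
    if (is.null(md$inchikey) || !grepl(inchikey_regex(), md$inchikey))
      return(FALSE)
    if (is.null(md[["smiles"]]) && is.null(md[["inchi"]])) return(FALSE)
    sum(s$mz >= mz_low & s$mz <= mz_high) >= min_peaks
  }, logical(1))
  spectra[keep]
}
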