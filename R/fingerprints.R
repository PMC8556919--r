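## Compound grouping, molecular fingerprints and the structural-similarity
## label matrix. Fingerprints of real structures are computed with RDKit
## through the system `python` (see inst/python/fingerprints.py); the
## synthetic-fixture path supplies precomputed fingerprints and needs no
## chemistry toolkit at all.

#' Construct a molecular fingerprint
#'
#' @param bits binary (0/1) vector of length `n_bits`, or an integer vector
#'   of active bit positions (1-based) if `n_bits` is given explicitly and
#'   `bits` is shorter than `n_bits` with `positions = TRUE`.
#' @param fp_type one of `"daylight"`, `"morgan2"`, `"morgan3"`,
#'   `"synthetic"`.
#' @param n_bits fingerprint length; defaults to `length(bits)`.
#' @param positions if `TRUE`, `bits` is interpreted as active positions.
#' @return object of class `molecular_fingerprint`.
#' @export
fingerprint <- function(bits, fp_type = "daylight", n_bits = length(bits),
                        positions = FALSE) {
  if (positions) {
    v <- integer(n_bits)
    if (length(bits)) {
      stopifnot(all(bits >= 1), all(bits <= n_bits))
      v[as.integer(bits)] <- 1L
    }
    bits <- v
  } else {
    bits <- as.integer(bits)
    if (length(bits) != n_bits) stop2("length(bits) != n_bits")
    if (any(!bits %in% c(0L, 1L))) stop2("fingerprint bits must be 0/1")
  }
  structure(list(bits = bits, fp_type = fp_type, n_bits = as.integer(n_bits)),
            class = "molecular_fingerprint")
}

#' @export
print.molecular_fingerprint <- function(x, ...) {
  cat(sprintf("<molecular_fingerprint> %s, %d bits, %d active\n",
              x$fp_type, x$n_bits, sum(x$bits)))
  invisible(x)
}

#' Group spectra by 2D compound identity
#'
#' Partitions spectra by the first 14 characters of their InChIKey, i.e. by
#' 2D structure disregarding stereochemistry. Exhaustive and disjoint.
#'
#' @param spectra list of [ms_spectrum], each carrying an InChIKey.
#' @return named list mapping the 14-character key to its spectra.
#' @export
group_by_compound <- function(spectra) {
  keys <- vapply(spectra, function(s) {
    k <- compound_key(s)
    if (is.na(k))
      stop2("spectrum '", s$metadata$identifier %||% "?", "' has no InChIKey")
    k
  }, "")
  split(spectra, factor(keys, levels = unique(keys)))
}

#' Pick the representative structure of a compound group
#'
#' Returns the most common structure string in the group (InChI preferred
#' over SMILES per spectrum); ties are broken by the lexicographically
#' smallest string so the choice is deterministic.
#'
#' @param group non-empty list of [ms_spectrum] sharing a compound key.
#' @return a single structure string.
#' @export
select_representative_structure <- function(group) {
  stopifnot(length(group) > 0)
  strs <- vapply(group, function(s) {
    st <- s$metadata[["inchi"]] %||% s$metadata[["smiles"]]
    if (is.null(st)) stop2("spectrum '", s$metadata$identifier %||% "?",
                           "' carries no structure string")
    st
  }, "")
  tab <- table(strs)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1]
}

fingerprint_python_script <- function() {
  p <- system.file("python", "fingerprints.py", package = "specsimnet")
  if (!nzchar(p)) stop2("bundled fingerprints.py not found; reinstall the package")
  p
}

#' Compute molecular fingerprints with RDKit
#'
#' Computes binary RDKit fingerprints for one or more structure strings
#' (SMILES or InChI, auto-detected), delegating to the system `python` with
#' RDKit installed. Structures are canonicalized by the toolkit first, so
#' different spellings of one molecule give identical bit patterns. The bit
#' patterns are toolkit-specific; the RDKit version is recorded in the
#' `version_tag` attribute of the result.
#'
#' @param structures character vector of SMILES and/or InChI strings.
#' @param fp_type `"daylight"` (topological path-based), `"morgan2"` or
#'   `"morgan3"` (circular, radius 2/3).
#' @param n_bits fingerprint length (default 2048).
#' @return for `compute_fingerprints`, a list of [fingerprint] objects (with
#'   attribute `version_tag`); `compute_fingerprint` is the single-structure
#'   convenience wrapper returning one fingerprint.
#' @export
compute_fingerprints <- function(structures,
                                 fp_type = c("daylight", "morgan2", "morgan3"),
                                 n_bits = 2048) {
  fp_type <- match.arg(fp_type)
  stopifnot(is.character(structures), length(structures) > 0)
  if (any(!nzchar(trimws(structures))))
    stop2("empty structure string at position ",
          which(!nzchar(trimws(structures)))[1])
  infile <- tempfile(fileext = ".txt")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  writeLines(structures, infile)
  status <- system2("python", c(fingerprint_python_script(), infile, outfile,
                                fp_type, n_bits),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop2("RDKit fingerprint computation failed:\n",
          paste(status, collapse = "\n"))
  res <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  bad <- which(vapply(res$fingerprints, is.null, TRUE) |
                 vapply(res$fingerprints, function(x) length(x) == 1 &&
                          identical(x[[1]], "ERROR"), TRUE))
  if (length(bad))
    stop2("unparseable structure(s): ",
          paste(structures[bad], collapse = ", "))
  out <- lapply(res$fingerprints, function(pos)
    fingerprint(unlist(pos) + 1L, fp_type = fp_type, n_bits = n_bits,
                positions = TRUE))
  attr(out, "version_tag") <- paste0("rdkit-", res$rdkit_version)
  out
}

#' @rdname compute_fingerprints
#' @param structure a single structure string.
#' @export
compute_fingerprint <- function(structure,
                                fp_type = c("daylight", "morgan2", "morgan3"),
                                n_bits = 2048) {
  compute_fingerprints(structure, fp_type, n_bits)[[1]]
}

as_bits <- function(x) {
  if (inherits(x, "molecular_fingerprint")) x$bits else as.integer(x)
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`. A pair of all-zero fingerprints is defined to
#' score 0.
#'
#' @param a,b fingerprints of equal length ([fingerprint] objects or 0/1
#'   vectors).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as_bits(a); b <- as_bits(b)
  if (length(a) != length(b)) stop2("fingerprint lengths differ")
  i <- sum(a & b)
  u <- sum(a | b)
  if (u == 0) 0 else i / u
}

#' Dice similarity of two fingerprints
#'
#' `2 |a AND b| / (|a| + |b|)`; an all-zero pair scores 0.
#'
#' @inheritParams tanimoto
#' @return similarity in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_bits(a); b <- as_bits(b)
  if (length(a) != length(b)) stop2("fingerprint lengths differ")
  s <- sum(a) + sum(b)
  if (s == 0) 0 else 2 * sum(a & b) / s
}

#' Build the compound-level structural-similarity label matrix
#'
#' Produces the symmetric K x K matrix of pairwise fingerprint similarities
#' over K compounds; this matrix supplies the training labels for every
#' spectrum pair via the two spectra's compound keys. Fingerprints may be
#' computed from structures (via `groups`, using
#' [select_representative_structure()] and RDKit) or supplied precomputed
#' (`fingerprints`), e.g. by the synthetic-fixture generator.
#'
#' The diagonal is exactly 1 (a compound versus itself), which also covers
#' the degenerate all-zero fingerprint.
#'
#' @param groups named list of spectrum groups as returned by
#'   [group_by_compound()]; ignored when `fingerprints` is given.
#' @param fingerprints named list of [fingerprint] objects keyed by compound.
#' @param fp_type,n_bits passed to [compute_fingerprints()] when computing
#'   from structures.
#' @param metric `"tanimoto"` or `"dice"`.
#' @return object of class `similarity_labels`: list with `compound_keys`,
#'   `scores` (symmetric matrix, dimnames = keys), `metric`, `fp_type`,
#'   `version_tag`.
#' @export
build_label_matrix <- function(groups = NULL, fingerprints = NULL,
                               fp_type = "daylight",
                               metric = c("tanimoto", "dice"),
                               n_bits = 2048) {
  metric <- match.arg(metric)
  version_tag <- "precomputed"
  if (is.null(fingerprints)) {
    if (is.null(groups)) stop2("supply either groups or fingerprints")
    structures <- vapply(groups, select_representative_structure, "")
    fingerprints <- compute_fingerprints(structures, fp_type, n_bits)
    version_tag <- attr(fingerprints, "version_tag")
    names(fingerprints) <- names(groups)
  }
  keys <- names(fingerprints)
  if (is.null(keys) || any(!nzchar(keys)))
    stop2("fingerprints must be a named list keyed by compound")
  B <- do.call(rbind, lapply(fingerprints, function(f) as_bits(f)))
  storage.mode(B) <- "double"
  counts <- rowSums(B)
  inter <- B %*% t(B)
  scores <- if (metric == "tanimoto") {
    un <- outer(counts, counts, "+") - inter
    ifelse(un == 0, 0, inter / un)
  } else {
    s <- outer(counts, counts, "+")
    ifelse(s == 0, 0, 2 * inter / s)
  }
  diag(scores) <- 1.0
  dimnames(scores) <- list(keys, keys)
  fpt <- unique(vapply(fingerprints, function(f)
    if (inherits(f, "molecular_fingerprint")) f$fp_type else fp_type, ""))
  structure(list(compound_keys = keys, scores = scores, metric = metric,
                 fp_type = paste(fpt, collapse = "+"),
                 version_tag = version_tag),
            class = "similarity_labels")
}

#' @export
print.similarity_labels <- function(x, ...) {
  cat(sprintf("<similarity_labels> %d x %d %s scores on %s fingerprints\n",
              nrow(x$scores), ncol(x$scores), x$metric, x$fp_type))
  invisible(x)
}

#' Look up the structural-similarity label of two compounds
#' @param labels a `similarity_labels` object.
#' @param key_a,key_b 14-character compound keys.
#' @return numeric score in `[0, 1]`.
#' @export
label_of <- function(labels, key_a, key_b) {
  if (!key_a %in% labels$compound_keys || !key_b %in% labels$compound_keys)
    stop2("compound key missing from label matrix")
  labels$scores[key_a, key_b]
}

## label matrix persistence: TSV matrix + JSON sidecar with keys/metadata
write_label_matrix <- function(labels, path_matrix, path_sidecar) {
  utils::write.table(labels$scores, path_matrix, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(compound_keys = labels$compound_keys,
                            metric = labels$metric, fp_type = labels$fp_type,
                            version_tag = labels$version_tag),
                       path_sidecar, auto_unbox = TRUE)
  invisible(path_matrix)
}

read_label_matrix <- function(path_matrix, path_sidecar) {
  side <- jsonlite::fromJSON(path_sidecar)
  m <- as.matrix(utils::read.table(path_matrix, sep = "\t"))
  dimnames(m) <- list(side$compound_keys, side$compound_keys)
  structure(list(compound_keys = side$compound_keys, scores = m,
                 metric = side$metric, fp_type = side$fp_type,
                 version_tag = side$version_tag),
            class = "similarity_labels")
}
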