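## Synthetic spectral libraries with a planted correlation between spectral
## content and fingerprint similarity. Compounds come in clusters: each
## cluster has a seed fingerprint, members are per-bit mutations of it, and
## every active bit maps deterministically to a small set of fragment m/z
## values — so fingerprint overlap translates into shared peaks, which is
## what makes the similarity-prediction task learnable at desk scale.
## Fingerprints here are synthetic bit vectors; no chemistry toolkit is
## involved anywhere on this path.

#' Synthetic-library settings
#'
#' Defaults describe a desk-scale library: 40 clusters of 5 compounds
#' (200 compounds), 256-bit fingerprints at 10% density, 5% per-bit
#' mutation within a cluster, 2 fragments per active bit, 3 replicate
#' spectra per compound with 10% log-normal intensity noise and 3 low
#' random noise peaks each.
#'
#' @param n_clusters number of compound clusters.
#' @param members_per_cluster compounds per cluster.
#' @param fp_bits fingerprint length.
#' @param bit_density expected fraction of active bits in a cluster seed.
#' @param mutation_rate per-bit flip probability for cluster members.
#' @param fragments_per_bit fragment m/z values derived from each active
#'   bit.
#' @param mz_range numeric length-2, fragment m/z range in Da.
#' @param spectra_per_compound replicate spectra per compound.
#' @param intensity_noise_sd log-normal sdlog of replicate intensity noise.
#' @param n_noise_peaks uniform random low-intensity noise peaks per
#'   spectrum.
#' @param seed integer seed; the library is fully deterministic given the
#'   config.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 40, members_per_cluster = 5,
                             fp_bits = 256, bit_density = 0.1,
                             mutation_rate = 0.05, fragments_per_bit = 2,
                             mz_range = c(10, 1000),
                             spectra_per_compound = 3,
                             intensity_noise_sd = 0.1, n_noise_peaks = 3,
                             seed = 1) {
  stopifnot(is_count(n_clusters), is_count(members_per_cluster),
            is_count(fp_bits), bit_density > 0, bit_density <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            is_count(fragments_per_bit), length(mz_range) == 2,
            mz_range[1] < mz_range[2], is_count(spectra_per_compound),
            intensity_noise_sd >= 0, n_noise_peaks >= 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 members_per_cluster = as.integer(members_per_cluster),
                 fp_bits = as.integer(fp_bits), bit_density = bit_density,
                 mutation_rate = mutation_rate,
                 fragments_per_bit = as.integer(fragments_per_bit),
                 mz_range = as.numeric(mz_range),
                 spectra_per_compound = as.integer(spectra_per_compound),
                 intensity_noise_sd = intensity_noise_sd,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## Deterministic hash of (bit index, fragment slot, seed) into [0, 1);
## a multiplicative LCG over doubles, exact below 2^53.
frag_hash <- function(bit, slot, seed) {
  h <- (as.numeric(bit) * 2654435.0 + as.numeric(slot) * 40503.0 +
          as.numeric(seed) * 97.0 + 17.0) %% 2147483647
  h <- (h * 48271) %% 2147483647
  h / 2147483647
}

## 14 uppercase letters encoding the compound index, layout-compatible with
## an InChIKey first block
synthetic_key <- function(i) {
  digits <- integer(8)
  x <- i
  for (d in 8:1) {
    digits[d] <- x %% 26
    x <- x %/% 26
  }
  paste0("SYNKEY", paste(LETTERS[digits + 1], collapse = ""))
}

#' Generate a synthetic compound library
#'
#' Draws `n_clusters` seed fingerprints at the configured bit density, then
#' populates each cluster by flipping every seed bit independently with
#' probability `mutation_rate`. Each active bit maps deterministically
#' (seeded hash) to `fragments_per_bit` m/z values inside `mz_range`, so
#' compounds sharing bits share fragment peaks.
#'
#' @param cfg a [synthetic_config()].
#' @return list of `synthetic_compound` objects: `key` (14-character
#'   synthetic identifier), `cluster`, `fingerprint`
#'   ([fingerprint] of type `"synthetic"`), `fragment_mzs`.
#' @export
generate_compounds <- function(cfg = synthetic_config()) {
  with_seed(cfg$seed, {
    out <- vector("list", cfg$n_clusters * cfg$members_per_cluster)
    idx <- 0L
    for (cl in seq_len(cfg$n_clusters)) {
      seed_bits <- stats::rbinom(cfg$fp_bits, 1L, cfg$bit_density)
      for (mem in seq_len(cfg$members_per_cluster)) {
        flips <- stats::rbinom(cfg$fp_bits, 1L, cfg$mutation_rate)
        bits <- as.integer(xor(seed_bits == 1L, flips == 1L))
        idx <- idx + 1L
        active <- which(bits == 1L)
        frag <- unlist(lapply(active, function(b)
          vapply(seq_len(cfg$fragments_per_bit), function(s)
            cfg$mz_range[1] +
              frag_hash(b, s, cfg$seed) * diff(cfg$mz_range), 0)))
        out[[idx]] <- structure(
          list(key = synthetic_key(idx), cluster = cl,
               fingerprint = fingerprint(bits, fp_type = "synthetic"),
               fragment_mzs = sort(frag)),
          class = "synthetic_compound")
      }
    }
    out
  })
}

#' Generate replicate spectra for synthetic compounds
#'
#' Per compound, `spectra_per_compound` replicates: peaks at the compound's
#' fragment m/z values with per-fragment base intensities (deterministic
#' per compound) perturbed log-normally (`sdlog = intensity_noise_sd`),
#' plus `n_noise_peaks` uniform random low-intensity noise peaks. Spectra
#' carry a synthetic InChIKey built from the compound key, a placeholder
#' structure string, and positive ion mode, so they pass
#' [select_annotated_positive()] whenever enough fragments exist.
#'
#' @param compounds list from [generate_compounds()].
#' @param cfg the same [synthetic_config()].
#' @return list of [ms_spectrum].
#' @export
generate_spectra <- function(compounds, cfg = synthetic_config()) {
  if (length(compounds) == 0) stop2("no compounds")
  with_seed(derive_seed(cfg$seed, 2), {
    out <- list()
    for (cp in compounds) {
      nf <- length(cp$fragment_mzs)
      base_int <- 0.2 + 0.8 * vapply(seq_len(nf), function(s)
        frag_hash(s, 99, cfg$seed + hash_string(cp$key)), 0)
      for (r in seq_len(cfg$spectra_per_compound)) {
        int <- base_int *
          stats::rlnorm(nf, meanlog = 0, sdlog = cfg$intensity_noise_sd)
        mz <- cp$fragment_mzs
        if (cfg$n_noise_peaks > 0) {
          mz <- c(mz, stats::runif(cfg$n_noise_peaks, cfg$mz_range[1],
                                   cfg$mz_range[2]))
          int <- c(int, stats::runif(cfg$n_noise_peaks, 0.001, 0.05))
        }
        out[[length(out) + 1L]] <- ms_spectrum(
          mz, int,
          list(identifier = sprintf("%s_rep%d", cp$key, r),
               inchikey = paste0(cp$key, "-UHFFFAOYSA-N"),
               smiles = paste0("*SYN:", cp$key),   # placeholder, not chemistry
               ionmode = "positive",
               precursor_mz = max(mz) + 1))
      }
    }
    out
  })
}

#' Fingerprint sidecar for a synthetic library
#'
#' @param compounds list from [generate_compounds()].
#' @return named list of [fingerprint] objects keyed by compound key, ready
#'   for [build_label_matrix()].
#' @export
synthetic_fingerprints <- function(compounds) {
  stats::setNames(lapply(compounds, function(cp) cp$fingerprint),
                  vapply(compounds, function(cp) cp$key, ""))
}

## JSON sidecar: key -> active bit positions (1-based)
write_fingerprint_sidecar <- function(fingerprints, path) {
  obj <- lapply(fingerprints, function(f)
    list(n_bits = f$n_bits, fp_type = f$fp_type,
         active_bits = which(as_bits(f) == 1L)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

read_fingerprint_sidecar <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stats::setNames(lapply(obj, function(o)
    fingerprint(unlist(o$active_bits), fp_type = o$fp_type,
                n_bits = o$n_bits, positions = TRUE)), names(obj))
}
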