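## Balanced spectrum-pair sampling across structural-similarity score bins,
## with on-the-fly augmentation of binned spectra. This counteracts the
## heavily left-skewed label distribution of all spectrum pairs: for each
## anchor a target score bin is drawn uniformly, then a partner whose label
## falls into that (iteratively widened) bin.

#' Augmentation settings for binned spectra
#'
#' Three operators are applied per training example, in order:
#' (1) low-intensity peak removal — a uniformly drawn fraction in
#' `[0, removal_max_fraction]` of the non-zero bins whose *pre-transform*
#' normalized intensity is below `removal_intensity_ceiling` is set to 0;
#' (2) peak intensity jitter — every remaining non-zero (post-transform)
#' bin value is multiplied by a factor uniform in
#' `[1 - jitter_max_fraction, 1 + jitter_max_fraction]`;
#' (3) new peak addition — a uniform count in `[0, max_new_peaks]` of
#' zero-intensity bins is set to values uniform in
#' `(0, new_peak_intensity_ceiling]` (post-transform scale).
#'
#' @param removal_max_fraction upper bound of the removed fraction
#'   (default 0.2).
#' @param removal_intensity_ceiling pre-transform intensity below which a
#'   bin is a removal candidate (default 0.4).
#' @param jitter_max_fraction maximal relative intensity change
#'   (default 0.4).
#' @param max_new_peaks maximal number of added peaks (default 10).
#' @param new_peak_intensity_ceiling upper bound of added intensities
#'   (default 0.01).
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(removal_max_fraction = 0.2,
                                removal_intensity_ceiling = 0.4,
                                jitter_max_fraction = 0.4,
                                max_new_peaks = 10,
                                new_peak_intensity_ceiling = 0.01) {
  stopifnot(removal_max_fraction >= 0, removal_max_fraction <= 1,
            jitter_max_fraction >= 0, jitter_max_fraction <= 1,
            max_new_peaks >= 0, new_peak_intensity_ceiling >= 0)
  structure(list(removal_max_fraction = removal_max_fraction,
                 removal_intensity_ceiling = removal_intensity_ceiling,
                 jitter_max_fraction = jitter_max_fraction,
                 max_new_peaks = as.integer(max_new_peaks),
                 new_peak_intensity_ceiling = new_peak_intensity_ceiling),
            class = "augmentation_config")
}

#' Pair-generator settings
#'
#' @param n_score_bins number of equal-width similarity bins over `[0, 1]`
#'   used for balanced sampling (default 10); bin i is
#'   `[i/n, (i+1)/n)`, the last bin closed at 1.
#' @param widen_step widening added to both bin edges per iteration when the
#'   drawn bin contains no label (default 0.1).
#' @param batch_size pairs per batch (default 32).
#' @param shuffle_seed optional integer; when given, the epoch's random
#'   stream (anchor order, bin draws, partner draws, augmentation) is seeded
#'   with it, as used for the fixed validation stream.
#' @param cycles_per_epoch number of passes over all spectra per epoch
#'   (default 1 for training; 10 is the convention for validation streams).
#' @param augmentation an [augmentation_config()].
#' @param augmentation_enabled logical; apply augmentation to both pair
#'   members when materializing batches.
#' @param compound_uniform logical; if `TRUE` (default) partner sampling is
#'   two-stage (uniform over eligible compounds, then uniform over that
#'   compound's spectra), avoiding over-weighting heavily re-measured
#'   compounds. `FALSE` samples uniformly over eligible spectra.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_score_bins = 10, widen_step = 0.1,
                             batch_size = 32, shuffle_seed = NULL,
                             cycles_per_epoch = 1,
                             augmentation = augmentation_config(),
                             augmentation_enabled = TRUE,
                             compound_uniform = TRUE) {
  stopifnot(is_count(n_score_bins), widen_step > 0, is_count(batch_size),
            is_count(cycles_per_epoch))
  structure(list(n_score_bins = as.integer(n_score_bins),
                 widen_step = widen_step, batch_size = as.integer(batch_size),
                 shuffle_seed = shuffle_seed,
                 cycles_per_epoch = as.integer(cycles_per_epoch),
                 augmentation = augmentation,
                 augmentation_enabled = isTRUE(augmentation_enabled),
                 compound_uniform = isTRUE(compound_uniform)),
            class = "generator_config")
}

## labels inside [low, high), closed at high when high has been clamped to 1
in_bin <- function(x, low, high) {
  if (high >= 1) x >= low & x <= 1 else x >= low & x < high
}

## Core sampler: pool_labels is the anchor's label against every pool
## element (numeric, aligned with the pool); pool_keys drives the
## compound-uniform stage; self_index excludes the anchor spectrum itself.
sample_partner_idx <- function(pool_labels, self_index, pool_keys, cfg) {
  n <- cfg$n_score_bins
  b <- sample.int(n, 1L) - 1L
  low <- b / n
  high <- (b + 1) / n
  eligible <- integer(0)
  repeat {
    eligible <- which(in_bin(pool_labels, low, high))
    if (!is.na(self_index)) eligible <- eligible[eligible != self_index]
    if (length(eligible) > 0) break
    if (low <= 0 && high >= 1)
      stop2("no eligible partner in pool")
    low <- max(0, low - cfg$widen_step)
    high <- min(1, high + cfg$widen_step)
  }
  pick <- if (cfg$compound_uniform) {
    keys <- unique(pool_keys[eligible])
    k <- keys[sample.int(length(keys), 1L)]
    members <- eligible[pool_keys[eligible] == k]
    members[sample.int(length(members), 1L)]
  } else {
    eligible[sample.int(length(eligible), 1L)]
  }
  list(index = pick, label = pool_labels[pick],
       bin_low = low, bin_high = high)
}

#' Sample a balanced partner for one anchor spectrum
#'
#' Draws a score bin uniformly among `n_score_bins`, widens it by
#' `widen_step` on both sides until at least one pool compound's label with
#' the anchor falls inside, then samples a compound (and one of its spectra)
#' uniformly from the eligible set. The anchor may be paired with another
#' spectrum of its own compound but never with itself; termination is
#' guaranteed because the fully widened bin `[0, 1]` contains at least the
#' anchor's self-compound label of 1 (when the pool holds a second spectrum
#' of that compound) or any other label.
#'
#' @param anchor an [ms_spectrum] or `binned_spectrum` with a compound key.
#' @param pool non-empty list of spectra/binned spectra (may contain the
#'   anchor itself, which is excluded by identifier).
#' @param labels a `similarity_labels` matrix covering all compound keys.
#' @param cfg a [generator_config()].
#' @return list with `partner` (the chosen pool element), `label`, and the
#'   bin actually used (`bin_low`, `bin_high`).
#' @export
sample_partner <- function(anchor, pool, labels, cfg = generator_config()) {
  if (length(pool) == 0) stop2("empty partner pool")
  anchor_key <- if (inherits(anchor, "binned_spectrum")) anchor$compound_key
                else compound_key(anchor)
  if (is.na(anchor_key) || !anchor_key %in% labels$compound_keys)
    stop2("anchor's compound key missing from label matrix")
  pool_keys <- vapply(pool, function(s)
    if (inherits(s, "binned_spectrum")) s$compound_key else compound_key(s), "")
  ids <- vapply(pool, function(s)
    if (inherits(s, "binned_spectrum")) s$source_id
    else s$metadata$identifier %||% NA_character_, "")
  anchor_id <- if (inherits(anchor, "binned_spectrum")) anchor$source_id
               else anchor$metadata$identifier %||% NA_character_
  self_index <- if (!is.na(anchor_id)) match(anchor_id, ids) else NA_integer_
  key_idx <- match(pool_keys, labels$compound_keys)
  if (anyNA(key_idx)) stop2("pool contains compound keys missing from labels")
  pool_labels <- labels$scores[match(anchor_key, labels$compound_keys), key_idx]
  r <- sample_partner_idx(pool_labels, self_index, pool_keys, cfg)
  list(partner = pool[[r$index]], label = r$label,
       bin_low = r$bin_low, bin_high = r$bin_high)
}

#' Augment a binned spectrum
#'
#' Applies removal, jitter and addition (see [augmentation_config()]) to a
#' binned intensity vector. Values never become negative, and at most
#' `max_new_peaks` zero bins are touched by the addition operator.
#'
#' @param b a `binned_spectrum` (its `raw_values` supply the pre-transform
#'   intensities used by the removal operator).
#' @param cfg an [augmentation_config()].
#' @return augmented `binned_spectrum`.
#' @export
augment_binned <- function(b, cfg = augmentation_config()) {
  v <- b$values
  raw <- b$raw_values
  ## (1) low-intensity peak removal (pre-transform scale)
  candidates <- which(v > 0 & raw < cfg$removal_intensity_ceiling)
  if (length(candidates) && cfg$removal_max_fraction > 0) {
    frac <- stats::runif(1, 0, cfg$removal_max_fraction)
    n_rm <- floor(frac * length(candidates))
    if (n_rm > 0) {
      rm_idx <- candidates[sample.int(length(candidates), n_rm)]
      v[rm_idx] <- 0
      raw[rm_idx] <- 0
    }
  }
  ## (2) multiplicative intensity jitter (post-transform scale)
  nz <- which(v > 0)
  if (length(nz) && cfg$jitter_max_fraction > 0) {
    f <- stats::runif(length(nz), 1 - cfg$jitter_max_fraction,
                      1 + cfg$jitter_max_fraction)
    v[nz] <- pmax(0, v[nz] * f)
    raw[nz] <- v[nz]^2                 # keep scales consistent
  }
  ## (3) new peak addition into zero bins
  if (cfg$max_new_peaks > 0 && cfg$new_peak_intensity_ceiling > 0) {
    zeros <- which(v == 0)
    k <- sample.int(cfg$max_new_peaks + 1L, 1L) - 1L
    k <- min(k, length(zeros))
    if (k > 0) {
      add_idx <- zeros[sample.int(length(zeros), k)]
      v[add_idx] <- stats::runif(k, 0, cfg$new_peak_intensity_ceiling)
      raw[add_idx] <- v[add_idx]^2
    }
  }
  b$values <- v
  b$raw_values <- raw
  b
}

#' Generate one epoch of balanced spectrum pairs
#'
#' Each cycle visits every spectrum exactly once as anchor in shuffled
#' order; each anchor is matched by [sample_partner()]. Pairs are grouped
#' into batches of `batch_size` (last batch may be short). The pair plan is
#' returned as indices plus a bookkeeping data frame; input matrices are
#' materialized lazily per batch with [batch_matrices()] so that large
#' epochs (e.g. 10-cycle validation streams) do not hold all inputs in
#' memory, and so that augmentation is drawn fresh at materialization time.
#'
#' @param binned list of `binned_spectrum` with compound keys.
#' @param labels a `similarity_labels` object.
#' @param cfg a [generator_config()]; `cfg$shuffle_seed`, when non-NULL,
#'   makes the pair plan reproducible without disturbing the caller's RNG.
#' @return object of class `epoch_pairs`: list with `pairs` (data frame:
#'   `anchor`, `partner` indices, `label`, `bin_low`, `bin_high`),
#'   `batches` (list of row-index vectors), `binned`, `cfg`.
#' @export
generate_epoch <- function(binned, labels, cfg = generator_config()) {
  if (length(binned) == 0) stop2("no spectra to generate pairs from")
  run <- function() {
    pool_keys <- vapply(binned, function(b) b$compound_key, "")
    if (anyNA(pool_keys)) stop2("all binned spectra need a compound key")
    missing <- setdiff(unique(pool_keys), labels$compound_keys)
    if (length(missing))
      stop2("compound keys missing from label matrix: ",
            paste(utils::head(missing, 3), collapse = ", "))
    key_idx <- match(pool_keys, labels$compound_keys)
    n <- length(binned)
    total <- n * cfg$cycles_per_epoch
    anchor <- integer(total); partner <- integer(total)
    lab <- numeric(total); blo <- numeric(total); bhi <- numeric(total)
    pos <- 0L
    for (cyc in seq_len(cfg$cycles_per_epoch)) {
      for (i in sample.int(n)) {
        pool_labels <- labels$scores[key_idx[i], key_idx]
        r <- sample_partner_idx(pool_labels, i, pool_keys, cfg)
        pos <- pos + 1L
        anchor[pos] <- i; partner[pos] <- r$index
        lab[pos] <- r$label; blo[pos] <- r$bin_low; bhi[pos] <- r$bin_high
      }
    }
    data.frame(anchor = anchor, partner = partner, label = lab,
               bin_low = blo, bin_high = bhi)
  }
  pairs <- if (is.null(cfg$shuffle_seed)) run()
           else with_seed(cfg$shuffle_seed, run())
  idx <- seq_len(nrow(pairs))
  batches <- split(idx, ceiling(idx / cfg$batch_size))
  structure(list(pairs = pairs, batches = unname(batches),
                 binned = binned, cfg = cfg),
            class = "epoch_pairs")
}

#' @export
print.epoch_pairs <- function(x, ...) {
  cat(sprintf("<epoch_pairs> %d pairs in %d batches (batch_size %d)\n",
              nrow(x$pairs), length(x$batches), x$cfg$batch_size))
  invisible(x)
}

#' Materialize the input matrices of one batch
#'
#' Builds the two input matrices (pairs x input_dim) and label vector for
#' batch `i` of an [generate_epoch()] plan, applying augmentation
#' independently to both pair members when enabled.
#'
#' @param epoch an `epoch_pairs` object.
#' @param i batch number.
#' @return list with matrices `a`, `b` and numeric `label`.
#' @export
batch_matrices <- function(epoch, i) {
  rows <- epoch$batches[[i]]
  cfg <- epoch$cfg
  fetch <- function(j) {
    b <- epoch$binned[[j]]
    if (cfg$augmentation_enabled) b <- augment_binned(b, cfg$augmentation)
    b$values
  }
  a <- do.call(rbind, lapply(epoch$pairs$anchor[rows], fetch))
  b <- do.call(rbind, lapply(epoch$pairs$partner[rows], fetch))
  list(a = a, b = b, label = epoch$pairs$label[rows])
}
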