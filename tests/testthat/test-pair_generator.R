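test_that("sample_partner draws labels inside the (widened) bin", {
  lib <- small_library()
  cfg <- generator_config()
  set.seed(30)
  for (i in sample(seq_along(lib$binned), 25)) {
    r <- sample_partner(lib$binned[[i]], lib$binned, lib$labels, cfg)
    expect_gte(r$label, r$bin_low)
    expect_true(r$label < r$bin_high || (r$bin_high >= 1 && r$label <= 1))
    expect_false(identical(r$partner$source_id, lib$binned[[i]]$source_id))
  }
})

test_that("widening reaches sparse labels and self-compound pairs exist", {
  ## two compounds only: labels are {cross, 1.0}; every drawn bin must
  ## resolve to one of the existing labels through widening
  k1 <- "AAAAAAAAAAAAAA"; k2 <- "BBBBBBBBBBBBBB"
  fps <- stats::setNames(list(fingerprint(c(1, 2, 3, 4), n_bits = 16,
                                          positions = TRUE),
                              fingerprint(c(3, 4, 5, 6), n_bits = 16,
                                          positions = TRUE)), c(k1, k2))
  labels <- build_label_matrix(fingerprints = fps)
  cross <- labels$scores[k1, k2]
  mk <- function(id, key) structure(
    list(values = c(1, 0), raw_values = c(1, 0), missing_fraction = 0,
         source_id = id, compound_key = key), class = "binned_spectrum")
  pool <- list(mk("a1", k1), mk("a2", k1), mk("b1", k2), mk("b2", k2))
  set.seed(31)
  labs <- replicate(200, sample_partner(pool[[1]], pool, labels,
                                        generator_config())$label)
  expect_true(all(labs %in% c(cross, 1.0)))
  expect_true(any(labs == 1.0))            # same-compound partner realized
  expect_true(any(labs == cross))
  expect_error(sample_partner(pool[[1]], list(), labels, generator_config()),
               "empty")
})

test_that("zero-magnitude augmentation is the identity", {
  lib <- small_library()
  b <- lib$binned[[1]]
  cfg <- augmentation_config(removal_max_fraction = 0,
                             jitter_max_fraction = 0, max_new_peaks = 0)
  set.seed(32)
  expect_identical(augment_binned(b, cfg)$values, b$values)
})

test_that("removal spares peaks with pre-transform intensity >= 0.4", {
  b <- structure(list(values = sqrt(c(0.5, 0.39, 0.41, 0.1, 0, 0.9)),
                      raw_values = c(0.5, 0.39, 0.41, 0.1, 0, 0.9),
                      missing_fraction = 0, source_id = "x",
                      compound_key = "K"), class = "binned_spectrum")
  cfg <- augmentation_config(removal_max_fraction = 1,
                             jitter_max_fraction = 0, max_new_peaks = 0)
  set.seed(33)
  for (i in 1:50) {
    a <- augment_binned(b, cfg)
    expect_true(all(a$values[c(1, 3, 6)] > 0))   # raw >= 0.4 never removed
    expect_true(all(a$values >= 0))
  }
})

test_that("addition touches at most max_new_peaks zero bins, values bounded", {
  zero <- structure(list(values = numeric(50), raw_values = numeric(50),
                         missing_fraction = 1, source_id = "z",
                         compound_key = "K"), class = "binned_spectrum")
  cfg <- augmentation_config()
  set.seed(34)
  for (i in 1:50) {
    a <- augment_binned(zero, cfg)
    nz <- which(a$values > 0)
    expect_lte(length(nz), cfg$max_new_peaks)
    expect_true(all(a$values[nz] <= cfg$new_peak_intensity_ceiling))
  }
})

test_that("jitter stays within +/- 40% and never goes negative", {
  b <- structure(list(values = c(0.2, 0.5, 1), raw_values = c(0.04, 0.25, 1),
                      missing_fraction = 0, source_id = "j",
                      compound_key = "K"), class = "binned_spectrum")
  cfg <- augmentation_config(removal_max_fraction = 0, max_new_peaks = 0,
                             jitter_max_fraction = 0.4)
  set.seed(35)
  for (i in 1:50) {
    a <- augment_binned(b, cfg)
    ratio <- a$values / b$values
    expect_true(all(ratio >= 0.6 - 1e-12 & ratio <= 1.4 + 1e-12))
  }
})

test_that("generate_epoch visits every spectrum once per cycle", {
  lib <- small_library()
  n <- length(lib$binned)
  cfg <- generator_config(batch_size = 32, cycles_per_epoch = 2,
                          shuffle_seed = 77)
  ep <- generate_epoch(lib$binned, lib$labels, cfg)
  expect_identical(nrow(ep$pairs), 2L * n)
  counts <- table(ep$pairs$anchor)
  expect_true(all(counts == 2))            # every spectrum anchors per cycle
  expect_identical(length(ep$batches), as.integer(ceiling(2 * n / 32)))
  ## fixed seed reproduces the exact pair sequence
  ep2 <- generate_epoch(lib$binned, lib$labels, cfg)
  expect_identical(ep$pairs, ep2$pairs)
})

test_that("batch materialization has the right shapes and labels", {
  lib <- small_library()
  cfg <- generator_config(batch_size = 16, shuffle_seed = 5,
                          augmentation_enabled = FALSE)
  ep <- generate_epoch(lib$binned, lib$labels, cfg)
  bm <- batch_matrices(ep, 1)
  d <- length(lib$scheme$known_bins)
  expect_identical(dim(bm$a), c(16L, d))
  expect_identical(dim(bm$b), c(16L, d))
  ## without augmentation the rows equal the stored binned vectors
  expect_equal(bm$a[1, ], lib$binned[[ep$pairs$anchor[1]]]$values)
  ## labels equal the label-matrix entries for the compound pair
  i <- ep$pairs$anchor[3]; j <- ep$pairs$partner[3]
  expect_equal(bm$label[3],
               label_of(lib$labels, lib$binned[[i]]$compound_key,
                        lib$binned[[j]]$compound_key))
})

test_that("balanced sampling flattens the label histogram (chi-square)", {
  lib <- small_library()
  cfg <- generator_config(shuffle_seed = 99, cycles_per_epoch = 10)
  ep <- generate_epoch(lib$binned, lib$labels, cfg)
  bins <- function(x) tabulate(pmin(floor(x * 10), 9) + 1, nbins = 10)
  sampled <- bins(ep$pairs$label)
  keys <- vapply(lib$binned, function(b) b$compound_key, "")
  idx <- match(keys, lib$labels$compound_keys)
  all_labels <- lib$labels$scores[idx, idx]
  raw <- bins(all_labels[upper.tri(all_labels)])
  chisq_vs_uniform <- function(h) {
    e <- sum(h) / length(h)
    sum((h - e)^2 / e)
  }
  expect_lt(chisq_vs_uniform(sampled / sum(sampled)),
            chisq_vs_uniform(raw / sum(raw)))
})
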