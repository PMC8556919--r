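test_that("build_model produces the configured shapes, seeded init", {
  cfg <- model_config(input_dim = 50, hidden_dims = c(8, 8),
                      embedding_dim = 4, seed = 3)
  m <- build_model(cfg)
  expect_identical(dim(m$params$W1), c(50L, 8L))
  expect_identical(dim(m$params$W_out), c(8L, 4L))
  e <- embed_spectra(m, runif(50))
  expect_identical(dim(e), c(1L, 4L))
  expect_true(all(is.finite(e)))
  m2 <- build_model(cfg)
  expect_identical(m$params, m2$params)      # same seed, same init
  m3 <- build_model(model_config(input_dim = 50, hidden_dims = c(8, 8),
                                 embedding_dim = 4, seed = 4))
  expect_false(identical(m$params$W1, m3$params$W1))
  expect_error(build_model(cfg, binning_scheme(10, 0, 10)), "known bins")
})

test_that("embedding is deterministic without dropout, stochastic with", {
  cfg <- model_config(input_dim = 30, hidden_dims = c(16, 16),
                      embedding_dim = 8, dropout_rate = 0.5, seed = 5)
  m <- build_model(cfg)
  x <- runif(30)
  expect_identical(embed_spectra(m, x), embed_spectra(m, x))
  set.seed(6)
  d1 <- embed_spectra(m, x, dropout_active = TRUE)
  d2 <- embed_spectra(m, x, dropout_active = TRUE)
  expect_false(identical(d1, d2))
  ## zero dropout rate: dropout-active pass equals the deterministic pass
  cfg0 <- model_config(input_dim = 30, hidden_dims = c(16, 16),
                       embedding_dim = 8, dropout_rate = 0, seed = 5)
  m0 <- build_model(cfg0)
  expect_identical(embed_spectra(m0, x, dropout_active = TRUE),
                   embed_spectra(m0, x))
  ## all-zero input still embeds (bias/batch-norm driven)
  expect_true(all(is.finite(embed_spectra(m, numeric(30)))))
  expect_error(embed_spectra(m, runif(29)), "features")
})

test_that("score_pair is a cosine with the documented edge cases", {
  e <- c(1, 2, 3)
  expect_equal(score_pair(e, e), 1.0)
  expect_equal(score_pair(e, -e), -1.0)
  expect_equal(score_pair(c(1, 0), c(0, 2)), 0.0)
  expect_equal(score_pair(e, 5 * e), 1.0)    # scale invariance
  expect_equal(score_pair(e, c(3, 2, 1)), score_pair(c(3, 2, 1), e))
  expect_error(score_pair(e, c(0, 0, 0)), "zero-norm")
  expect_error(score_pair(e, c(1, 2)), "lengths")
})

test_that("early stopping triggers after exactly patience non-improving epochs", {
  ## best at epoch 3; epochs 4-8 do not improve; patience 5 stops at 8
  losses <- c(1.0, 0.9, 0.8, 0.85, 0.86, 0.87, 0.88, 0.89, 0.7, 0.6)
  expect_identical(early_stopping_epoch(losses, patience = 5), 8L)
  expect_identical(early_stopping_epoch(c(0.5, 0.4, 0.3), patience = 5),
                   NA_integer_)
  ## a plateau (equal losses) counts as non-improving
  expect_identical(early_stopping_epoch(rep(0.5, 4), patience = 3), 4L)
  ## train_model agrees with the helper on its own history
  tm <- small_trained_model()
  h <- tm$model$history$val_loss
  stop_at <- early_stopping_epoch(h, tm$model$config$early_stop_patience)
  if (!is.na(stop_at)) expect_identical(nrow(tm$model$history), stop_at)
})

test_that("train_model refuses overlapping compound splits", {
  lib <- small_library()
  cfg <- model_config(input_dim = length(lib$scheme$known_bins),
                      hidden_dims = 8, embedding_dim = 4, max_epochs = 1)
  m <- build_model(cfg, lib$scheme)
  expect_error(train_model(m, lib$binned[1:6], lib$binned[4:9], lib$labels),
               "share compound keys")
})

test_that("training is deterministic given the seed and learns the toy set", {
  lib <- small_library()
  split <- split_by_compound(lib$keys, 6, 6, seed = 21)
  train_pool <- pool_by_keys(lib$binned, split$train)
  val_pool <- pool_by_keys(lib$binned, split$val)
  cfg <- model_config(input_dim = length(lib$scheme$known_bins),
                      hidden_dims = c(32, 32), embedding_dim = 16,
                      learning_rate = 0.005, max_epochs = 4,
                      early_stop_patience = 4, seed = 77)
  m1 <- train_model(build_model(cfg, lib$scheme), train_pool, val_pool,
                    lib$labels)
  m2 <- train_model(build_model(cfg, lib$scheme), train_pool, val_pool,
                    lib$labels)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("the network can overfit a tiny pool to near-zero training MSE", {
  ## capacity / optimization sanity: 20 spectra, augmentation off,
  ## training loss must be driven below 0.01
  lib <- small_library()
  split <- split_by_compound(lib$keys, 6, 6, seed = 22)
  train_pool <- pool_by_keys(lib$binned, split$train)[1:20]
  val_pool <- pool_by_keys(lib$binned, split$val)
  cfg <- model_config(input_dim = length(lib$scheme$known_bins),
                      hidden_dims = c(32, 32), embedding_dim = 16,
                      learning_rate = 0.01, dropout_rate = 0,
                      max_epochs = 200, early_stop_patience = 200,
                      restore_best = FALSE, seed = 23)
  gen <- generator_config(augmentation_enabled = FALSE)
  m <- train_model(build_model(cfg, lib$scheme), train_pool, val_pool,
                   lib$labels, gen_cfg = gen)
  expect_lt(min(m$history$train_loss), 0.01)
})

test_that("split_by_compound partitions disjointly and reproducibly", {
  keys <- sprintf("KEY%011d", 1:1000)
  s <- split_by_compound(keys, 100, 100, seed = 1)
  expect_length(s$train, 800L)
  expect_length(intersect(s$val, s$test), 0L)
  expect_length(intersect(s$train, c(s$val, s$test)), 0L)
  expect_setequal(c(s$train, s$val, s$test), keys)
  expect_identical(split_by_compound(keys, 100, 100, seed = 1), s)
  expect_error(split_by_compound(keys[1:10], 5, 5), "smaller")
})

test_that("model archives round trip bit-for-bit and validate on load", {
  tm <- small_trained_model()
  m <- tm$model
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir)
  x <- tm$lib$binned[[1]]
  expect_identical(embed_spectra(back, x), embed_spectra(m, x))
  expect_identical(back$config, m$config)
  expect_equal(back$binning$known_bins, m$binning$known_bins)
  ## incomplete archive refused
  dir2 <- withr::local_tempdir()
  save_model(m, dir2)
  unlink(file.path(dir2, "binning.json"))
  expect_error(load_model(dir2), "binning.json")
  ## version mismatch refused
  dir3 <- withr::local_tempdir()
  save_model(m, dir3)
  cfgj <- jsonlite::fromJSON(file.path(dir3, "config.json"))
  cfgj$archive_version <- "other-archive-9"
  jsonlite::write_json(cfgj, file.path(dir3, "config.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(dir3), "version mismatch")
})
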