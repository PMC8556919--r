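## hand-made score matrix for the arithmetic tests
toy_score_matrix <- function(pred, truth, keys = NULL) {
  ids <- paste0("s", seq_len(nrow(pred)))
  dimnames(pred) <- dimnames(truth) <- list(ids, ids)
  structure(list(ids = ids, predicted = pred, true_labels = truth,
                 compound_of = if (!is.null(keys))
                   stats::setNames(keys, ids) else NULL,
                 n_unique_pairs = nrow(pred) * (nrow(pred) + 1) / 2),
            class = "score_matrix")
}

test_that("all_vs_all counts unique pairs and matches per-pair scoring", {
  tm <- small_trained_model()
  binned <- tm$lib$binned[1:10]
  sm <- all_vs_all(tm$model, binned, tm$lib$labels)
  expect_equal(sm$n_unique_pairs, 10 * 11 / 2)
  expect_identical(sm$predicted, t(sm$predicted))
  ## oracle: full Siamese forward per pair (embed both sides, cosine)
  for (i in c(1, 4)) for (j in c(2, 9)) {
    e_i <- embed_spectra(tm$model, binned[[i]])
    e_j <- embed_spectra(tm$model, binned[[j]])
    expect_equal(sm$predicted[i, j], score_pair(e_i, e_j), tolerance = 1e-10)
  }
  expect_equal(unname(diag(sm$predicted)), rep(1, 10))
  ## true labels broadcast from compound level
  expect_equal(sm$true_labels[1, 4],
               label_of(tm$lib$labels, binned[[1]]$compound_key,
                        binned[[4]]$compound_key))
  expect_error(all_vs_all(tm$model, list()), "no spectra")
})

test_that("binned_errors matches hand-computed RMSE/MAE per label bin", {
  ## 4 spectra -> 6 non-self pairs with hand-set labels and predictions
  truth <- matrix(1, 4, 4)
  truth[1, 2] <- truth[2, 1] <- 0.05
  truth[1, 3] <- truth[3, 1] <- 0.12
  truth[1, 4] <- truth[4, 1] <- 0.95
  truth[2, 3] <- truth[3, 2] <- 0.55
  truth[2, 4] <- truth[4, 2] <- 0.58
  truth[3, 4] <- truth[4, 3] <- 1.00
  pred <- truth
  pred[1, 2] <- pred[2, 1] <- 0.15          # err 0.1 in bin [0, 0.1)
  pred[2, 3] <- pred[3, 2] <- 0.35          # err -0.2 in bin [0.5, 0.6)
  pred[2, 4] <- pred[4, 2] <- 0.68          # err 0.1 in bin [0.5, 0.6)
  sm <- toy_score_matrix(pred, truth)
  be <- binned_errors(sm, 10)
  expect_identical(sum(be$n_pairs), 6L)     # counts cover all unique pairs
  expect_equal(be$rmse[1], 0.1)                          # bin [0, 0.1)
  expect_equal(be$rmse[6], sqrt(mean(c(0.2, 0.1)^2)))    # bin [0.5, 0.6)
  expect_equal(be$mae[6], 0.15)
  expect_equal(be$rmse[10], 0)              # label 0.95 and 1.0, exact
  expect_true(is.na(be$rmse[4]))            # empty bin reported missing
  ## constant offset: every non-empty bin shows that offset as RMSE
  sm2 <- toy_score_matrix(truth + 0.1, truth)
  be2 <- binned_errors(sm2, 10)
  expect_equal(be2$rmse[!is.na(be2$rmse)],
               rep(0.1, sum(!is.na(be2$rmse))))
})

test_that("pooled RMSE equals count-weighted root-mean of per-bin MSE", {
  tm <- small_trained_model()
  sm <- all_vs_all(tm$model, tm$lib$binned[1:20], tm$lib$labels)
  be <- binned_errors(sm, 10)
  up <- upper.tri(sm$predicted)
  pooled <- sqrt(mean((sm$predicted[up] - sm$true_labels[up])^2))
  ok <- !is.na(be$rmse)
  recombined <- sqrt(sum(be$n_pairs[ok] * be$rmse[ok]^2) / sum(be$n_pairs[ok]))
  expect_equal(pooled, recombined)
})

test_that("precision/recall match a hand-counted 6-pair table", {
  truth <- matrix(1, 4, 4)
  truth[upper.tri(truth)] <- c(0.9, 0.2, 0.7, 0.1, 0.3, 0.8)
  truth[lower.tri(truth)] <- t(truth)[lower.tri(truth)]
  pred <- matrix(1, 4, 4)
  pred[upper.tri(pred)] <- c(0.85, 0.4, 0.6, 0.15, 0.55, 0.7)
  pred[lower.tri(pred)] <- t(pred)[lower.tri(pred)]
  sm <- toy_score_matrix(pred, truth)
  pr <- precision_recall_high_similarity(sm, 0.6, score_grid = c(0.5, 0.8))
  ## labels > 0.6: pairs with truth 0.9, 0.7, 0.8 (3 related of 6)
  ## X = 0.5: selected preds {0.85, 0.6, 0.55, 0.7} -> related {0.85,0.6,0.7}
  expect_equal(pr$precision[1], 3 / 4)
  expect_equal(pr$recall[1], 1.0)
  ## X = 0.8: selected {0.85} -> related {0.85}
  expect_equal(pr$precision[2], 1.0)
  expect_equal(pr$recall[2], 1 / 3)
  ## X below all predictions: recall 1, precision = prevalence
  pr0 <- precision_recall_high_similarity(sm, 0.6, score_grid = 0)
  expect_equal(pr0$recall, 1.0)
  expect_equal(pr0$precision, 3 / 6)
  ## recall is non-increasing along any grid
  prg <- precision_recall_high_similarity(sm, 0.6,
                                          score_grid = seq(0, 0.9, 0.05))
  expect_true(all(diff(prg$recall) <= 0))
  ## degenerate labels refused
  all_high <- toy_score_matrix(pred, matrix(0.9, 4, 4))
  expect_error(precision_recall_high_similarity(all_high, 0.6), "degenerate")
})

test_that("same-compound aggregation medians spectrum pairs per compound pair", {
  ## compounds: s1,s2,s3 -> A; s4 -> B
  pred <- diag(4)
  pred[1, 4] <- pred[4, 1] <- 0.2
  pred[2, 4] <- pred[4, 2] <- 0.5
  pred[3, 4] <- pred[4, 3] <- 0.8
  pred[1, 2] <- pred[2, 1] <- 0.91
  pred[1, 3] <- pred[3, 1] <- 0.93
  pred[2, 3] <- pred[3, 2] <- 0.99
  sm <- toy_score_matrix(pred, pred, keys = c("A", "A", "A", "B"))
  agg <- aggregate_same_compound(sm)
  ab <- agg[agg$key_a == "A" & agg$key_b == "B", ]
  expect_equal(ab$median, 0.5)              # median of {0.2, 0.5, 0.8}
  expect_identical(ab$n_spectrum_pairs, 3L)
  aa <- agg[agg$key_a == "A" & agg$key_b == "A", ]
  expect_equal(aa$median, 0.93)             # within-compound spectrum pairs
  ## IQR filter drops the spread-out pair, retained fraction matches count
  filt <- aggregate_same_compound(sm, iqr_threshold = 0.1)
  expect_identical(nrow(filt), 1L)
  expect_equal(attr(filt, "retained_fraction"), 0.5)
})

test_that("aggregation of a perfect predictor returns the label matrix", {
  tm <- small_trained_model()
  lib <- tm$lib
  binned <- lib$binned[1:12]
  keys <- vapply(binned, function(b) b$compound_key, "")
  idx <- match(keys, lib$labels$compound_keys)
  truth <- lib$labels$scores[idx, idx]
  sm <- toy_score_matrix(truth, truth, keys = keys)
  agg <- aggregate_same_compound(sm)
  for (r in seq_len(nrow(agg))) {
    expect_equal(agg$median[r],
                 label_of(lib$labels, agg$key_a[r], agg$key_b[r]))
    expect_equal(agg$iqr[r], 0)
  }
})

test_that("rmse_under_iqr_filter computes restricted RMSE and rate", {
  tab <- data.frame(median = c(0.1, 0.5, 0.9), iqr = c(0.01, 0.10, 0.30),
                    label = c(0.0, 0.5, 0.5))
  r <- rmse_under_iqr_filter(tab, 0.2)
  expect_equal(r$retrieval_rate, 2 / 3)
  expect_equal(r$rmse, sqrt(mean(c(0.1, 0)^2)))
  expect_true(is.na(rmse_under_iqr_filter(tab, 0)$rmse))
})
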