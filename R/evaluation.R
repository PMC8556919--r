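## Evaluation procedures: all-vs-all scoring, per-similarity-bin error
## reports, precision/recall for high-similarity retrieval, and aggregation
## of scores over spectra of the same compound pair.

#' All-vs-all score matrix
#'
#' Embeds every spectrum exactly once (deterministic inference pass) and
#' scores all unique unordered pairs — including self-pairs — by cosine;
#' for m spectra that is `m (m + 1) / 2` unique pairs. When a label matrix
#' is supplied, the compound-level structural-similarity labels are
#' broadcast to spectrum pairs.
#'
#' @param model a trained `siamese_model`.
#' @param binned non-empty list of `binned_spectrum`.
#' @param labels optional `similarity_labels` covering the spectra's
#'   compound keys.
#' @return object of class `score_matrix`: list with `ids`, `predicted`
#'   (symmetric m x m matrix), `true_labels` (symmetric matrix or `NULL`),
#'   `compound_of` (named key vector or `NULL`), `n_unique_pairs`.
#' @export
all_vs_all <- function(model, binned, labels = NULL) {
  if (length(binned) == 0) stop2("no spectra to score")
  E <- embed_spectra(model, binned)
  nrm <- sqrt(rowSums(E^2))
  if (any(nrm == 0)) stop2("zero-norm embedding")
  En <- E / nrm
  predicted <- En %*% t(En)
  predicted <- (predicted + t(predicted)) / 2   # exact float symmetry
  if (model$config$clip_predictions) predicted <- pmin(pmax(predicted, 0), 1)
  ids <- vapply(binned, function(b) b$source_id, "")
  dimnames(predicted) <- list(ids, ids)
  true_labels <- NULL
  compound_of <- NULL
  if (!is.null(labels)) {
    keys <- vapply(binned, function(b) b$compound_key, "")
    idx <- match(keys, labels$compound_keys)
    if (anyNA(idx)) stop2("compound keys missing from label matrix")
    true_labels <- labels$scores[idx, idx, drop = FALSE]
    dimnames(true_labels) <- list(ids, ids)
    compound_of <- stats::setNames(keys, ids)
  }
  m <- length(ids)
  structure(list(ids = ids, predicted = predicted, true_labels = true_labels,
                 compound_of = compound_of,
                 n_unique_pairs = m * (m + 1) / 2),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d spectra, %.0f unique pairs%s\n",
              length(x$ids), x$n_unique_pairs,
              if (is.null(x$true_labels)) "" else ", labels attached"))
  invisible(x)
}

## upper-triangle (i < j) indices: unique non-self pairs
upper_pairs <- function(m) which(upper.tri(matrix(0, m, m)))

#' Per-similarity-bin error report
#'
#' Assigns unique non-self spectrum pairs to `n_bins` equal bins of the
#' *true* structural-similarity label (last bin closed at 1) and reports
#' per-bin RMSE, MAE and pair counts. Self-pairs (a spectrum against
#' itself) are excluded; empty bins report `NA`, never 0.
#'
#' @param sm a `score_matrix` with `true_labels`.
#' @param n_bins number of label bins (default 10).
#' @return data frame with columns `bin_low`, `bin_high`, `n_pairs`,
#'   `rmse`, `mae`.
#' @export
binned_errors <- function(sm, n_bins = 10) {
  if (is.null(sm$true_labels)) stop2("score matrix carries no true labels")
  stopifnot(is_count(n_bins))
  m <- length(sm$ids)
  up <- upper_pairs(m)
  pred <- sm$predicted[up]
  truth <- sm$true_labels[up]
  bin <- pmin(floor(truth * n_bins), n_bins - 1)   # last bin closed at 1
  err <- pred - truth
  out <- data.frame(bin_low = (0:(n_bins - 1)) / n_bins,
                    bin_high = (1:n_bins) / n_bins,
                    n_pairs = NA_integer_, rmse = NA_real_, mae = NA_real_)
  for (b in 0:(n_bins - 1)) {
    sel <- bin == b
    out$n_pairs[b + 1] <- sum(sel)
    if (any(sel)) {
      out$rmse[b + 1] <- sqrt(mean(err[sel]^2))
      out$mae[b + 1] <- mean(abs(err[sel]))
    }
  }
  out
}

#' Precision/recall curve for high-structural-similarity retrieval
#'
#' Pairs whose true label exceeds `label_threshold` are the "related"
#' class. For each score threshold X in `score_grid`, the selection is the
#' set of unique non-self pairs with predicted score > X; precision is the
#' fraction of the selection that is related and recall the fraction of all
#' related pairs that is selected. Precision of an empty selection is
#' reported as `NA`.
#'
#' @param sm a `score_matrix` with `true_labels`.
#' @param label_threshold true-label cutoff defining relatedness
#'   (default 0.6).
#' @param score_grid increasing vector of prediction thresholds.
#' @return data frame with `threshold`, `n_selected`, `precision`,
#'   `recall`.
#' @export
precision_recall_high_similarity <- function(sm, label_threshold = 0.6,
                                             score_grid = seq(0, 0.95,
                                                              by = 0.05)) {
  if (is.null(sm$true_labels)) stop2("score matrix carries no true labels")
  m <- length(sm$ids)
  up <- upper_pairs(m)
  pred <- sm$predicted[up]
  related <- sm$true_labels[up] > label_threshold
  n_related <- sum(related)
  if (n_related == 0 || n_related == length(related))
    stop2("degenerate label distribution: no pairs ",
          if (n_related == 0) "above" else "below", " label threshold ",
          label_threshold)
  out <- lapply(score_grid, function(x) {
    sel <- pred > x
    n_sel <- sum(sel)
    data.frame(threshold = x, n_selected = n_sel,
               precision = if (n_sel) sum(related[sel]) / n_sel else NA_real_,
               recall = sum(related[sel]) / n_related)
  })
  do.call(rbind, out)
}

#' Aggregate spectrum-pair scores per compound pair
#'
#' Collects all predicted spectrum-pair scores for each unordered compound
#' pair (within-compound pairs use distinct-spectrum pairs only) and
#' returns their median and IQR. With `iqr_threshold`, compound pairs with
#' `IQR >= threshold` are dropped and the retained fraction reported —
#' aggregation plus outlier removal for repeatedly measured compounds.
#'
#' @param sm a `score_matrix`.
#' @param compound_of named character vector mapping spectrum id to
#'   compound key; defaults to the mapping stored in `sm`.
#' @param iqr_threshold optional IQR cutoff (strictly-below retained).
#' @return data frame `key_a`, `key_b`, `median`, `iqr`, `n_spectrum_pairs`
#'   (attribute `retained_fraction` when filtering).
#' @export
aggregate_same_compound <- function(sm, compound_of = sm$compound_of,
                                    iqr_threshold = NULL) {
  if (is.null(compound_of)) stop2("no spectrum-to-compound mapping available")
  keys <- unname(compound_of[sm$ids])
  if (anyNA(keys)) stop2("every spectrum id must map to a compound key")
  m <- length(sm$ids)
  up <- upper_pairs(m)
  ii <- row(sm$predicted)[up]
  jj <- col(sm$predicted)[up]
  pred <- sm$predicted[up]
  ka <- keys[ii]; kb <- keys[jj]
  swap <- ka > kb
  tmp <- ka[swap]; ka[swap] <- kb[swap]; kb[swap] <- tmp
  grp <- paste(ka, kb, sep = "|")
  agg <- lapply(split(seq_along(grp), grp), function(rows) {
    q <- stats::quantile(pred[rows], c(0.25, 0.5, 0.75), names = FALSE,
                         type = 7)
    data.frame(key_a = ka[rows[1]], key_b = kb[rows[1]], median = q[2],
               iqr = q[3] - q[1], n_spectrum_pairs = length(rows))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  if (!is.null(iqr_threshold)) {
    keep <- out$iqr < iqr_threshold
    retained <- mean(keep)
    out <- out[keep, , drop = FALSE]
    attr(out, "retained_fraction") <- retained
  }
  out
}

#' Error of predictions against labels under an IQR filter
#'
#' Helper for uncertainty evaluation: given a Monte-Carlo score table (see
#' [mc_score_table()]) joined with true labels, computes the RMSE of the
#' median scores restricted to rows with `iqr < threshold`, plus the
#' retrieval rate.
#'
#' @param table data frame with columns `median`, `iqr`, `label`.
#' @param threshold IQR threshold.
#' @return list with `rmse` (NA when nothing is retained),
#'   `retrieval_rate`, `n`.
#' @export
rmse_under_iqr_filter <- function(table, threshold) {
  keep <- table$iqr < threshold
  list(rmse = if (any(keep))
         sqrt(mean((table$median[keep] - table$label[keep])^2)) else NA_real_,
       retrieval_rate = mean(keep), n = sum(keep))
}

## TSV + JSON report writers used by the CLI
write_evaluation_reports <- function(sm, out_dir, n_bins = 10,
                                     label_threshold = 0.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  be <- binned_errors(sm, n_bins)
  utils::write.table(be, file.path(out_dir, "binned_errors.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pr <- precision_recall_high_similarity(sm, label_threshold)
  utils::write.table(pr, file.path(out_dir, "precision_recall.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  m <- length(sm$ids)
  up <- upper_pairs(m)
  pooled_rmse <- sqrt(mean((sm$predicted[up] - sm$true_labels[up])^2))
  jsonlite::write_json(list(n_spectra = m,
                            n_unique_pairs = sm$n_unique_pairs,
                            pooled_rmse = pooled_rmse,
                            pooled_mae = mean(abs(sm$predicted[up] -
                                                    sm$true_labels[up]))),
                       file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
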