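## Monte-Carlo-dropout ensembling: n embeddings per spectrum with dropout
## kept active, n x n cosine score samples per pair, summarized by median
## and interquartile range; filtering by IQR trades retrieval rate for
## precision.

#' Ensemble (Monte-Carlo dropout) settings
#'
#' @param n_draws embeddings sampled per spectrum (default 10, giving
#'   `n_draws^2 = 100` score samples per pair).
#' @param iqr_low,iqr_high quantile levels of the spread measure
#'   (defaults 0.25 and 0.75, i.e. the interquartile range).
#' @param seed integer; each spectrum's draws are seeded from this and the
#'   spectrum identifier, so the same spectrum gets the same draw set in
#'   every pairing.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_draws = 10, iqr_low = 0.25, iqr_high = 0.75,
                            seed = 42) {
  stopifnot(is_count(n_draws), iqr_low >= 0, iqr_low < iqr_high,
            iqr_high <= 1)
  structure(list(n_draws = as.integer(n_draws), iqr_low = iqr_low,
                 iqr_high = iqr_high, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Sample Monte-Carlo-dropout embeddings for one spectrum
#'
#' Runs `n_draws` forward passes with dropout kept active (batch-norm in
#' inference mode), each pass silencing a random subset of nodes in the
#' dropout-carrying hidden layers. Draws are seeded per spectrum
#' identifier, so they are reproducible and independent of pairing order.
#'
#' @param model a trained `siamese_model`.
#' @param b a `binned_spectrum` (or numeric input vector).
#' @param cfg an [ensemble_config()].
#' @return matrix of `n_draws` rows x `embedding_dim` columns.
#' @export
mc_embeddings <- function(model, b, cfg = ensemble_config()) {
  sid <- if (inherits(b, "binned_spectrum")) b$source_id else "input"
  if (is.null(sid) || is.na(sid)) sid <- "input"
  X <- as_input_matrix(b)
  X <- X[rep(1L, cfg$n_draws), , drop = FALSE]
  ## one batched pass: dropout masks are drawn independently per row
  with_seed(derive_seed(cfg$seed, hash_string(sid %||% "input")),
            embed_spectra(model, X, dropout_active = TRUE))
}

#' Summarize an ensemble of pairwise scores
#'
#' Computes all `n_draws^2` cosine scores between the two draw sets and
#' returns their median and interquartile range (linear-interpolation
#' quantiles). Zero-norm draws are skipped with a warning; if every sample
#' is skipped an error is raised.
#'
#' @param draws_a,draws_b embedding matrices from [mc_embeddings()].
#' @param cfg an [ensemble_config()].
#' @return object of class `ensemble_score`: list with `median`, `iqr`,
#'   `n_samples`.
#' @export
ensemble_score <- function(draws_a, draws_b, cfg = ensemble_config()) {
  na <- sqrt(rowSums(draws_a^2))
  nb <- sqrt(rowSums(draws_b^2))
  bad_a <- na == 0; bad_b <- nb == 0
  if (any(bad_a) || any(bad_b)) {
    warning(sum(bad_a) + sum(bad_b), " zero-norm draw(s) skipped",
            call. = FALSE)
    draws_a <- draws_a[!bad_a, , drop = FALSE]; na <- na[!bad_a]
    draws_b <- draws_b[!bad_b, , drop = FALSE]; nb <- nb[!bad_b]
  }
  if (nrow(draws_a) == 0 || nrow(draws_b) == 0)
    stop2("all ensemble draws had zero norm")
  S <- (draws_a / na) %*% t(draws_b / nb)
  q <- stats::quantile(S, c(cfg$iqr_low, 0.5, cfg$iqr_high), names = FALSE,
                       type = 7)
  structure(list(median = q[2], iqr = q[3] - q[1], n_samples = length(S)),
            class = "ensemble_score")
}

#' @export
print.ensemble_score <- function(x, ...) {
  cat(sprintf("<ensemble_score> median %.4f, IQR %.4f (n = %d)\n",
              x$median, x$iqr, x$n_samples))
  invisible(x)
}

#' Filter ensemble scores by uncertainty
#'
#' Retains the scores whose IQR is strictly below `threshold`; the
#' retrieval rate is the retained fraction.
#'
#' @param scores list of `ensemble_score` objects, or a data frame with an
#'   `iqr` column.
#' @param threshold IQR threshold (>= 0); strict inequality.
#' @return list with `retained` (same container type as the input) and
#'   `retrieval_rate`.
#' @export
filter_by_iqr <- function(scores, threshold) {
  stopifnot(threshold >= 0)
  if (is.data.frame(scores)) {
    if (nrow(scores) == 0) stop2("no scores to filter")
    keep <- scores$iqr < threshold
    return(list(retained = scores[keep, , drop = FALSE],
                retrieval_rate = mean(keep)))
  }
  if (length(scores) == 0) stop2("no scores to filter")
  iqrs <- vapply(scores, function(s) s$iqr, 0)
  keep <- iqrs < threshold
  list(retained = scores[keep], retrieval_rate = mean(keep))
}

#' All-vs-all Monte-Carlo-dropout score table
#'
#' Embeds every spectrum `n_draws` times (never per pair), then summarizes
#' every unordered spectrum pair by the median and IQR of its
#' `n_draws^2` score samples.
#'
#' @param model a trained `siamese_model`.
#' @param binned list of `binned_spectrum`.
#' @param cfg an [ensemble_config()].
#' @param include_self include self-pairs (default `FALSE`).
#' @return data frame with columns `id_a`, `id_b`, `median`, `iqr`,
#'   `n_samples`.
#' @export
mc_score_table <- function(model, binned, cfg = ensemble_config(),
                           include_self = FALSE) {
  m <- length(binned)
  draws <- lapply(binned, mc_embeddings, model = model, cfg = cfg)
  norm <- lapply(draws, function(D) D / sqrt(rowSums(D^2)))
  ids <- vapply(binned, function(b) b$source_id, "")
  rows <- list()
  k <- 0L
  for (i in seq_len(m)) {
    for (j in if (include_self) i:m else if (i < m) (i + 1L):m else integer(0)) {
      S <- norm[[i]] %*% t(norm[[j]])
      q <- stats::quantile(S, c(cfg$iqr_low, 0.5, cfg$iqr_high),
                           names = FALSE, type = 7)
      k <- k + 1L
      rows[[k]] <- data.frame(id_a = ids[i], id_b = ids[j], median = q[2],
                              iqr = q[3] - q[1], n_samples = length(S))
    }
  }
  do.call(rbind, rows)
}
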