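## The Siamese model: configuration, construction, training with early
## stopping, embedding, pair scoring, persistence, and compound-level data
## splitting.

#' Model configuration
#'
#' Architecture and optimization settings for the Siamese network. The
#' reference architecture is input -> dense(500, L1+L2 regularized) ->
#' batch-norm -> ReLU -> dense(500) -> batch-norm -> ReLU -> dropout(0.2) ->
#' dense(200, linear), scored by the cosine of the two embeddings and
#' trained with Adam on the mean squared error against the structural
#' similarity label.
#'
#' @param input_dim length of the binned input vector (= number of known
#'   bins of the binning scheme).
#' @param hidden_dims sizes of the hidden dense layers (default `c(500, 500)`).
#' @param embedding_dim embedding size (default 200).
#' @param dropout_rate dropout rate in `[0, 1)` (default 0.2).
#' @param l1_penalty,l2_penalty weight-regularization strengths applied to
#'   the first dense layer (defaults 1e-6 each).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size training batch size (default 32).
#' @param early_stop_patience stop after this many consecutive epochs
#'   without validation-loss improvement (default 5).
#' @param max_epochs hard epoch cap (default 100).
#' @param seed integer seeding weight init, pair sampling, dropout.
#' @param dropout_from_layer first hidden layer (1-based) that carries
#'   dropout; default 2, i.e. the first dense layer has L1/L2 but no
#'   dropout.
#' @param restore_best restore the best-validation-epoch weights after
#'   early stopping (default `TRUE`).
#' @param ema_decay exponential-moving-average decay for Polyak weight
#'   averaging, applied per epoch; 0 (default) disables it. When active,
#'   the averaged weights replace the final weights after training
#'   (`restore_best` then refers to the averaged trajectory's best epoch
#'   and is usually disabled). Averaging the tail of a noisy small-batch
#'   trajectory stabilizes the final model.
#' @param clip_predictions clip cosine scores into `[0, 1]` when predicting
#'   (default `FALSE`; scores are reported raw).
#' @param bn_momentum,bn_epsilon batch-norm running-average momentum and
#'   variance floor.
#' @return object of class `model_config`.
#' @export
model_config <- function(input_dim, hidden_dims = c(500, 500),
                         embedding_dim = 200, dropout_rate = 0.2,
                         l1_penalty = 1e-6, l2_penalty = 1e-6,
                         learning_rate = 0.001, batch_size = 32,
                         early_stop_patience = 5, max_epochs = 100,
                         seed = 42, dropout_from_layer = 2,
                         restore_best = TRUE, clip_predictions = FALSE,
                         bn_momentum = 0.9, bn_epsilon = 1e-3,
                         ema_decay = 0) {
  stopifnot(is_count(input_dim), all(vapply(hidden_dims, is_count, TRUE)),
            is_count(embedding_dim), dropout_rate >= 0, dropout_rate < 1,
            l1_penalty >= 0, l2_penalty >= 0, learning_rate > 0,
            is_count(batch_size), is_count(early_stop_patience),
            is_count(max_epochs), ema_decay >= 0, ema_decay < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 embedding_dim = as.integer(embedding_dim),
                 dropout_rate = as.numeric(dropout_rate),
                 l1_penalty = as.numeric(l1_penalty),
                 l2_penalty = as.numeric(l2_penalty),
                 learning_rate = as.numeric(learning_rate),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 dropout_from_layer = as.integer(dropout_from_layer),
                 restore_best = isTRUE(restore_best),
                 clip_predictions = isTRUE(clip_predictions),
                 bn_momentum = as.numeric(bn_momentum),
                 bn_epsilon = as.numeric(bn_epsilon),
                 ema_decay = as.numeric(ema_decay)),
            class = "model_config")
}

#' Build an (untrained) Siamese model
#'
#' Initializes base-network weights (Glorot-uniform, seeded by
#' `cfg$seed`) for the configured architecture. The head of the Siamese
#' network is parameter-free (cosine of the two embeddings).
#'
#' @param cfg a [model_config()].
#' @param binning optional [binning_scheme()]; when given, its number of
#'   known bins must equal `cfg$input_dim` and the scheme travels with the
#'   model into saved archives.
#' @return object of class `siamese_model`.
#' @export
build_model <- function(cfg, binning = NULL) {
  if (!is.null(binning) && length(binning$known_bins) != cfg$input_dim)
    stop2("binning scheme has ", length(binning$known_bins),
          " known bins but cfg$input_dim = ", cfg$input_dim)
  params <- with_seed(cfg$seed, init_params(cfg))
  structure(list(config = cfg, params = params,
                 bn_stats = init_bn_stats(cfg), binning = binning,
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0)),
                 label_metadata = NULL, trained = FALSE),
            class = "siamese_model")
}

#' @export
print.siamese_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<siamese_model> %d -> %s -> %d embedding, dropout %.2g",
                     " (%strained%s)\n"),
              cfg$input_dim, paste(cfg$hidden_dims, collapse = " -> "),
              cfg$embedding_dim, cfg$dropout_rate,
              if (x$trained) "" else "un",
              if (nrow(x$history)) paste0(", ", nrow(x$history), " epochs")
              else ""))
  invisible(x)
}

as_input_matrix <- function(x) {
  if (inherits(x, "binned_spectrum")) matrix(x$values, nrow = 1)
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, nrow = 1)
  else if (is.list(x)) do.call(rbind, lapply(x, function(b)
    if (inherits(b, "binned_spectrum")) b$values else as.numeric(b)))
  else stop2("cannot coerce input to a matrix of binned vectors")
}

#' Embed binned spectra
#'
#' Runs the base network forward. With `dropout_active = FALSE` (default)
#' the pass is deterministic (batch-norm uses running statistics, no
#' dropout); with `dropout_active = TRUE` a Monte-Carlo-dropout sample of
#' the perturbed network is drawn.
#'
#' @param model a `siamese_model`.
#' @param x a `binned_spectrum`, a numeric vector, a list of binned spectra
#'   or a matrix (rows = spectra).
#' @param dropout_active sample dropout masks at inference.
#' @return an embedding matrix (rows = spectra, `embedding_dim` columns);
#'   a single input yields a 1-row matrix.
#' @export
embed_spectra <- function(model, x, dropout_active = FALSE) {
  X <- as_input_matrix(x)
  forward_base(model$params, model$bn_stats, model$config, X,
               training = FALSE, dropout_on = dropout_active,
               update_bn = FALSE)$E
}

#' Cosine score of two embeddings
#'
#' The Siamese head: cosine similarity of two embedding vectors, reported
#' raw (may fall slightly outside `[0, 1]`); it is the model's estimate of
#' the structural-similarity (Tanimoto/Dice) label.
#'
#' @param e1,e2 numeric vectors (or 1-row matrices) of equal length; must
#'   have non-zero norm.
#' @return cosine similarity in `[-1, 1]`.
#' @export
score_pair <- function(e1, e2) {
  e1 <- as.numeric(e1); e2 <- as.numeric(e2)
  if (length(e1) != length(e2)) stop2("embedding lengths differ")
  n1 <- sqrt(sum(e1^2)); n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0) stop2("zero-norm embedding")
  sum(e1 * e2) / (n1 * n2)
}

#' Epoch at which early stopping halts training
#'
#' Implements the patience rule used by [train_model()]: the best (lowest)
#' validation loss so far is tracked; an epoch that does not improve on it
#' increments a wait counter, an improving epoch resets it, and training
#' stops after the epoch at which the counter reaches `patience`.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @return the 1-based epoch index after which training stops, or `NA` if
#'   the sequence never exhausts the patience.
#' @export
early_stopping_epoch <- function(val_losses, patience = 5) {
  best <- Inf
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  NA_integer_
}

#' Split compounds into training / validation / test sets
#'
#' Uniform random disjoint selection of compound keys; all spectra of a
#' compound travel with its key, so splits never share a compound.
#'
#' @param compound_keys character vector of unique compound keys.
#' @param n_val,n_test number of keys for validation and test.
#' @param seed integer seed.
#' @return list with character vectors `train`, `val`, `test`.
#' @export
split_by_compound <- function(compound_keys, n_val, n_test, seed = 42) {
  compound_keys <- unique(compound_keys)
  K <- length(compound_keys)
  if (n_val + n_test >= K)
    stop2("n_val + n_test must be smaller than the number of keys (", K, ")")
  with_seed(seed, {
    held <- sample(compound_keys, n_val + n_test)
    list(train = setdiff(compound_keys, held),
         val = held[seq_len(n_val)],
         test = held[n_val + seq_len(n_test)])
  })
}

## mean data MSE over an epoch plan, eval mode (used for validation)
evaluate_stream_loss <- function(model, epoch) {
  total <- 0
  n <- 0
  for (i in seq_along(epoch$batches)) {
    bm <- batch_matrices(epoch, i)
    Ea <- forward_base(model$params, model$bn_stats, model$config, bm$a)$E
    Eb <- forward_base(model$params, model$bn_stats, model$config, bm$b)$E
    s <- cosine_rows(Ea, Eb)
    total <- total + sum((s - bm$label)^2)
    n <- n + length(s)
  }
  total / n
}

#' Train the Siamese model
#'
#' Per epoch: one pass of balanced pair batches from [generate_epoch()]
#' (augmentation on by default), forward through both branches of the
#' shared base network in training mode, backprop of the mean squared error
#' of the cosine score against the structural-similarity label (plus L1/L2
#' penalty on the first layer), Adam updates; then the validation loss on a
#' fixed-seed validation pair stream evaluated in inference mode. Training
#' stops when the validation loss has not improved for
#' `early_stop_patience` epochs (see [early_stopping_epoch()]) or at
#' `max_epochs`; the best-validation weights are restored when
#' `restore_best` is set.
#'
#' Training and validation pools must not share any compound key (data
#' leakage guard).
#'
#' @param model an untrained or pre-trained `siamese_model`.
#' @param train_binned,val_binned lists of `binned_spectrum` with compound
#'   keys.
#' @param labels a `similarity_labels` matrix covering both pools.
#' @param gen_cfg training [generator_config()].
#' @param val_cfg validation generator config; default: 10 cycles, fixed
#'   seed derived from `model$config$seed`, no augmentation.
#' @param verbose print per-epoch losses.
#' @return the trained `siamese_model` with `$history` filled in.
#' @export
train_model <- function(model, train_binned, val_binned, labels,
                        gen_cfg = generator_config(),
                        val_cfg = NULL, verbose = FALSE) {
  cfg <- model$config
  train_keys <- unique(vapply(train_binned, function(b) b$compound_key, ""))
  val_keys <- unique(vapply(val_binned, function(b) b$compound_key, ""))
  overlap <- intersect(train_keys, val_keys)
  if (length(overlap))
    stop2("training and validation pools share compound keys (e.g. ",
          overlap[1], "); split by compound first")
  if (is.null(val_cfg))
    val_cfg <- generator_config(n_score_bins = gen_cfg$n_score_bins,
                                widen_step = gen_cfg$widen_step,
                                batch_size = gen_cfg$batch_size,
                                shuffle_seed = derive_seed(cfg$seed, 7919),
                                cycles_per_epoch = 10,
                                augmentation_enabled = FALSE,
                                compound_uniform = gen_cfg$compound_uniform)
  set.seed(derive_seed(cfg$seed, 1))
  val_epoch <- generate_epoch(val_binned, labels, val_cfg)
  adam <- init_adam(model$params)
  best_loss <- Inf
  best <- NULL
  wait <- 0L
  ema <- NULL
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  model$label_metadata <- list(fp_type = labels$fp_type,
                               metric = labels$metric)
  for (ep in seq_len(cfg$max_epochs)) {
    epoch <- generate_epoch(train_binned, labels, gen_cfg)
    tot <- 0; npair <- 0
    for (bi in seq_along(epoch$batches)) {
      bm <- batch_matrices(epoch, bi)
      fa <- forward_base(model$params, model$bn_stats, cfg, bm$a,
                         training = TRUE, keep_cache = TRUE)
      model$bn_stats <- fa$bn_stats
      fb <- forward_base(model$params, model$bn_stats, cfg, bm$b,
                         training = TRUE, keep_cache = TRUE)
      model$bn_stats <- fb$bn_stats
      head <- cosine_mse_grad(fa$E, fb$E, bm$label)
      grads <- backward_base(model$params, cfg, fa$cache, head$dEa)
      grads <- add_grads(grads, backward_base(model$params, cfg, fb$cache,
                                              head$dEb))
      grads <- add_reg_grad(grads, model$params, cfg)
      upd <- adam_step(model$params, grads, adam, cfg$learning_rate)
      model$params <- upd$params
      adam <- upd$state
      tot <- tot + head$loss * length(bm$label)
      npair <- npair + length(bm$label)
    }
    train_loss <- tot / npair
    if (cfg$ema_decay > 0) {
      if (is.null(ema)) ema <- model$params
      else for (nm in names(ema))
        ema[[nm]] <- cfg$ema_decay * ema[[nm]] +
          (1 - cfg$ema_decay) * model$params[[nm]]
    }
    val_loss <- evaluate_stream_loss(model, val_epoch)
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, train_loss,
                      val_loss))
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best <- list(params = model$params, bn_stats = model$bn_stats,
                   epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  if (cfg$restore_best && !is.null(best)) {
    model$params <- best$params
    model$bn_stats <- best$bn_stats
  } else if (cfg$ema_decay > 0 && !is.null(ema)) {
    model$params <- ema
  }
  model$history <- history
  model$trained <- TRUE
  model
}

ARCHIVE_VERSION <- "specsimnet-archive-1"

#' Save / load a model archive
#'
#' The archive is a directory holding `weights.json` (all weights and
#' batch-norm running statistics, 17 significant digits so embeddings
#' reproduce bit-for-bit), `config.json` (architecture, label metadata and
#' archive version), `binning.json` (the binning scheme) and `history.csv`.
#' `load_model` refuses archives with a mismatching version tag, a missing
#' binning scheme, or a binning scheme whose known-bin count disagrees with
#' the configured input dimension.
#'
#' @param model a `siamese_model` (must carry a binning scheme).
#' @param path archive directory (created if needed).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `siamese_model`.
#' @export
save_model <- function(model, path) {
  if (is.null(model$binning))
    stop2("model carries no binning scheme; attach one before saving")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(params = model$params, bn_stats = model$bn_stats),
                       file.path(path, "weights.json"), digits = I(17),
                       matrix = "rowmajor")
  cfg <- unclass(model$config)
  jsonlite::write_json(list(archive_version = ARCHIVE_VERSION, config = cfg,
                            label_metadata = model$label_metadata,
                            trained = model$trained),
                       file.path(path, "config.json"), auto_unbox = TRUE,
                       digits = I(17))
  write_binning_scheme(model$binning, file.path(path, "binning.json"))
  utils::write.csv(model$history, file.path(path, "history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  need <- c("weights.json", "config.json", "binning.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop2("incomplete model archive, missing: ", paste(missing, collapse = ", "))
  meta <- jsonlite::fromJSON(file.path(path, "config.json"))
  if (!identical(meta$archive_version, ARCHIVE_VERSION))
    stop2("archive version mismatch: archive has '", meta$archive_version,
          "', this package reads '", ARCHIVE_VERSION, "'")
  cfg <- do.call(model_config, meta$config[names(meta$config) %in%
                                             names(formals(model_config))])
  binning <- read_binning_scheme(file.path(path, "binning.json"))
  if (length(binning$known_bins) != cfg$input_dim)
    stop2("binning scheme (", length(binning$known_bins),
          " known bins) does not match input_dim (", cfg$input_dim, ")")
  w <- jsonlite::fromJSON(file.path(path, "weights.json"),
                          simplifyDataFrame = FALSE)
  params <- w$params
  H <- length(cfg$hidden_dims)
  for (i in seq_len(H)) {
    for (nm in paste0(c("b", "gamma", "beta"), i))
      params[[nm]] <- as.numeric(params[[nm]])
  }
  params$b_out <- as.numeric(params$b_out)
  bn_stats <- lapply(w$bn_stats, function(s)
    list(mean = as.numeric(s$mean), var = as.numeric(s$var)))
  history <- if (file.exists(file.path(path, "history.csv")))
    utils::read.csv(file.path(path, "history.csv"))
  else data.frame(epoch = integer(0), train_loss = numeric(0),
                  val_loss = numeric(0))
  structure(list(config = cfg, params = params, bn_stats = bn_stats,
                 binning = binning, history = history,
                 label_metadata = meta$label_metadata,
                 trained = isTRUE(meta$trained)),
            class = "siamese_model")
}
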