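#' Configuration of the recurrent deep-feature extractor
#'
#' Hyperparameters of the GRU (or Bi-GRU) extractor. The defaults are the
#' tuned operating point of the method: input length 1200 nt, a learned
#' 50-dimensional nucleotide embedding, 20 hidden units, learning rate
#' 0.001 and batch size 16. The hidden activations are max-pooled along
#' the hidden axis in two stages (kernel sizes `pool1_size` then
#' `pool2_size`, partial windows kept) and the remaining channels
#' max-merged, leaving one value per sequence position — hence a deep
#' feature vector of dimension `seq_length` (1200 by default) for both the
#' unidirectional and the bidirectional variant.
#'
#' @param seq_length Input/encoding length in nucleotides (feature
#'   dimension D equals this).
#' @param embedding_dim Dimension of the learned per-base embedding.
#' @param hidden_units GRU hidden state size (per direction).
#' @param bidirectional Use a Bi-GRU (forward + backward pass,
#'   position-wise concatenated before pooling).
#' @param pool1_size,pool2_size Kernel sizes of the two max-pool stages
#'   over the hidden axis.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without improvement of
#'   the internal validation loss); set to `Inf` to disable.
#' @param validation_fraction Fraction of the training set held out
#'   internally for early stopping.
#' @param seed Integer seed: initialization and batch shuffling are fully
#'   determined by it.
#' @return An `ncp_extractor_config` list.
#' @export
extractor_config <- function(seq_length = 1200, embedding_dim = 50,
                             hidden_units = 20, bidirectional = FALSE,
                             pool1_size = 5, pool2_size = 3,
                             learning_rate = 0.001, batch_size = 16,
                             epochs = 30, patience = 5,
                             validation_fraction = 0.15, seed = 1) {
  cfg <- list(seq_length = as.integer(seq_length),
              embedding_dim = as.integer(embedding_dim),
              hidden_units = as.integer(hidden_units),
              bidirectional = isTRUE(bidirectional),
              pool1_size = as.integer(pool1_size),
              pool2_size = as.integer(pool2_size),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), patience = patience,
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  sizes <- c(cfg$seq_length, cfg$embedding_dim, cfg$hidden_units,
             cfg$pool1_size, cfg$pool2_size, cfg$batch_size, cfg$epochs)
  if (any(sizes < 1L)) stop("all sizes must be positive integers")
  channels <- cfg$hidden_units * (1L + cfg$bidirectional)
  pooled <- ceiling(ceiling(channels / cfg$pool1_size) / cfg$pool2_size)
  if (pooled < 1L) {
    stop("pooling the ", channels, " hidden channels by ", cfg$pool1_size,
         " then ", cfg$pool2_size, " leaves no output channel")
  }
  structure(cfg, class = "ncp_extractor_config")
}

#' Build an untrained extractor
#'
#' Instantiates the embedding (6-token vocabulary: pad, A, C, G, T, N),
#' the gated recurrent layer(s) and the sigmoid classification head, with
#' all parameters drawn uniformly from (-0.1, 0.1) under the config seed.
#'
#' @param config An [extractor_config()].
#' @return An `ncp_gru` model object (untrained).
#' @export
build_extractor <- function(config) {
  stopifnot(inherits(config, "ncp_extractor_config"))
  h <- config$hidden_units
  d <- config$embedding_dim
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)
  params <- withr::with_seed(config$seed, {
    p <- list(E = rmat(d, 6))
    dirs <- if (config$bidirectional) c("", "_b") else ""
    for (s in dirs) {
      p[[paste0("Wu_h", s)]] <- rmat(h, h)
      p[[paste0("Wu_x", s)]] <- rmat(h, d)
      p[[paste0("Wr_h", s)]] <- rmat(h, h)
      p[[paste0("Wr_x", s)]] <- rmat(h, d)
      p[[paste0("Wc_h", s)]] <- rmat(h, h)
      p[[paste0("Wc_x", s)]] <- rmat(h, d)
      p[[paste0("bu", s)]] <- numeric(h)
      p[[paste0("br", s)]] <- numeric(h)
      p[[paste0("bc", s)]] <- numeric(h)
    }
    p$head_w <- as.numeric(rmat(config$seq_length, 1))
    p$head_b <- 0
    p
  })
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL,
                 fingerprint = config_fingerprint(config)),
            class = "ncp_gru")
}

#' Train the extractor as a binary sequence classifier
#'
#' Minimizes binary cross-entropy with Adam at the configured learning
#' rate and batch size, backpropagating through the pooled head, the
#' recurrent layer(s) and the embedding. A stratified internal split
#' (`validation_fraction`) drives early stopping. Fully deterministic
#' under the config seed.
#'
#' @param model An `ncp_gru` from [build_extractor()].
#' @param encoded `seq_length` x n integer token matrix from
#'   [encode_dataset()].
#' @param class_labels Class vector of length n (`ncRNA` positive).
#' @return The trained model, with a `history` tibble (epoch, train_loss,
#'   val_loss).
#' @export
train_extractor <- function(model, encoded, class_labels) {
  stopifnot(inherits(model, "ncp_gru"))
  cfg <- model$config
  if (nrow(encoded) != cfg$seq_length) {
    stop("encoded length ", nrow(encoded), " does not match config seq_length ",
         cfg$seq_length)
  }
  y <- as.numeric(factor(class_labels, levels = class_levels())) - 1
  if (anyNA(y)) stop("labels must be mRNA/ncRNA")
  if (length(unique(y)) < 2L) stop("both classes required for training")
  n <- ncol(encoded)
  if (n < 2L * cfg$batch_size) {
    stop("need at least ", 2L * cfg$batch_size, " training examples")
  }

  params <- model$params
  adam <- list(m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0), t = 0)
  history <- list()
  withr::with_seed(cfg$seed + 1L, {
    # stratified internal early-stopping split
    val_idx <- unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, max(1L, floor(cfg$validation_fraction * length(rows))))
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        res <- gru_batch_cpp(params, encoded[, idx, drop = FALSE], y[idx],
                             cfg$bidirectional, TRUE)
        upd <- adam_step(params, res$grads, adam, cfg$learning_rate)
        params <- upd$params
        adam <- upd$state
        losses <- c(losses, res$loss)
      }
      val <- gru_batch_cpp(params, encoded[, val_idx, drop = FALSE],
                           y[val_idx], cfg$bidirectional, FALSE)
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = val$loss)
      if (val$loss < best$loss - 1e-8) {
        best <- list(loss = val$loss, params = params, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (is.finite(cfg$patience) && wait >= cfg$patience) break
      }
    }
    params <- best$params
  })
  model$params <- params
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  model
}

#' Extract the deep feature vector of one encoded sequence
#'
#' Runs the recurrent layer(s) and the max-pooling stages (no
#' classification head) and returns the pooled activations: one value per
#' sequence position, i.e. a vector of dimension `seq_length` (1200 under
#' the default config).
#'
#' @param model An `ncp_gru` (trained or freshly built).
#' @param encoded Integer token vector of length `seq_length` (from
#'   [encode_indices()]).
#' @return Numeric vector of length `seq_length` with attribute
#'   `config_fingerprint`.
#' @export
extract_deep_features <- function(model, encoded) {
  stopifnot(inherits(model, "ncp_gru"))
  L <- model$config$seq_length
  if (length(encoded) != L) {
    stop("encoded input has length ", length(encoded),
         "; the extractor expects ", L)
  }
  f <- extract_deep_features_batch(model, matrix(as.integer(encoded), ncol = 1))
  out <- as.numeric(f[1, ])
  attr(out, "config_fingerprint") <- model$fingerprint
  out
}

#' Extract deep features for a whole encoded dataset
#'
#' @param model An `ncp_gru`.
#' @param encoded `seq_length` x n integer token matrix
#'   ([encode_dataset()]).
#' @return An n x D tibble (columns `gru_0001` ...), rows in input order.
#' @export
extract_deep_features_batch <- function(model, encoded) {
  stopifnot(inherits(model, "ncp_gru"), is.matrix(encoded))
  cfg <- model$config
  if (nrow(encoded) != cfg$seq_length) {
    stop("encoded length ", nrow(encoded),
         " does not match config seq_length ", cfg$seq_length)
  }
  n <- ncol(encoded)
  D <- cfg$seq_length
  if (n == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = D)
  } else {
    blocks <- split(seq_len(n), ceiling(seq_len(n) / 64))
    m <- do.call(rbind, lapply(blocks, function(idx) {
      t(gru_batch_cpp(model$params, encoded[, idx, drop = FALSE], numeric(0),
                      cfg$bidirectional, FALSE)$features)
    }))
  }
  colnames(m) <- sprintf("gru_%04d", seq_len(D))
  stopifnot(all(is.finite(m)))
  tibble::as_tibble(m)
}

#' Save / load an extractor checkpoint
#'
#' The checkpoint stores the parameters together with the config
#' fingerprint; loading verifies them and extraction refuses a model whose
#' fingerprint does not match its config.
#'
#' @param model An `ncp_gru`.
#' @param path Checkpoint path (RDS).
#' @return `path` invisibly; `load_extractor()` returns the model.
#' @export
save_extractor <- function(model, path) {
  stopifnot(inherits(model, "ncp_gru"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ncp_gru"))
  if (!identical(model$fingerprint, config_fingerprint(model$config))) {
    stop("checkpoint fingerprint does not match its stored config; ",
         "refusing to extract")
  }
  model
}

#' @export
print.ncp_gru <- function(x, ...) {
  cfg <- x$config
  cat("<ncp_gru> ", if (cfg$bidirectional) "Bi-GRU" else "GRU",
      " extractor: L=", cfg$seq_length, ", embed=", cfg$embedding_dim,
      ", hidden=", cfg$hidden_units, ", ",
      if (x$trained) paste0("trained (", nrow(x$history), " epochs)")
      else "untrained", "\n", sep = "")
  invisible(x)
}

# ---- internal ---------------------------------------------------------

config_fingerprint <- function(config) {
  paste(vapply(config, function(v) paste(format(v, digits = 15),
                                         collapse = ","),
               character(1)),
        collapse = "|")
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
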