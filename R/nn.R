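## Native implementation of the deep sequence classifiers.
##
## Two architectures share one training loop:
##   * LSTM:  embedding (or one-hot input) -> LSTM (last hidden state) ->
##            dense ReLU -> sigmoid output       (the LSTM_WE / LSTM_one-hot
##            classifiers)
##   * CNN:   embedding -> 4 x (1-d conv, ReLU, same padding) -> global max
##            pool -> sigmoid output              (the CNN_WE comparator)
##
## Training: binary cross-entropy, Adam, mini-batches, inverted dropout after
## the recurrent/pooled representation and after the dense layer.  All
## gradients are hand-derived and verified against finite differences in the
## test suite.  Everything is deterministic given the training seed.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) (x > 0) * x

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(nr, nc) {
  a <- matrix(stats::rnorm(nr * nc), nr, nc)
  qr_ <- qr(a)
  q <- qr.Q(qr_)
  ## fix signs for determinism across LAPACK implementations
  q * rep(sign(diag(qr.R(qr_)) + (diag(qr.R(qr_)) == 0)), each = nrow(q))
}

#' Architecture specification of the LSTM classifier
#'
#' Defaults are the published architecture: a 21-symbol vocabulary embedded in
#' 5 dimensions, an LSTM cell with 32 hidden units, a 128-unit ReLU dense
#' layer, a single sigmoid output, and dropout rate 0.2 applied after the
#' recurrent and dense layers.
#'
#' @param vocab_size Vocabulary size (21: 20 amino acids + gap).
#' @param embed_dim Word-vector dimension (5).
#' @param lstm_units LSTM hidden units (32).
#' @param dense_units Dense-layer units (128).
#' @param dropout_rate Dropout after recurrent and dense layers (0.2).
#' @param input_length Window length (31).
#' @return List of class `lemp_deep_spec`.
#' @export
deep_model_spec <- function(vocab_size = 21L, embed_dim = 5L,
                            lstm_units = 32L, dense_units = 128L,
                            dropout_rate = 0.2, input_length = 31L) {
  stopifnot(vocab_size > 0, embed_dim > 0, lstm_units > 0, dense_units > 0,
            dropout_rate >= 0, dropout_rate < 1, input_length > 0)
  structure(list(vocab_size = as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 input_length = as.integer(input_length)),
            class = "lemp_deep_spec")
}

#' Training configuration for the deep classifiers
#'
#' Defaults follow the published regimen: at most 300 epochs of Adam on
#' binary cross-entropy with batch size 512.  Early stopping on validation
#' loss is optional (off by default, matching the fixed-epoch regimen).
#'
#' @param max_epochs Maximum training epochs (300).
#' @param batch_size Mini-batch size (512).
#' @param learning_rate Adam step size (0.001).
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param seed Integer seed controlling shuffling, dropout and initial state.
#' @param patience Optional early-stopping patience in epochs (NULL = off).
#' @param validation_fraction Held-out fraction for early stopping (0.1).
#' @return List of class `lemp_train_config`.
#' @export
train_config <- function(max_epochs = 300L, batch_size = 512L,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1L, patience = NULL,
                         validation_fraction = 0.1) {
  stopifnot(max_epochs >= 1L, batch_size >= 1L)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed),
                 patience = patience,
                 validation_fraction = validation_fraction),
            class = "lemp_train_config")
}

#' Build an untrained LSTM classifier
#'
#' In `"embedding"` mode the model consumes integer token sequences
#' ([encode_tokens()]); in `"onehot"` mode it consumes one-hot rows
#' ([encode_onehot_batch()]) fed sequentially to the same LSTM.
#'
#' @param spec Architecture from [deep_model_spec()].
#' @param input_mode `"embedding"` or `"onehot"`.
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `lemp_deep_model` (untrained).
#' @export
build_deep_model <- function(spec = deep_model_spec(),
                             input_mode = c("embedding", "onehot"),
                             seed = 1L) {
  input_mode <- match.arg(input_mode)
  stopifnot(inherits(spec, "lemp_deep_spec"))
  u <- spec$lstm_units
  in_dim <- if (input_mode == "embedding") spec$embed_dim else 20L
  params <- with_local_seed(seed, {
    p <- list()
    if (input_mode == "embedding")
      p$E <- matrix(stats::runif(spec$vocab_size * spec$embed_dim,
                                 -0.05, 0.05),
                    spec$vocab_size, spec$embed_dim)
    p$Wx <- glorot_uniform(in_dim, 4L * u)
    p$Wh <- do.call(cbind, replicate(4, orthogonal_init(u, u),
                                     simplify = FALSE))
    b <- numeric(4L * u)
    b[(u + 1L):(2L * u)] <- 1          # forget-gate bias
    p$b <- b
    p$Wd <- glorot_uniform(u, spec$dense_units)
    p$bd <- numeric(spec$dense_units)
    p$Wo <- glorot_uniform(spec$dense_units, 1L)
    p$bo <- 0
    p
  })
  structure(list(arch = "lstm", input_mode = input_mode, spec = spec,
                 params = params, trained = FALSE, history = numeric(0),
                 metadata = list(alphabet = WINDOW_ALPHABET,
                                 init_seed = seed,
                                 encoding = if (input_mode == "embedding")
                                   "tokens" else "onehot",
                                 package_version =
                                   as.character(utils::packageVersion("lemp")))),
            class = "lemp_deep_model")
}

#' Build an untrained convolutional comparator classifier
#'
#' Embedding input, `n_conv_layers` 1-d convolutions (ReLU, same padding),
#' global max pooling and a sigmoid output.  Filter count and kernel size are
#' free parameters of this package.
#'
#' @param spec Architecture ([deep_model_spec()]; `embed_dim`, `vocab_size`,
#'   `dropout_rate` and `input_length` are used).
#' @param n_filters Filters per convolution layer (default 64).
#' @param kernel_size Odd convolution kernel width (default 5).
#' @param n_conv_layers Number of convolution layers (default 4).
#' @param seed Integer seed for initialisation.
#' @return Object of class `lemp_deep_model` (untrained).
#' @export
build_cnn_model <- function(spec = deep_model_spec(), n_filters = 64L,
                            kernel_size = 5L, n_conv_layers = 4L, seed = 1L) {
  stopifnot(kernel_size %% 2L == 1L, n_conv_layers >= 1L)
  params <- with_local_seed(seed, {
    p <- list(E = matrix(stats::runif(spec$vocab_size * spec$embed_dim,
                                      -0.05, 0.05),
                         spec$vocab_size, spec$embed_dim))
    in_ch <- spec$embed_dim
    for (l in seq_len(n_conv_layers)) {
      p[[paste0("Wc", l)]] <- glorot_uniform(kernel_size * in_ch, n_filters)
      p[[paste0("bc", l)]] <- numeric(n_filters)
      in_ch <- n_filters
    }
    p$Wo <- glorot_uniform(n_filters, 1L)
    p$bo <- 0
    p
  })
  structure(list(arch = "cnn", input_mode = "embedding", spec = spec,
                 n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size),
                 n_conv_layers = as.integer(n_conv_layers),
                 params = params, trained = FALSE, history = numeric(0),
                 metadata = list(alphabet = WINDOW_ALPHABET,
                                 init_seed = seed, encoding = "tokens",
                                 package_version =
                                   as.character(utils::packageVersion("lemp")))),
            class = "lemp_deep_model")
}

## ---- forward / backward ----------------------------------------------------

## inputs: tokens (n x T integer, 0-based) or one-hot array (n x T x 20)
deep_input_list <- function(model, x) {
  Tlen <- model$spec$input_length
  if (model$input_mode == "embedding") {
    stopifnot(is.matrix(x), ncol(x) == Tlen)
    lapply(seq_len(Tlen), function(t)
      model$params$E[x[, t] + 1L, , drop = FALSE])
  } else {
    stopifnot(length(dim(x)) == 3L, dim(x)[2] == Tlen, dim(x)[3] == 20L)
    lapply(seq_len(Tlen), function(t) matrix(x[, t, ], dim(x)[1], 20L))
  }
}

lstm_forward <- function(params, X, u) {
  n <- nrow(X[[1]]); Tlen <- length(X)
  h <- matrix(0, n, u); cc <- matrix(0, n, u)
  cache <- vector("list", Tlen)
  gi <- seq_len(u); gf <- u + gi; gg <- 2L * u + gi; go <- 3L * u + gi
  for (t in seq_len(Tlen)) {
    z <- X[[t]] %*% params$Wx + h %*% params$Wh +
      matrix(params$b, n, 4L * u, byrow = TRUE)
    i <- sigmoid(z[, gi, drop = FALSE]); f <- sigmoid(z[, gf, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE]);    o <- sigmoid(z[, go, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, c_prev = c_prev,
                       tc = tc, h_prev = h)
    h <- o * tc
  }
  list(h = h, cache = cache)
}

lstm_backward <- function(params, X, cache, dh_last, u) {
  n <- nrow(dh_last); Tlen <- length(X)
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- numeric(4L * u)
  dX <- vector("list", Tlen)
  dh <- dh_last; dc <- matrix(0, n, u)
  gi <- seq_len(u); gf <- u + gi; gg <- 2L * u + gi; go <- 3L * u + gi
  for (t in rev(seq_len(Tlen))) {
    cc <- cache[[t]]
    do_ <- dh * cc$tc
    dct <- dh * cc$o * (1 - cc$tc^2) + dc
    df <- dct * cc$c_prev
    di <- dct * cc$g
    dg <- dct * cc$i
    dc <- dct * cc$f
    dz <- matrix(0, n, 4L * u)
    dz[, gi] <- di * cc$i * (1 - cc$i)
    dz[, gf] <- df * cc$f * (1 - cc$f)
    dz[, gg] <- dg * (1 - cc$g^2)
    dz[, go] <- do_ * cc$o * (1 - cc$o)
    dWx <- dWx + crossprod(X[[t]], dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- tcrossprod(dz, params$Wx)
    dh <- tcrossprod(dz, params$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

conv1d_forward <- function(Xarr, W, b, kernel) {
  ## Xarr: n x T x C; W: (kernel*C) x F; same padding
  n <- dim(Xarr)[1]; Tlen <- dim(Xarr)[2]; C <- dim(Xarr)[3]
  pad <- (kernel - 1L) %/% 2L
  Xp <- array(0, c(n, Tlen + 2L * pad, C))
  Xp[, pad + seq_len(Tlen), ] <- Xarr
  col <- matrix(0, n * Tlen, kernel * C)
  for (k in seq_len(kernel))
    col[, (k - 1L) * C + seq_len(C)] <-
      matrix(Xp[, (k - 1L) + seq_len(Tlen), , drop = FALSE], n * Tlen, C)
  out <- col %*% W + matrix(b, n * Tlen, length(b), byrow = TRUE)
  list(out = array(out, c(n, Tlen, ncol(W))), col = col)
}

conv1d_backward <- function(dOut, col, W, kernel, n, Tlen, C) {
  dOutM <- matrix(dOut, n * Tlen, dim(dOut)[3])
  dW <- crossprod(col, dOutM)
  db <- colSums(dOutM)
  dcol <- tcrossprod(dOutM, W)
  pad <- (kernel - 1L) %/% 2L
  dXp <- array(0, c(n, Tlen + 2L * pad, C))
  for (k in seq_len(kernel))
    dXp[, (k - 1L) + seq_len(Tlen), ] <-
      dXp[, (k - 1L) + seq_len(Tlen), , drop = FALSE] +
      array(dcol[, (k - 1L) * C + seq_len(C)], c(n, Tlen, C))
  list(dW = dW, db = db, dX = dXp[, pad + seq_len(Tlen), , drop = FALSE])
}

## full forward pass; training = TRUE draws dropout masks from the RNG
deep_forward <- function(model, x, training = FALSE) {
  p <- model$params
  drop <- model$spec$dropout_rate
  mask <- function(nr, nc) {
    if (!training || drop == 0) return(NULL)
    matrix(stats::rbinom(nr * nc, 1L, 1 - drop) / (1 - drop), nr, nc)
  }
  if (model$arch == "lstm") {
    X <- deep_input_list(model, x)
    fw <- lstm_forward(p, X, model$spec$lstm_units)
    m1 <- mask(nrow(fw$h), ncol(fw$h))
    h_d <- if (is.null(m1)) fw$h else fw$h * m1
    pre <- h_d %*% p$Wd + matrix(p$bd, nrow(h_d), length(p$bd), byrow = TRUE)
    a <- relu(pre)
    m2 <- mask(nrow(a), ncol(a))
    a_d <- if (is.null(m2)) a else a * m2
    y <- sigmoid(as.numeric(a_d %*% p$Wo + p$bo))
    list(y = y, X = X, fw = fw, m1 = m1, h_d = h_d, pre = pre, a = a,
         m2 = m2, a_d = a_d)
  } else {
    stopifnot(is.matrix(x))
    n <- nrow(x); Tlen <- ncol(x)
    A <- array(p$E[x + 1L, ], c(n, Tlen, model$spec$embed_dim))
    acts <- list(); cols <- list(); pres <- list()
    cur <- A
    for (l in seq_len(model$n_conv_layers)) {
      cf <- conv1d_forward(cur, p[[paste0("Wc", l)]], p[[paste0("bc", l)]],
                           model$kernel_size)
      pres[[l]] <- cf$out
      cols[[l]] <- cf$col
      cur <- relu(cf$out)
      acts[[l]] <- cur
    }
    ## global max pool over time
    pooled <- apply(cur, c(1, 3), max)
    amax <- apply(cur, c(1, 3), which.max)
    m1 <- mask(nrow(pooled), ncol(pooled))
    pooled_d <- if (is.null(m1)) pooled else pooled * m1
    y <- sigmoid(as.numeric(pooled_d %*% p$Wo + p$bo))
    list(y = y, A = A, acts = acts, cols = cols, pres = pres, pooled = pooled,
         amax = amax, m1 = m1, pooled_d = pooled_d, tokens = x)
  }
}

## gradients of mean BCE loss wrt all parameters
deep_backward <- function(model, x, fwd, y_true) {
  p <- model$params
  n <- length(fwd$y)
  dy <- matrix((fwd$y - y_true) / n, n, 1L)
  grads <- list()
  if (model$arch == "lstm") {
    grads$Wo <- crossprod(fwd$a_d, dy)
    grads$bo <- sum(dy)
    da <- tcrossprod(dy, p$Wo)
    if (!is.null(fwd$m2)) da <- da * fwd$m2
    dpre <- da * (fwd$pre > 0)
    grads$Wd <- crossprod(fwd$h_d, dpre)
    grads$bd <- colSums(dpre)
    dh <- tcrossprod(dpre, p$Wd)
    if (!is.null(fwd$m1)) dh <- dh * fwd$m1
    bk <- lstm_backward(p, fwd$X, fwd$fw$cache, dh, model$spec$lstm_units)
    grads$Wx <- bk$dWx; grads$Wh <- bk$dWh; grads$b <- bk$db
    if (model$input_mode == "embedding") {
      dE <- p$E * 0
      for (t in seq_along(bk$dX)) {
        gt <- rowsum(bk$dX[[t]], group = x[, t], reorder = FALSE)
        dE[as.integer(rownames(gt)) + 1L, ] <-
          dE[as.integer(rownames(gt)) + 1L, ] + gt
      }
      grads$E <- dE
    }
  } else {
    grads$Wo <- crossprod(fwd$pooled_d, dy)
    grads$bo <- sum(dy)
    dpool <- tcrossprod(dy, p$Wo)
    if (!is.null(fwd$m1)) dpool <- dpool * fwd$m1
    L <- model$n_conv_layers
    Tlen <- ncol(fwd$tokens)
    Fch <- model$n_filters
    dcur <- array(0, dim(fwd$acts[[L]]))
    idx <- cbind(rep(seq_len(n), Fch), as.vector(fwd$amax),
                 rep(seq_len(Fch), each = n))
    dcur[idx] <- as.vector(dpool)
    for (l in rev(seq_len(L))) {
      dpre <- dcur * (fwd$pres[[l]] > 0)
      Cin <- if (l == 1L) model$spec$embed_dim else Fch
      bk <- conv1d_backward(dpre, fwd$cols[[l]], p[[paste0("Wc", l)]],
                            model$kernel_size, n, Tlen, Cin)
      grads[[paste0("Wc", l)]] <- bk$dW
      grads[[paste0("bc", l)]] <- bk$db
      dcur <- bk$dX
    }
    ## embedding gradient: dcur is n x T x embed_dim
    dE <- p$E * 0
    for (t in seq_len(Tlen)) {
      gt <- rowsum(matrix(dcur[, t, , drop = FALSE], n,
                          model$spec$embed_dim),
                   group = fwd$tokens[, t], reorder = FALSE)
      dE[as.integer(rownames(gt)) + 1L, ] <-
        dE[as.integer(rownames(gt)) + 1L, ] + gt
    }
    grads$E <- dE
  }
  grads
}

bce_loss <- function(y_hat, y_true, eps = 1e-12) {
  y_hat <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y_true * log(y_hat) + (1 - y_true) * log(1 - y_hat))
}

#' Train a deep classifier
#'
#' Mini-batch Adam on binary cross-entropy.  Dropout is active only during
#' training; prediction is deterministic.  Training is fully reproducible from
#' `cfg$seed`.  Divergence (non-finite loss) raises an error with diagnostics.
#'
#' @param model Untrained model from [build_deep_model()] /
#'   [build_cnn_model()].
#' @param x Encoded inputs: token matrix (embedding mode) or one-hot array
#'   (onehot mode).
#' @param labels Binary labels (see [as_binary_labels()]).
#' @param cfg Training configuration from [train_config()].
#' @return The trained model, with per-epoch mean training loss in
#'   `$history` (and `$val_history` when early stopping is enabled).
#' @export
train_deep <- function(model, x, labels, cfg = train_config()) {
  stopifnot(inherits(model, "lemp_deep_model"),
            inherits(cfg, "lemp_train_config"))
  y <- as.numeric(as_binary_labels(labels))
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  stopifnot(length(y) == n)
  take <- function(z, idx) if (is.matrix(z)) z[idx, , drop = FALSE] else
    z[idx, , , drop = FALSE]

  with_local_seed(cfg$seed, {
    val_idx <- integer(0)
    if (!is.null(cfg$patience)) {
      val_idx <- sample.int(n, max(1L, round(cfg$validation_fraction * n)))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    m <- lapply(model$params, function(p) p * 0)
    v <- lapply(model$params, function(p) p * 0)
    step <- 0L
    history <- numeric(0); val_history <- numeric(0)
    best_val <- Inf; wait <- 0L; best_params <- NULL
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      batch_starts <- seq(1L, length(ord), by = cfg$batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
        xb <- take(x, idx); yb <- y[idx]
        fwd <- deep_forward(model, xb, training = TRUE)
        loss <- bce_loss(fwd$y, yb)
        if (!is.finite(loss))
          stop("training diverged at epoch ", epoch, " (loss = ", loss,
               "); try a lower learning rate")
        grads <- deep_backward(model, xb, fwd, yb)
        step <- step + 1L
        for (nm in names(grads)) {
          m[[nm]] <- cfg$beta1 * m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
          v[[nm]] <- cfg$beta2 * v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - cfg$beta1^step)
          vhat <- v[[nm]] / (1 - cfg$beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + cfg$epsilon)
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      history <- c(history, ep_loss / ep_n)
      if (!is.null(cfg$patience)) {
        vy <- deep_forward(model, take(x, val_idx), training = FALSE)$y
        vl <- bce_loss(vy, y[val_idx])
        val_history <- c(val_history, vl)
        if (vl < best_val - 1e-6) {
          best_val <- vl; wait <- 0L; best_params <- model$params
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) {
            model$params <- best_params
            break
          }
        }
      }
    }
    model$trained <- TRUE
    model$history <- history
    if (!is.null(cfg$patience)) model$val_history <- val_history
    model$metadata$train_seed <- cfg$seed
    model$metadata$epochs_run <- length(history)
    model$metadata$batch_size <- cfg$batch_size
    model$metadata$learning_rate <- cfg$learning_rate
    model
  })
}

#' Prediction scores in [0, 1]
#'
#' Generic over the package's classifier types; deterministic at inference
#' (dropout disabled) and order-preserving.
#'
#' @param model A trained `lemp_deep_model`, `lemp_forest_model` or
#'   `lemp_ensemble` object.
#' @param inputs Encoded inputs matching the model (token matrix, one-hot
#'   array or feature matrix), or a character vector of peptide windows which
#'   is encoded automatically.
#' @param ... Passed to methods.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, inputs, ...) UseMethod("predict_scores")

#' @rdname predict_scores
#' @param batch_size Inference batch size (default 4096).
#' @export
predict_scores.lemp_deep_model <- function(model, inputs, batch_size = 4096L,
                                           ...) {
  if (is.character(inputs)) {
    inputs <- if (model$input_mode == "embedding")
      encode_tokens(inputs, unknown_as_gap = TRUE)
    else encode_onehot_batch(inputs)
  }
  n <- if (is.matrix(inputs)) nrow(inputs) else dim(inputs)[1]
  Tlen <- if (is.matrix(inputs)) ncol(inputs) else dim(inputs)[2]
  if (Tlen != model$spec$input_length)
    stop("input length ", Tlen, " does not match model input_length ",
         model$spec$input_length)
  take <- function(z, idx) if (is.matrix(z)) z[idx, , drop = FALSE] else
    z[idx, , , drop = FALSE]
  out <- numeric(n)
  for (bs in seq(1L, n, by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1L, n)
    out[idx] <- deep_forward(model, take(inputs, idx), training = FALSE)$y
  }
  out
}

#' Extract the learned residue embedding matrix
#'
#' @param model A trained embedding-mode deep model.
#' @return `vocab_size x embed_dim` matrix (21 x 5 by default), rows named by
#'   the window alphabet (20 amino acids then the gap).
#' @export
extract_embedding <- function(model) {
  stopifnot(inherits(model, "lemp_deep_model"))
  if (model$input_mode != "embedding")
    stop("model has no embedding layer (input_mode = '", model$input_mode,
         "')")
  E <- model$params$E
  rownames(E) <- model$metadata$alphabet
  colnames(E) <- paste0("d", seq_len(ncol(E)))
  E
}

#' @export
print.lemp_deep_model <- function(x, ...) {
  cat(sprintf("<lemp_deep_model: %s, %s input, %strained>\n", toupper(x$arch),
              x$input_mode, if (x$trained) "" else "un"))
  if (x$trained)
    cat(sprintf("  %d epoch(s); final training loss %.4f\n",
                length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}
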