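#' Classifier architecture specification
#'
#' Two architectures are supported, one per feature representation:
#' \describe{
#'   \item{`"lstm"`}{for the 100 x 7 time-series features: two stacked LSTM
#'     layers of 64 units with a dropout layer (rate 0.5) between them, a
#'     64-unit dense (ReLU) layer on the final hidden state, and a softmax
#'     output over the identity labels.}
#'   \item{`"dense"`}{for the 16-value statistical features: three hidden
#'     ReLU layers of 100, 75 and 50 neurons and a softmax output.}
#' }
#'
#' @param kind `"lstm"` or `"dense"`.
#' @param num_labels Number of identity classes (>= 2).
#' @param lstm_units Units per recurrent layer (and the dense layer after
#'   them).
#' @param dense_hidden Hidden-layer sizes of the dense network.
#' @param dropout_rate Dropout rate between the recurrent layers.
#' @param timesteps,input_channels Sequence layout consumed by the LSTM.
#' @param input_dim Input length consumed by the dense network.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("lstm", "dense"), num_labels,
                       lstm_units = 64, dense_hidden = c(100, 75, 50),
                       dropout_rate = 0.5, timesteps = 100,
                       input_channels = 7, input_dim = 16) {
  kind <- match.arg(kind)
  if (num_labels < 2L) {
    stop_gazeid("num_labels must be >= 2", "gazeid_validation_error")
  }
  structure(list(kind = kind, num_labels = as.integer(num_labels),
                 lstm_units = lstm_units, dense_hidden = dense_hidden,
                 dropout_rate = dropout_rate, timesteps = timesteps,
                 input_channels = input_channels, input_dim = input_dim),
            class = "model_spec")
}

#' Training configuration
#'
#' Adam with learning rate 0.001 and categorical cross-entropy; a fixed epoch
#' budget with no early stopping, so runs under different conditions stay
#' comparable.
#'
#' @param epochs Number of full passes over the training data.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size. The default of 16 keeps the number of
#'   optimiser updates per epoch high enough that the regularised LSTM makes
#'   progress even on the moderate training-set sizes (hundreds to a few
#'   thousand samples) this package typically sees.
#' @param seed Integer seed for weight init, shuffling and dropout masks.
#' @param verbose Print per-epoch loss.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 150, lr = 0.001, batch_size = 16,
                         seed = 1, verbose = FALSE) {
  if (epochs < 1L) {
    stop_gazeid("epochs must be >= 1", "gazeid_validation_error")
  }
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = seed,
                 verbose = verbose),
            class = "train_config")
}

# ---- parameter initialisation -------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Combined-gate LSTM layer parameters; gate column blocks ordered i, f, g, o.
init_lstm_layer <- function(d, u) {
  b <- numeric(4 * u)
  b[(u + 1):(2 * u)] <- 1 # forget-gate bias at 1, the standard init
  list(W = glorot(d, 4 * u), U = glorot(u, 4 * u), b = b)
}

#' Build an untrained classifier
#'
#' Weights use Glorot-uniform initialisation (forget-gate biases at 1).
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initial weights.
#' @return An object of class `gazeid_model` holding the parameter list.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  params <- with_seed(seed, {
    if (spec$kind == "lstm") {
      u <- spec$lstm_units
      list(l1 = init_lstm_layer(spec$input_channels, u),
           l2 = init_lstm_layer(u, u),
           Wd = glorot(u, u), bd = numeric(u),
           Wo = glorot(u, spec$num_labels), bo = numeric(spec$num_labels))
    } else {
      sizes <- c(spec$input_dim, spec$dense_hidden, spec$num_labels)
      layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
        list(W = glorot(sizes[i], sizes[i + 1]), b = numeric(sizes[i + 1]))
      })
      list(layers = layers)
    }
  })
  structure(list(spec = spec, params = params, trained = FALSE,
                 loss_trace = numeric(0)),
            class = "gazeid_model")
}

#' @export
print.gazeid_model <- function(x, ...) {
  cat(sprintf("<gazeid_model> kind=%s labels=%d %s\n", x$spec$kind,
              x$spec$num_labels,
              if (x$trained) sprintf("(trained, %d epochs)",
                                     length(x$loss_trace)) else "(untrained)"))
  invisible(x)
}

# ---- shared numerics -----------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(y, l) {
  m <- matrix(0, length(y), l)
  m[cbind(seq_along(y), y)] <- 1
  m
}

add_bias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

# ---- LSTM forward/backward ----------------------------------------------

# X: [B, T, d] array. Returns hidden-state sequence H ([B, T, u]) plus the
# per-timestep caches needed for backpropagation through time.
lstm_forward <- function(X, layer) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; d <- dim(X)[3]
  u <- ncol(layer$U)
  u <- u / 4
  X2d <- matrix(X, B * Tn, d) # row b + (t-1)B
  XW <- add_bias(X2d %*% layer$W, layer$b)
  H <- array(0, dim = c(B, Tn, u))
  gates <- vector("list", Tn)
  Cs <- array(0, dim = c(B, Tn, u)) # cell states
  h <- matrix(0, B, u)
  cc <- matrix(0, B, u)
  for (t in seq_len(Tn)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    Z <- XW[rows, , drop = FALSE] + h %*% layer$U
    i <- sigmoid(Z[, 1:u, drop = FALSE])
    f <- sigmoid(Z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(Z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigmoid(Z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    H[, t, ] <- h
    Cs[, t, ] <- cc
    gates[[t]] <- list(i = i, f = f, g = g, o = o, tc = tc, c_prev = c_prev)
  }
  list(H = H, gates = gates, X2d = X2d, B = B, Tn = Tn, u = u)
}

# dH: [B, T, u] gradient w.r.t. the hidden-state sequence. Returns parameter
# gradients and the gradient w.r.t. the layer input as [B, T, d].
lstm_backward <- function(fwd, layer, dH) {
  B <- fwd$B; Tn <- fwd$Tn; u <- fwd$u
  dZ_all <- matrix(0, B * Tn, 4 * u)
  Hprev2d <- matrix(0, B * Tn, u)
  dh_carry <- matrix(0, B, u)
  dc <- matrix(0, B, u)
  Ut <- t(layer$U)
  for (t in rev(seq_len(Tn))) {
    gt <- fwd$gates[[t]]
    dh <- matrix(dH[, t, ], B, u) + dh_carry
    do_ <- dh * gt$tc
    dc <- dc + dh * gt$o * (1 - gt$tc^2)
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * gt$c_prev
    dZ <- cbind(di * gt$i * (1 - gt$i),
                df * gt$f * (1 - gt$f),
                dg * (1 - gt$g^2),
                do_ * gt$o * (1 - gt$o))
    rows <- ((t - 1L) * B + 1L):(t * B)
    dZ_all[rows, ] <- dZ
    if (t > 1L) Hprev2d[rows, ] <- matrix(fwd$H[, t - 1L, ], B, u)
    dh_carry <- dZ %*% Ut
    dc <- dc * gt$f
  }
  dX2d <- dZ_all %*% t(layer$W)
  list(dW = crossprod(fwd$X2d, dZ_all),
       dU = crossprod(Hprev2d, dZ_all),
       db = colSums(dZ_all),
       dX = array(dX2d, dim = c(B, Tn, ncol(dX2d))))
}

# Full LSTM-classifier forward pass. dropout_mask NULL at inference.
lstm_net_forward <- function(params, X, dropout_mask = NULL) {
  f1 <- lstm_forward(X, params$l1)
  H1 <- f1$H
  if (!is.null(dropout_mask)) H1 <- H1 * dropout_mask
  f2 <- lstm_forward(H1, params$l2)
  hT <- matrix(f2$H[, dim(X)[2], ], dim(X)[1], f1$u)
  Dpre <- add_bias(hT %*% params$Wd, params$bd)
  D <- pmax(Dpre, 0)
  logits <- add_bias(D %*% params$Wo, params$bo)
  list(f1 = f1, f2 = f2, hT = hT, D = D, probs = softmax_rows(logits))
}

lstm_net_gradient <- function(params, X, y_onehot, dropout_mask = NULL) {
  fwd <- lstm_net_forward(params, X, dropout_mask)
  B <- dim(X)[1]; Tn <- dim(X)[2]; u <- fwd$f1$u
  dlogits <- (fwd$probs - y_onehot) / B
  grads <- list()
  grads$Wo <- crossprod(fwd$D, dlogits)
  grads$bo <- colSums(dlogits)
  dD <- dlogits %*% t(params$Wo)
  dD[fwd$D <= 0] <- 0
  grads$Wd <- crossprod(fwd$hT, dD)
  grads$bd <- colSums(dD)
  dH2 <- array(0, dim = c(B, Tn, u))
  dH2[, Tn, ] <- dD %*% t(params$Wd)
  b2 <- lstm_backward(fwd$f2, params$l2, dH2)
  grads$l2 <- b2[c("dW", "dU", "db")]
  dH1 <- b2$dX
  if (!is.null(dropout_mask)) dH1 <- dH1 * dropout_mask
  b1 <- lstm_backward(fwd$f1, params$l1, dH1)
  grads$l1 <- b1[c("dW", "dU", "db")]
  loss <- -mean(log(pmax(rowSums(fwd$probs * y_onehot), 1e-12)))
  list(loss = loss, grads = grads, probs = fwd$probs)
}

# ---- dense net forward/backward -----------------------------------------

mlp_forward <- function(params, X) {
  acts <- list(X)
  nl <- length(params$layers)
  A <- X
  for (i in seq_len(nl)) {
    Z <- add_bias(A %*% params$layers[[i]]$W, params$layers[[i]]$b)
    A <- if (i < nl) pmax(Z, 0) else softmax_rows(Z)
    acts[[i + 1L]] <- A
  }
  list(acts = acts, probs = A)
}

mlp_gradient <- function(params, X, y_onehot) {
  fwd <- mlp_forward(params, X)
  nl <- length(params$layers)
  B <- nrow(X)
  grads <- vector("list", nl)
  delta <- (fwd$probs - y_onehot) / B
  for (i in rev(seq_len(nl))) {
    grads[[i]] <- list(W = crossprod(fwd$acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- delta %*% t(params$layers[[i]]$W)
      delta[fwd$acts[[i]] <= 0] <- 0
    }
  }
  loss <- -mean(log(pmax(rowSums(fwd$probs * y_onehot), 1e-12)))
  list(loss = loss, grads = list(layers = grads), probs = fwd$probs)
}

# ---- Adam ----------------------------------------------------------------

# Parameters and gradients share a nested-list shape; walk it recursively.
adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

adam_step <- function(params, grads, m, v, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m1, v1) {
    if (is.list(p)) {
      out_p <- p; out_m <- m1; out_v <- v1
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], m1[[k]], v1[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m1 + (1 - beta1) * g
      v2 <- beta2 * v1 + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^t)
      vhat <- v2 / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  walk(params, grads, m, v)
}

# Map gradient names (dW/dU/db) onto parameter names (W/U/b) so the two trees
# share a shape for Adam.
align_grads <- function(grads) {
  rename <- function(g) {
    if (is.list(g)) {
      names(g) <- sub("^d", "", names(g))
      lapply(g, rename)
    } else {
      g
    }
  }
  rename(grads)
}

# ---- training and prediction --------------------------------------------

#' Train a classifier
#'
#' Mini-batch Adam on categorical cross-entropy for exactly `cfg$epochs`
#' epochs (no early stopping). The run is a pure function of the model's
#' initial weights, the data and `cfg$seed` (shuffling and dropout masks).
#'
#' @param model A [build_model()] result.
#' @param x Features: array `[N, timesteps, channels]` for the LSTM, matrix
#'   `[N, input_dim]` for the dense network.
#' @param y Integer class labels in `1..num_labels`; every class must occur.
#' @param cfg A [train_config()].
#' @return The trained model, with `loss_trace` of length `cfg$epochs` (mean
#'   mini-batch loss per epoch).
#' @export
train_model <- function(model, x, y, cfg = train_config()) {
  stopifnot(inherits(model, "gazeid_model"), inherits(cfg, "train_config"))
  spec <- model$spec
  y <- as.integer(y)
  n <- if (spec$kind == "lstm") dim(x)[1] else nrow(x)
  if (length(y) != n) {
    stop_gazeid("x and y must have matching lengths", "gazeid_validation_error")
  }
  missing_classes <- setdiff(seq_len(spec$num_labels), unique(y))
  if (length(missing_classes) > 0L) {
    stop_gazeid(sprintf("class(es) absent from training data: %s",
                        paste(missing_classes, collapse = ", ")),
                "gazeid_validation_error")
  }
  check_feature_shape(spec, x)
  Y <- one_hot(y, spec$num_labels)
  params <- model$params
  m <- adam_init(params)
  v <- adam_init(params)
  step <- 0L
  keep <- 1 - spec$dropout_rate
  trace <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Yb <- Y[idx, , drop = FALSE]
        if (spec$kind == "lstm") {
          Xb <- x[idx, , , drop = FALSE]
          B <- length(idx)
          mask <- if (keep < 1) {
            array(stats::rbinom(B * spec$timesteps * spec$lstm_units, 1, keep) / keep,
                  dim = c(B, spec$timesteps, spec$lstm_units))
          } else {
            NULL
          }
          res <- lstm_net_gradient(params, Xb, Yb, mask)
        } else {
          res <- mlp_gradient(params, x[idx, , drop = FALSE], Yb)
        }
        step <- step + 1L
        upd <- adam_step(params, align_grads(res$grads), m, v, step, cfg$lr)
        params <- upd$p; m <- upd$m; v <- upd$v
        batch_losses <- c(batch_losses, res$loss)
      }
      trace[epoch] <- mean(batch_losses)
      if (cfg$verbose) {
        message(sprintf("epoch %3d/%d loss %.4f", epoch, cfg$epochs,
                        trace[epoch]))
      }
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$loss_trace <- trace
  model
}

check_feature_shape <- function(spec, x) {
  if (spec$kind == "lstm") {
    if (length(dim(x)) != 3L || dim(x)[2] != spec$timesteps ||
        dim(x)[3] != spec$input_channels) {
      stop_gazeid(sprintf("lstm expects [N, %d, %d] features",
                          spec$timesteps, spec$input_channels),
                  "gazeid_validation_error")
    }
  } else {
    if (!is.matrix(x) || ncol(x) != spec$input_dim) {
      stop_gazeid(sprintf("dense model expects [N, %d] features",
                          spec$input_dim),
                  "gazeid_validation_error")
    }
  }
  invisible(TRUE)
}

#' Per-sample class probabilities
#'
#' @param model A trained (or untrained) [build_model()] result.
#' @param x Features in the layout the model consumes.
#' @return Matrix `[N, num_labels]`; rows are softmax distributions summing
#'   to 1. Dropout is inactive at inference.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "gazeid_model"))
  check_feature_shape(model$spec, x)
  if (model$spec$kind == "lstm") {
    lstm_net_forward(model$params, x)$probs
  } else {
    mlp_forward(model$params, x)$probs
  }
}
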