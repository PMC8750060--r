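#' Model configuration
#'
#' Architecture hyper-parameters of the classifier: attention block, input
#' dropout, two valid 3x3 convolutions with ReLU, flatten, three fully
#' connected sigmoid layers ending in a single sigmoid output. Filter counts,
#' kernel sizes, FC widths and the dropout rate are configurable; the defaults
#' keep the network deliberately small.
#'
#' @param conv List of `c(filters, kernel)` pairs (default two layers:
#'   32@3x3, 64@3x3).
#' @param fc_widths Fully connected layer widths; the final width must be 1
#'   (default `c(128, 32, 1)`).
#' @param dropout_rate Input dropout probability (default 0.25).
#' @param conv_activation,fc_activation Activation names; `"relu"` and
#'   `"sigmoid"` are supported.
#' @param attention Apply the frequency-attention block (FALSE gives the
#'   without-attention ablation).
#' @param seed Seed for weight initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv = list(c(32L, 3L), c(64L, 3L)),
                         fc_widths = c(128L, 32L, 1L),
                         dropout_rate = 0.25,
                         conv_activation = "relu",
                         fc_activation = "sigmoid",
                         attention = TRUE,
                         seed = 1L) {
  if (utils::tail(fc_widths, 1) != 1L) {
    stop("the final fully connected layer must have width 1", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (!identical(conv_activation, "relu") || !identical(fc_activation, "sigmoid")) {
    stop("supported activations: relu (conv), sigmoid (fc)", call. = FALSE)
  }
  structure(
    list(conv = conv, fc_widths = as.integer(fc_widths),
         dropout_rate = dropout_rate, conv_activation = conv_activation,
         fc_activation = fc_activation, attention = isTRUE(attention),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Training configuration
#'
#' Momentum SGD with Nesterov acceleration and time-based learning-rate
#' decay (`lr_t = lr / (1 + decay * step)`), binary cross-entropy loss,
#' He-style weight initialisation.
#'
#' @param optimizer Only `"sgd"` (momentum SGD) is implemented; the name is a
#'   config hook.
#' @param lr Learning rate (default 0.01).
#' @param momentum Momentum coefficient (default 0.9).
#' @param decay Learning-rate decay (default 1e-4).
#' @param nesterov Use Nesterov momentum (default TRUE).
#' @param batch_size Mini-batch size (default 80).
#' @param epochs Training epochs (default 83).
#' @param validation_fraction Fraction of training samples held out for
#'   per-epoch validation (default 0.2).
#' @param seed Seed for the shuffle, validation split and dropout masks.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "sgd", lr = 0.01, momentum = 0.9,
                         decay = 1e-4, nesterov = TRUE, batch_size = 80L,
                         epochs = 83L, validation_fraction = 0.2, seed = 1L) {
  if (lr < 0) stop("`lr` must be >= 0", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  structure(
    list(optimizer = optimizer, lr = lr, momentum = momentum, decay = decay,
         nesterov = isTRUE(nesterov), batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         validation_fraction = validation_fraction, seed = as.integer(seed)),
    class = "train_config"
  )
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow = nrow)
}

#' Build an untrained classifier
#'
#' Layer sequence: attention -> dropout -> conv -> conv -> flatten ->
#' FC -> FC -> FC(1, sigmoid). Weights are He-initialised from `cfg$seed`, so
#' two builds with the same configuration are identical.
#'
#' @param cfg A [model_config()].
#' @param input_shape `c(channels, a, b)`, default `c(20, 32, 32)`.
#' @return An object of class `fccnn_model` (untrained).
#' @export
build_model <- function(cfg = model_config(), input_shape = c(20L, 32L, 32L)) {
  stopifnot(inherits(cfg, "model_config"))
  h <- input_shape[2]; w <- input_shape[3]; cin <- input_shape[1]
  conv <- vector("list", length(cfg$conv))
  with_seed(cfg$seed, {
    for (i in seq_along(cfg$conv)) {
      f <- cfg$conv[[i]][1]; k <- cfg$conv[[i]][2]
      if (k > h || k > w) {
        stop(sprintf("conv layer %d: kernel %d exceeds feature map %dx%d",
                     i, k, h, w), call. = FALSE)
      }
      fan_in <- cin * k * k
      conv[[i]] <- list(W = he_init(f, fan_in, fan_in), b = numeric(f), k = k)
      h <- h - k + 1L; w <- w - k + 1L; cin <- f
    }
    flat <- cin * h * w
    fc <- vector("list", length(cfg$fc_widths))
    prev <- flat
    for (i in seq_along(cfg$fc_widths)) {
      width <- cfg$fc_widths[i]
      fc[[i]] <- list(W = he_init(width, prev, prev), b = numeric(width))
      prev <- width
    }
    structure(
      list(cfg = cfg, input_shape = as.integer(input_shape), conv = conv,
           fc = fc, flat_dim = flat, input_scale = 1, trained = FALSE,
           history = NULL, train_cfg = NULL),
      class = "fccnn_model"
    )
  })
}

#' Number of learnable parameters
#'
#' @param model An `fccnn_model`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  stopifnot(inherits(model, "fccnn_model"))
  s <- 0L
  for (l in model$conv) s <- s + length(l$W) + length(l$b)
  for (l in model$fc) s <- s + length(l$W) + length(l$b)
  s
}

#' @export
print.fccnn_model <- function(x, ...) {
  cat(sprintf(
    "<fccnn_model> input %s | %s | %d parameters | attention %s | %s\n",
    paste(x$input_shape, collapse = "x"),
    paste(vapply(x$cfg$conv, function(c) sprintf("conv%d@%dx%d", c[1], c[2], c[2]),
                 character(1)), collapse = " -> "),
    parameter_count(x),
    if (x$cfg$attention) "on" else "off",
    if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

# Stack segments into a (C, a, b, N) array after applying the (deterministic,
# parameter-free) attention block. The attention weights depend only on each
# segment itself, so this preprocessing is exactly the in-network block.
prepare_tensors <- function(model, segments) {
  d <- model$input_shape
  n <- length(segments)
  x <- array(0, dim = c(d, n))
  for (i in seq_len(n)) {
    ts <- segments[[i]]
    if (!all(dim(ts$tensor) == d)) {
      stop(sprintf("segment %d has shape %s, expected %s", i,
                   paste(dim(ts$tensor), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
    }
    ts <- apply_attention(ts, enabled = model$cfg$attention)
    x[, , , i] <- ts$tensor
  }
  x * model$input_scale
}

# Forward pass on a prepared (C, a, b, B) array. `dropout_mask`, when given,
# multiplies the input (inverted dropout, training only). With
# `keep_cache = TRUE` (training) the fused conv+ReLU kernel retains each
# layer's patch matrix for the backward pass.
forward_fccnn <- function(model, x, dropout_mask = NULL, keep_cache = FALSE) {
  B <- dim(x)[4]
  if (!is.null(dropout_mask)) x <- x * dropout_mask
  caches <- list()
  a_prev <- x
  dims <- dim(x)
  for (i in seq_along(model$conv)) {
    l <- model$conv[[i]]
    if (keep_cache) {
      cf <- cpp_conv_relu_forward(a_prev, as.integer(dims), l$W, l$b,
                                  as.integer(l$k))
      A <- cf$A
      caches[[i]] <- list(A = A, M = cf$M, in_dim = dims, k = l$k)
    } else {
      A <- relu(cpp_conv_forward(as.vector(a_prev), as.integer(dims), l$W,
                                 l$b, as.integer(l$k)))
    }
    dims <- c(nrow(A), dims[2] - l$k + 1L, dims[3] - l$k + 1L, B)
    a_prev <- A   # (F, Ho*Wo*B) matrix; memory layout == (F, Ho, Wo, B)
  }
  # flatten: (F, Ho, Wo, B) -> (F*Ho*Wo, B)
  flat <- matrix(a_prev, nrow = model$flat_dim, ncol = B)
  fc_a <- list()
  a_fc <- flat
  for (i in seq_along(model$fc)) {
    z <- model$fc[[i]]$W %*% a_fc + model$fc[[i]]$b
    a_fc <- sigmoid(z)
    if (keep_cache) fc_a[[i]] <- a_fc
  }
  list(prob = as.vector(a_fc), conv = caches, fc_a = fc_a, flat = flat,
       B = B)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One backward pass; returns gradients in the same shape as the parameters.
backward_fccnn <- function(model, fw, y) {
  B <- fw$B
  n_fc <- length(model$fc)
  grads <- list(conv = vector("list", length(model$conv)),
                fc = vector("list", n_fc))
  # sigmoid + BCE at the output
  dZ <- matrix(fw$fc_a[[n_fc]] - rep(y, each = 1), nrow = 1) / B
  for (i in rev(seq_len(n_fc))) {
    a_prev <- if (i == 1L) fw$flat else fw$fc_a[[i - 1L]]
    grads$fc[[i]] <- list(dW = dZ %*% t(a_prev), db = rowSums(dZ))
    if (i > 1L) {
      dA <- crossprod(model$fc[[i]]$W, dZ)
      a <- fw$fc_a[[i - 1L]]
      dZ <- dA * a * (1 - a)
    } else {
      dFlat <- crossprod(model$fc[[1L]]$W, dZ)
    }
  }
  # back through the conv stack
  n_conv <- length(model$conv)
  dA_conv <- dFlat  # (F*Ho*Wo, B) == flattened conv output
  for (i in rev(seq_len(n_conv))) {
    cache <- fw$conv[[i]]
    F_i <- nrow(cache$A)
    dA_mat <- matrix(dA_conv, nrow = F_i)           # (F, Ho*Wo*B)
    bk <- cpp_conv_relu_backward(cache$M, model$conv[[i]]$W, cache$A, dA_mat,
                                 as.integer(cache$in_dim),
                                 as.integer(cache$k), i > 1L)
    grads$conv[[i]] <- list(dW = bk$dW, db = as.vector(bk$db))
    if (i > 1L) dA_conv <- bk$dx
  }
  grads
}

accuracy_of <- function(p, y) mean(as.integer(p >= 0.5) == y)

#' Train the classifier
#'
#' Minimises binary cross-entropy with momentum SGD on the training half of a
#' subject-level [split_by_subject()] split. Within the training set an 80/20
#' stratified shuffle split provides per-epoch validation metrics. Inputs are
#' standardised by one global RMS factor estimated on the training set (a
#' common constant across channels, which leaves the attention weights
#' unchanged). Deterministic given the model and training seeds.
#'
#' @param model An untrained [build_model()] output.
#' @param split A `dataset_split` (only `split$train` is used).
#' @param tc A [train_config()].
#' @param verbose Print per-epoch metrics.
#' @return A trained `fccnn_model` with a `history` data.frame
#'   (loss, accuracy, val_loss, val_accuracy per epoch).
#' @export
train_model <- function(model, split, tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "fccnn_model"), inherits(split, "dataset_split"),
            inherits(tc, "train_config"))
  segs <- split$train
  if (length(segs) == 0L) stop("empty training set", call. = FALSE)
  y_all <- vapply(segs, function(s) s$class_label, integer(1))
  if (length(unique(y_all)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }

  # global RMS scale from raw (attention-applied) training tensors
  model$input_scale <- 1
  x_all <- prepare_tensors(model, segs)
  rms <- sqrt(mean(x_all^2))
  if (rms > 0) {
    model$input_scale <- 1 / rms
    x_all <- x_all * model$input_scale
  }

  n <- length(segs)
  # stratified 80/20 train/validation shuffle split
  idx_val <- with_seed(derive_seed(tc$seed, 1L), {
    unlist(lapply(unique(y_all), function(cl) {
      pool <- which(y_all == cl)
      sample(pool, max(1L, round(tc$validation_fraction * length(pool))))
    }))
  })
  idx_tr <- setdiff(seq_len(n), idx_val)
  x_val <- x_all[, , , idx_val, drop = FALSE]
  y_val <- y_all[idx_val]

  vel <- list(conv = lapply(model$conv, function(l) list(dW = 0 * l$W, db = 0 * l$b)),
              fc = lapply(model$fc, function(l) list(dW = 0 * l$W, db = 0 * l$b)))
  step <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  d_in <- model$input_shape

  for (epoch in seq_len(tc$epochs)) {
    order_ep <- with_seed(derive_seed(tc$seed, 1000L + epoch), sample(idx_tr))
    batch_starts <- seq(1L, length(order_ep), by = tc$batch_size)
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0L
    for (bs in batch_starts) {
      ids <- order_ep[bs:min(bs + tc$batch_size - 1L, length(order_ep))]
      xb <- x_all[, , , ids, drop = FALSE]
      yb <- y_all[ids]
      mask <- NULL
      if (model$cfg$dropout_rate > 0) {
        mask <- with_seed(derive_seed(tc$seed, 2000L + step), {
          array(stats::rbinom(prod(d_in) * length(ids), 1L,
                              1 - model$cfg$dropout_rate) /
                  (1 - model$cfg$dropout_rate),
                dim = c(d_in, length(ids)))
        })
      }
      fw <- forward_fccnn(model, xb, dropout_mask = mask, keep_cache = TRUE)
      loss <- bce_loss(fw$prob, yb)
      grads <- backward_fccnn(model, fw, yb)
      lr_t <- tc$lr / (1 + tc$decay * step)
      upd <- function(par, v, g) {
        v$dW <- tc$momentum * v$dW - lr_t * g$dW
        v$db <- tc$momentum * v$db - lr_t * g$db
        if (tc$nesterov) {
          par$W <- par$W + tc$momentum * v$dW - lr_t * g$dW
          par$b <- par$b + tc$momentum * v$db - lr_t * g$db
        } else {
          par$W <- par$W + v$dW
          par$b <- par$b + v$db
        }
        list(par = par, v = v)
      }
      for (i in seq_along(model$conv)) {
        r <- upd(model$conv[[i]], vel$conv[[i]], grads$conv[[i]])
        model$conv[[i]]$W <- r$par$W; model$conv[[i]]$b <- r$par$b
        vel$conv[[i]] <- r$v
      }
      for (i in seq_along(model$fc)) {
        r <- upd(model$fc[[i]], vel$fc[[i]], grads$fc[[i]])
        model$fc[[i]]$W <- r$par$W; model$fc[[i]]$b <- r$par$b
        vel$fc[[i]] <- r$v
      }
      step <- step + 1L
      ep_loss <- ep_loss + loss * length(ids)
      ep_acc <- ep_acc + accuracy_of(fw$prob, yb) * length(ids)
      ep_n <- ep_n + length(ids)
    }
    val_fw <- forward_fccnn(model, x_val)
    hist_row <- data.frame(
      epoch = epoch,
      loss = ep_loss / ep_n,
      accuracy = ep_acc / ep_n,
      val_loss = bce_loss(val_fw$prob, y_val),
      val_accuracy = accuracy_of(val_fw$prob, y_val)
    )
    history <- rbind(history, hist_row)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                      epoch, hist_row$loss, hist_row$accuracy,
                      hist_row$val_loss, hist_row$val_accuracy))
    }
  }
  model$trained <- TRUE
  model$history <- history
  model$train_cfg <- tc
  model
}

#' Predict segment class probabilities
#'
#' @param object A trained `fccnn_model`.
#' @param segments List of `tensor_segment` objects.
#' @param ... Unused.
#' @return data.frame with `probability` in `[0, 1]` and `label`
#'   (1 iff probability >= 0.5; the tie at exactly 0.5 goes to the positive
#'   class), plus segment metadata.
#' @export
predict.fccnn_model <- function(object, segments, ...) {
  x <- prepare_tensors(object, segments)  # attention + stored input scale
  fw <- forward_fccnn(object, x)
  data.frame(
    subject_id = vapply(segments, function(s) s$subject_id, character(1)),
    class_label = vapply(segments, function(s) s$class_label, integer(1)),
    probability = fw$prob,
    label = as.integer(fw$prob >= 0.5)
  )
}
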