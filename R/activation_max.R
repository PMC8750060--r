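#' Activation-maximization configuration
#'
#' @param lambda_weight Coefficient of the `lambda * ||x||^2` regulariser;
#'   default 0 since the hard norm constraint already bounds the input.
#' @param norm_budget Norm constraint rho: the input is rescaled to
#'   `||x||_2 = rho` after every step (default 1; the scale is arbitrary for
#'   ranking channel entropies).
#' @param step_size Initial gradient-ascent step (adapted by backtracking).
#' @param move_tolerance Convergence threshold on the input displacement.
#' @param max_iter Iteration cap.
#' @param seed Seed for the random start on the sphere.
#' @return An object of class `am_config`.
#' @export
am_config <- function(lambda_weight = 0, norm_budget = 1, step_size = 0.1,
                      move_tolerance = 1e-8, max_iter = 500L, seed = 1L) {
  if (lambda_weight < 0) stop("`lambda_weight` must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(norm_budget, "norm_budget", positive = TRUE)
  stop_if_not_scalar_number(step_size, "step_size", positive = TRUE)
  stop_if_not_scalar_number(move_tolerance, "move_tolerance", positive = TRUE)
  structure(
    list(lambda_weight = lambda_weight, norm_budget = norm_budget,
         step_size = step_size, move_tolerance = move_tolerance,
         max_iter = as.integer(max_iter), seed = as.integer(seed)),
    class = "am_config"
  )
}

#' Maximize a unit's activation over a norm sphere
#'
#' Projected gradient ascent on `f(x) - lambda * ||x||^2` with `x` rescaled
#' to `||x||_2 = rho` after each step. Steps that would decrease the
#' objective are rejected and retried with a halved step (so the objective is
#' non-decreasing across accepted steps); the step grows mildly after
#' accepted moves. Terminates when the accepted displacement falls below
#' `move_tolerance` or at `max_iter`.
#'
#' @param f Objective function of a numeric vector.
#' @param grad Gradient function of `f`.
#' @param d Input dimension.
#' @param cfg An [am_config()].
#' @param x0 Optional start; default random on the sphere from `cfg$seed`.
#' @return List with `x` (the maximizing input), `value` (achieved
#'   activation `f(x)`), `iterations`, `converged`.
#' @export
maximize_unit <- function(f, grad, d, cfg = am_config(), x0 = NULL) {
  rho <- cfg$norm_budget
  proj <- function(x) {
    nx <- sqrt(sum(x^2))
    if (nx == 0) x else x * (rho / nx)
  }
  x <- if (is.null(x0)) {
    with_seed(cfg$seed, proj(stats::rnorm(d)))
  } else {
    proj(x0)
  }
  obj <- function(x) f(x) - cfg$lambda_weight * sum(x^2)
  cur <- obj(x)
  if (!is.finite(cur)) stop("objective non-finite at the start", call. = FALSE)
  step <- cfg$step_size
  it <- 0L
  converged <- FALSE
  while (it < cfg$max_iter) {
    it <- it + 1L
    g <- grad(x) - 2 * cfg$lambda_weight * x
    if (sqrt(sum(g^2)) < 1e-15) { converged <- TRUE; break }
    accepted <- FALSE
    while (step > 1e-14) {
      x_try <- proj(x + step * g)
      val <- obj(x_try)
      if (!is.finite(val)) {
        stop(sprintf("objective diverged (non-finite) at iteration %d", it),
             call. = FALSE)
      }
      if (val >= cur) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    move <- sqrt(sum((x_try - x)^2))
    x <- x_try
    cur <- val
    step <- step * 1.2
    if (move < cfg$move_tolerance) { converged <- TRUE; break }
  }
  list(x = x, value = f(x), iterations = it, converged = converged)
}

# Objective and gradient for one input channel of a trained classifier:
# summed ReLU activation of every first-conv filter when only channel `ch`'s
# plane is free (all other channels zero). Returns closures over the model.
channel_unit <- function(model, ch) {
  k <- model$conv[[1]]$k
  C <- model$input_shape[1]
  a <- model$input_shape[2]; b <- model$input_shape[3]
  # rows of the im2col patch matrix belonging to channel `ch`
  ck <- expand.grid(c = seq_len(C), dy = 0:(k - 1L), dx = 0:(k - 1L))
  rows <- which(ck$c == ch)
  Wc <- model$conv[[1]]$W[, rows, drop = FALSE]
  bias <- model$conv[[1]]$b
  fwd <- function(x) {
    xa <- array(x, dim = c(1L, a, b, 1L))
    conv_forward(xa, Wc, bias, k)
  }
  list(
    f = function(x) sum(relu(fwd(x)$Z)),
    grad = function(x) {
      cf <- fwd(x)
      dZ <- (cf$Z > 0) * 1
      as.vector(conv_backward(dZ, cf, Wc, need_dx = TRUE)$dx)
    },
    d = a * b
  )
}

#' Activation maximization of the input layer, per channel
#'
#' For each input channel, finds the a x b input plane that maximizes the
#' summed ReLU response of all first-convolution filters restricted to that
#' channel (other channels held at zero), under the norm constraint of
#' `cfg`. The result is one activation matrix per channel — the input
#' pattern the trained network is most responsive to on that channel.
#'
#' @param model A trained `fccnn_model`.
#' @param cfg An [am_config()]; channel c uses seed `cfg$seed + c`.
#' @return An object of class `activation_map`: `per_channel` (named list of
#'   a x b matrices), `achieved_activation`, `iterations`, `channel_labels`.
#' @export
activation_maximization <- function(model, cfg = am_config()) {
  stopifnot(inherits(model, "fccnn_model"))
  if (!model$trained) {
    warning("activation maximization on an untrained model", call. = FALSE)
  }
  C <- model$input_shape[1]
  a <- model$input_shape[2]; b <- model$input_shape[3]
  labels <- attr(model, "channel_labels")
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(C))
  per_channel <- vector("list", C)
  achieved <- numeric(C)
  iters <- integer(C)
  for (ch in seq_len(C)) {
    unit <- channel_unit(model, ch)
    cfg_ch <- cfg
    cfg_ch$seed <- derive_seed(cfg$seed, ch)
    res <- maximize_unit(unit$f, unit$grad, unit$d, cfg_ch)
    per_channel[[ch]] <- matrix(res$x, nrow = a, ncol = b)
    achieved[ch] <- res$value
    iters[ch] <- res$iterations
  }
  names(per_channel) <- labels
  names(achieved) <- labels
  structure(
    list(per_channel = per_channel, achieved_activation = achieved,
         iterations = iters, channel_labels = labels),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d channels, activation range [%.3f, %.3f]\n",
              length(x$per_channel), min(x$achieved_activation),
              max(x$achieved_activation)))
  invisible(x)
}
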