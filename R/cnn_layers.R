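# Convolution expressed as matrix multiplication (im2col + GEMM), the
# standard lowering used by deep-learning frameworks; the patch
# gather/scatter runs in compiled code (src/conv.cpp), the GEMMs in BLAS.

# x: array (C, H, W, B); Wmat: (F x C*k*k); b: length F.
# Returns the pre-activation Z as (F, Ho*Wo*B) plus what backprop needs.
conv_forward <- function(x, Wmat, b, k) {
  d <- dim(x)
  Z <- cpp_conv_forward(as.vector(x), as.integer(d), Wmat, b, as.integer(k))
  list(Z = Z, x = x, k = k, in_dim = d)
}

# dZ: (F, Ho*Wo*B) gradient at the pre-activation. Returns parameter grads
# and (optionally) the gradient w.r.t. the layer input.
conv_backward <- function(dZ, cache, Wmat, need_dx = TRUE) {
  r <- cpp_conv_backward(as.vector(cache$x), as.integer(cache$in_dim), Wmat,
                         as.integer(cache$k), dZ, need_dx)
  list(dW = r$dW, db = as.vector(r$db),
       dx = if (need_dx) array(r$dx, dim = cache$in_dim) else NULL)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))
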