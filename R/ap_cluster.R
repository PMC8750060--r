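#' Affinity-propagation clustering of 1-D values
#'
#' Exemplar-based clustering by alternating, damped message passing between a
#' responsibility matrix R(i,k) and an availability matrix A(i,k) on the
#' similarity matrix s(i,k) = -(v_i - v_k)^2, with the preference on the
#' diagonal controlling how many exemplars emerge. Iteration stops when the
#' exemplar set has been stable for `convergence_iter` rounds or `max_iter`
#' is reached; after convergence cluster exemplars are refined to the member
#' maximising total within-cluster similarity and points are assigned to
#' their most similar exemplar.
#'
#' @param values Numeric vector (N >= 1).
#' @param preference Diagonal self-similarity; default the median of the
#'   off-diagonal similarities.
#' @param damping Damping factor in `[0.5, 1)` applied to both message
#'   matrices (default 0.5).
#' @param max_iter Maximum message-passing rounds (default 200).
#' @param convergence_iter Rounds of unchanged exemplar set required to stop
#'   (default 15).
#' @return List with `exemplars` (indices into `values`), `assignment`
#'   (exemplar index per point), `labels` (cluster id 1..K per point) and
#'   `converged` (logical).
#' @export
ap_cluster <- function(values, preference = NULL, damping = 0.5,
                       max_iter = 200L, convergence_iter = 15L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stop("need at least one value", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (damping < 0.5 || damping >= 1) {
    stop("`damping` must lie in [0.5, 1)", call. = FALSE)
  }
  if (n == 1L || max(values) == min(values)) {
    return(list(exemplars = 1L, assignment = rep(1L, n),
                labels = rep(1L, n), converged = TRUE))
  }

  S <- -outer(values, values, "-")^2
  if (is.null(preference)) {
    preference <- stats::median(S[upper.tri(S) | lower.tri(S)])
  }
  diag(S) <- preference

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- integer(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Mx <- matrix(max1, n, n)
    Mx[cbind(seq_len(n), max1_idx)] <- max2
    R <- damping * R + (1 - damping) * (S - Mx)
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    # off-diagonal: min(0, R(k,k) + sum_{i' != i,k} max(0, R(i',k)))
    #             = min(0, cs[k] - Rp[i,k])  since cs already holds R(k,k)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    Anew[Anew > 0] <- 0
    # diagonal: sum_{i' != k} max(0, R(i',k)) = cs[k] - R(k,k)
    diag(Anew) <- cs - diag(R)
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, prev_ex) && length(ex) > 0L) {
      stable <- stable + 1L
      if (stable >= convergence_iter) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
    prev_ex <- ex
  }

  exemplars <- which(diag(A) + diag(R) > 0)
  if (length(exemplars) == 0L) {
    exemplars <- which.max(diag(A) + diag(R))
  }
  # assign points to the most similar exemplar, then refine exemplars to the
  # member maximising within-cluster similarity (standard final step)
  assign_to <- exemplars[max.col(S[, exemplars, drop = FALSE], ties.method = "first")]
  assign_to[exemplars] <- exemplars
  for (e in unique(assign_to)) {
    members <- which(assign_to == e)
    sums <- colSums(S[members, members, drop = FALSE])
    new_e <- members[which.max(sums)]
    if (new_e != e) assign_to[members] <- new_e
  }
  exemplars <- sort(unique(assign_to))
  assign_to <- exemplars[max.col(S[, exemplars, drop = FALSE], ties.method = "first")]
  assign_to[exemplars] <- exemplars
  labels <- match(assign_to, exemplars)
  list(exemplars = exemplars, assignment = assign_to, labels = labels,
       converged = converged)
}
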