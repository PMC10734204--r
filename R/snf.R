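# Nonlinear cross-diffusion fusion of two similarity matrices over one
# entity type (sequence/structure similarity with the interaction-profile
# kernel), yielding the comprehensive similarity matrix for that type.

#' Row-normalize a nonnegative similarity matrix
#'
#' Each row is divided by its sum; an all-zero row becomes a uniform row
#' `1/N` (logged via a message).
#'
#' @param S Nonnegative square matrix.
#' @return Row-stochastic matrix.
#' @export
row_normalize <- function(S) {
  if (any(S < 0)) stop("similarity entries must be nonnegative")
  rs <- rowSums(S)
  if (any(rs == 0)) {
    message(sum(rs == 0), " all-zero row(s) replaced by uniform rows")
    S[rs == 0, ] <- 1 / ncol(S)
    rs <- rowSums(S)
  }
  S / rs
}

#' KNN-truncated local affinity operator
#'
#' Keeps, for each row `i`, only the `k` most similar entities (self always
#' included), renormalized to sum to 1; all other entries are set to 0. Ties
#' are broken by column index.
#'
#' @param S Nonnegative square similarity matrix.
#' @param k Neighborhood size (clipped to `N` with a warning if larger).
#' @return Row-stochastic sparse local affinity matrix.
#' @export
knn_affinity <- function(S, k) {
  n <- nrow(S)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) {
    warning("k = ", k, " exceeds N = ", n, "; clipped")
    k <- n
  }
  out <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    ord <- order(S[i, ], decreasing = TRUE)
    keep <- ord[seq_len(k)]
    if (!(i %in% keep)) keep[k] <- i   # self is always a neighbor
    v <- S[i, keep]
    tot <- sum(v)
    out[i, keep] <- if (tot > 0) v / tot else 1 / k
  }
  out
}

#' Default KNN size for fusion
#'
#' `ceiling(N / 3)` capped at 20 — a conventional choice; exposed as a
#' configuration knob because the neighborhood size is a free parameter of
#' the fusion.
#'
#' @param n Number of entities.
#' @return Integer neighborhood size.
#' @export
snf_default_k <- function(n) min(20L, max(1L, ceiling(n / 3)))

#' Nonlinear cross-diffusion fusion of two similarity matrices
#'
#' Starting from the row-normalized inputs, the two chains are alternately
#' diffused through fixed KNN-truncated local operators computed from the
#' *initial* similarities:
#' `S1 <- C1 %*% S2 %*% t(C1)` and `S2 <- C2 %*% S1 %*% t(C2)` (both from the
#' previous iterates), row-normalizing after every iteration and re-blending
#' half the identity (the self-similarity regularization customary for this
#' fusion scheme: the bare power iteration would converge to the
#' uninformative uniform matrix on any connected neighbor graph), until both
#' relative Frobenius changes fall below `tol` or `max_iter` is reached.
#' The result is the average of the two chains, symmetrized.
#'
#' @param S1,S2 Square nonnegative similarity matrices of equal shape.
#' @param k KNN size (default [snf_default_k()]).
#' @param tol Relative-change convergence threshold (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return Fused symmetric similarity matrix, with attributes
#'   `iterations` (integer) and `converged` (logical).
#' @export
snf_fuse <- function(S1, S2, k = NULL, tol = 1e-6, max_iter = 100L) {
  stopifnot(all(dim(S1) == dim(S2)))
  n <- nrow(S1)
  if (is.null(k)) k <- snf_default_k(n)
  C1 <- knn_affinity(S1, k)
  C2 <- knn_affinity(S2, k)
  P1 <- row_normalize(S1)
  P2 <- row_normalize(S2)
  I_half <- diag(n) / 2
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # identity re-blending keeps self-similarity dominant; without it the
    # cross-diffusion power iteration has the uninformative uniform matrix
    # as its fixed point on any connected neighbor graph
    N1 <- row_normalize(C1 %*% P2 %*% t(C1)) / 2 + I_half
    N2 <- row_normalize(C2 %*% P1 %*% t(C2)) / 2 + I_half
    r1 <- norm(N1 - P1, "F") / max(norm(P1, "F"), .Machine$double.eps)
    r2 <- norm(N2 - P2, "F") / max(norm(P2, "F"), .Machine$double.eps)
    P1 <- N1
    P2 <- N2
    if (r1 < tol && r2 < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("fusion did not converge within ", max_iter,
                          " iterations")
  S <- (P1 + P2) / 2
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(S1)
  attr(S, "iterations") <- it
  attr(S, "converged") <- converged
  S
}
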