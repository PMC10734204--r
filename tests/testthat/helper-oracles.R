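# Independent oracles and small fixture builders used across the suite.

# Edit distance with insertion/deletion cost 1 and substitution cost 2,
# by straightforward dynamic programming (independent of utils::adist).
lev_indel_dp <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j + 1L] + 1L,
        D[i + 1L, j] + 1L,
        D[i, j] + if (x[i] == y[j]) 0L else 2L)
    }
  }
  D[n + 1L, m + 1L]
}

lev_ratio_oracle <- function(a, b) {
  a <- unname(a); b <- unname(b)
  if (nchar(a) + nchar(b) == 0L) return(1)
  1 - lev_indel_dp(a, b) / (nchar(a) + nchar(b))
}

# AUC by exhaustive positive-negative pair counting with 0.5 tie credit.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# GIP kernel by an explicit double loop.
gip_oracle <- function(P, gamma) {
  n <- nrow(P)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
    }
  }
  K
}

# DLapRLS objective recomputed term by term with explicit trace loops.
dlaprls_loss_oracle <- function(ac, ad, IC, ID, Lc, Ld, Y, pc, pd) {
  trm <- function(A, M, B) sum(diag(t(A) %*% M %*% B))
  trm(ac, IC, ac) + trm(ad, ID, ad) +
    2 * sum(diag((IC %*% ac) %*% (ID %*% ad))) -
    4 * trm(ac, IC, Y) - 4 * trm(ad, ID, t(Y)) +
    4 * sum(Y^2) +
    pc * trm(ac, Lc, ac) + pd * trm(ad, Ld, ad)
}

random_binary_matrix <- function(n, m, p = 0.3, seed = 1) {
  set.seed(seed)
  Y <- matrix(rbinom(n * m, 1L, p), n, m,
              dimnames = list(sprintf("c%02d", 1:n), sprintf("d%02d", 1:m)))
  # guard against empty profiles so GIP bandwidths stay defined
  for (i in which(rowSums(Y) == 0)) Y[i, sample(m, 1L)] <- 1L
  for (j in which(colSums(Y) == 0)) Y[sample(n, 1L), j] <- 1L
  Y
}

# random PSD kernel pair via random embeddings
random_kernel <- function(n, d = 3, gamma = 0.3, seed = 1) {
  set.seed(seed)
  H <- matrix(rnorm(n * d), n, d)
  r <- rowSums(H^2)
  exp(-gamma * pmax(outer(r, r, `+`) - 2 * tcrossprod(H), 0))
}

small_study <- function(seed = 1, n_circ = 24L, n_drug = 16L) {
  simulate_study(synthetic_spec(n_circ = n_circ, n_drug = n_drug,
                                n_blocks = 2L, seed = seed))
}

fast_config <- function(seed = 1, epochs = 4L, ...) {
  assoc_config(dim = 8L, heads = 2L, epochs = epochs, sparsify_k = 5L,
               snf_k = 6L, seed = seed, ...)
}
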