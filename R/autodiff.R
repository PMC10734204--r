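# Reverse-mode automatic differentiation on a matrix tape.
#
# The attention encoder is trained with Adam, which needs gradients of the
# regularized least-squares objective with respect to every encoder parameter.
# All quantities are dense base-R matrices (problem sizes here are a few
# hundred nodes at most), so a small tape of matrix-level operations with
# hand-written vector-Jacobian products is sufficient and fast.
#
# Every op returns a "node": an environment holding `value` (a matrix),
# `parents` (list of nodes), and `backward` (a function that reads the node's
# accumulated gradient and adds each parent's share to `parent$grad`).
# Gradients only flow through nodes with `needs_grad = TRUE`.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    needs_grad = NULL) {
  nd <- new.env(parent = emptyenv(), size = 8L)
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  if (is.null(needs_grad)) {
    needs_grad <- FALSE
    for (p in parents) if (p$needs_grad) { needs_grad <- TRUE; break }
  }
  nd$needs_grad <- needs_grad
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd$tape <- tape
  nd
}

ad_const <- function(tape, value) {
  ad_node(tape, as.matrix(value), needs_grad = FALSE)
}

ad_param <- function(tape, value) {
  ad_node(tape, as.matrix(value), needs_grad = TRUE)
}

ad_accum <- function(p, g) {
  if (!p$needs_grad) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

#' @noRd
ad_backward <- function(root) {
  tape <- root$tape
  root$grad <- matrix(1, nrow(root$value), ncol(root$value))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && nd$needs_grad && !is.null(nd$backward)) {
      nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ad_mm <- function(a, b) {
  out <- ad_node(a$tape, a$value %*% b$value, list(a, b))
  out$backward <- function(g) {
    ad_accum(a, tcrossprod(g, b$value))
    ad_accum(b, crossprod(a$value, g))
  }
  out
}

ad_t <- function(a) {
  out <- ad_node(a$tape, t(a$value), list(a))
  out$backward <- function(g) ad_accum(a, t(g))
  out
}

ad_add <- function(a, b) {
  out <- ad_node(a$tape, a$value + b$value, list(a, b))
  out$backward <- function(g) { ad_accum(a, g); ad_accum(b, g) }
  out
}

ad_sub <- function(a, b) {
  out <- ad_node(a$tape, a$value - b$value, list(a, b))
  out$backward <- function(g) { ad_accum(a, g); ad_accum(b, -g) }
  out
}

ad_emul <- function(a, b) {
  out <- ad_node(a$tape, a$value * b$value, list(a, b))
  out$backward <- function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  }
  out
}

# multiply by a plain numeric constant
ad_scale <- function(a, k) {
  out <- ad_node(a$tape, a$value * k, list(a))
  out$backward <- function(g) ad_accum(a, g * k)
  out
}

# multiply a matrix node by a 1x1 scalar node
ad_scalar_mul <- function(a, s) {
  sv <- s$value[1L]
  out <- ad_node(a$tape, a$value * sv, list(a, s))
  out$backward <- function(g) {
    ad_accum(a, g * sv)
    ad_accum(s, matrix(sum(g * a$value), 1L, 1L))
  }
  out
}

ad_exp <- function(a) {
  v <- exp(a$value)
  out <- ad_node(a$tape, v, list(a))
  out$backward <- function(g) ad_accum(a, g * v)
  out
}

ad_square <- function(a) {
  out <- ad_node(a$tape, a$value^2, list(a))
  out$backward <- function(g) ad_accum(a, 2 * g * a$value)
  out
}

# elementwise power with constant exponent; values must stay positive
ad_powk <- function(a, p) {
  v <- a$value^p
  out <- ad_node(a$tape, v, list(a))
  out$backward <- function(g) ad_accum(a, g * p * a$value^(p - 1))
  out
}

ad_leaky <- function(a, slope = 0.2) {
  v <- a$value
  fac <- (v > 0) * (1 - slope) + slope
  out <- ad_node(a$tape, v * fac, list(a))
  out$backward <- function(g) ad_accum(a, g * fac)
  out
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  out <- ad_node(a$tape, v, list(a))
  out$backward <- function(g) ad_accum(a, g * v * (1 - v))
  out
}

# row sums as an N x 1 column
ad_rowsums <- function(a) {
  out <- ad_node(a$tape, matrix(rowSums(a$value), ncol = 1L), list(a))
  out$backward <- function(g) {
    ad_accum(a, matrix(g, nrow(a$value), ncol(a$value)))
  }
  out
}

ad_sum <- function(a) {
  out <- ad_node(a$tape, matrix(sum(a$value), 1L, 1L), list(a))
  out$backward <- function(g) {
    ad_accum(a, matrix(g[1L], nrow(a$value), ncol(a$value)))
  }
  out
}

# N x 1 vector -> N x N diagonal matrix
ad_diagm <- function(v) {
  n <- nrow(v$value)
  out <- ad_node(v$tape, diag(as.vector(v$value), n), list(v))
  out$backward <- function(g) ad_accum(v, matrix(diag(g), ncol = 1L))
  out
}

# scale row i of x by w[i] (w is an N x 1 node)
ad_rowscale <- function(x, w) {
  wv <- as.vector(w$value)
  out <- ad_node(x$tape, x$value * wv, list(x, w))
  out$backward <- function(g) {
    ad_accum(x, g * wv)
    ad_accum(w, matrix(rowSums(g * x$value), ncol = 1L))
  }
  out
}

# outer sum: u (N x 1), v (M x 1) -> N x M with entries u_i + v_j
ad_outer_sum <- function(u, v) {
  un <- length(u$value)
  vn <- length(v$value)
  val <- matrix(u$value, un, vn) + matrix(as.vector(v$value), un, vn,
                                          byrow = TRUE)
  out <- ad_node(u$tape, val, list(u, v))
  out$backward <- function(g) {
    ad_accum(u, matrix(rowSums(g), ncol = 1L))
    ad_accum(v, matrix(colSums(g), ncol = 1L))
  }
  out
}

# column j of x as an N x 1 node
ad_col <- function(x, j) {
  out <- ad_node(x$tape, x$value[, j, drop = FALSE], list(x))
  out$backward <- function(g) {
    gg <- matrix(0, nrow(x$value), ncol(x$value))
    gg[, j] <- g
    ad_accum(x, gg)
  }
  out
}

# cbind a list of N x 1 nodes into N x K
ad_cbind <- function(cols) {
  val <- do.call(cbind, lapply(cols, function(c) c$value))
  out <- ad_node(cols[[1L]]$tape, val, cols)
  out$backward <- function(g) {
    for (j in seq_along(cols)) {
      ad_accum(cols[[j]], g[, j, drop = FALSE])
    }
  }
  out
}

# Masked row-wise softmax. `mask` is a plain 0/1 matrix (not a node); rows
# whose mask is all zero come out as all-zero rows (no neighbors).
ad_softmax_rows <- function(x, mask = NULL) {
  v <- x$value
  if (is.null(mask)) {
    vm <- v
    keep <- NULL
  } else {
    keep <- mask > 0
    vm <- v * keep - 1e30 * !keep
  }
  mx <- vm[cbind(seq_len(nrow(vm)), max.col(vm, ties.method = "first"))]
  mx[mx <= -1e29] <- 0
  e <- exp(vm - mx)
  if (!is.null(keep)) e <- e * keep
  s <- rowSums(e)
  s[s == 0] <- 1
  a <- e / s
  out <- ad_node(x$tape, a, list(x))
  out$backward <- function(g) {
    dot <- rowSums(g * a)
    ad_accum(x, a * (g - dot))
  }
  out
}

# vector softmax over a K x 1 node
ad_softmax_vec <- function(x) {
  v <- as.vector(x$value)
  e <- exp(v - max(v))
  a <- matrix(e / sum(e), ncol = 1L)
  out <- ad_node(x$tape, a, list(x))
  out$backward <- function(g) {
    ad_accum(x, a * (g - sum(g * a)))
  }
  out
}

# Row-wise layer normalization with learnable gain/bias (1 x d nodes).
ad_layernorm <- function(x, gain, bias, eps = 1e-5) {
  v <- x$value
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  n <- nrow(v)
  gv <- rep(as.vector(gain$value), each = n)
  bv <- rep(as.vector(bias$value), each = n)
  val <- xhat * gv + bv
  out <- ad_node(x$tape, val, list(x, gain, bias))
  out$backward <- function(g) {
    ad_accum(gain, matrix(colSums(g * xhat), nrow = 1L))
    ad_accum(bias, matrix(colSums(g), nrow = 1L))
    gx <- g * gv
    m1 <- rowMeans(gx)
    m2 <- rowMeans(gx * xhat)
    ad_accum(x, (gx - m1 - xhat * m2) * istd)
  }
  out
}

# Gaussian kernel over the rows of an embedding node:
# K_ij = exp(-gamma * ||h_i - h_j||^2), built from primitives.
ad_gip_rows <- function(h, gamma) {
  r <- ad_rowsums(ad_square(h))
  d2 <- ad_sub(ad_outer_sum(r, r), ad_scale(ad_mm(h, ad_t(h)), 2))
  ad_exp(ad_scale(d2, -gamma))
}

# ---- numeric-gradient helper (used by tests) -------------------------------

# Central-difference gradient of f (returning a scalar) with respect to a
# matrix argument; independent oracle for the tape's vector-Jacobian products.
numeric_gradient <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
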