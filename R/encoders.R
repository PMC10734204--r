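# Dual hierarchical attention encoder.
#
# Intra-type stage: for each same-type relation, masked self-attention over
# the relation's neighbors (scores LeakyReLU(a' [h_i || h_j]), row softmax),
# relation-specific layer normalization, then relation-level fusion mixing a
# per-node (local) softmax importance with a global softmax-normalized
# relation weight, smoothed by a learnable scalar in [0, 1].
#
# Inter-type stage: both sides are projected into a common space; for each
# cross-type relation, attention over cross-type neighbors followed by
# relation-level fusion with per-node softmax weights.
#
# Multi-head attention averages the outputs of independent single-head
# computations, so the embedding dimension (and hence the kernel stage) is
# independent of the head count.

#' Encoder configuration
#'
#' @param dim Output embedding dimension (default 16).
#' @param heads Attention heads (default 5); heads are averaged.
#' @param layers_intra Intra-type encoder layers (default 1).
#' @param layers_inter Inter-type encoder layers (default 1).
#' @param dropout Dropout rate on post-softmax attention coefficients during
#'   training (default 0.026).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.2).
#' @param seed Seed for parameter initialization.
#' @return A list of class `cdn_encoder_config`.
#' @export
encoder_config <- function(dim = 16L, heads = 5L, layers_intra = 1L,
                           layers_inter = 1L, dropout = 0.026,
                           leaky_slope = 0.2, seed = 1L) {
  stopifnot(dim >= 1L, heads >= 1L, layers_intra >= 1L, layers_inter >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(dim = dim, heads = heads, layers_intra = layers_intra,
                 layers_inter = layers_inter, dropout = dropout,
                 leaky_slope = leaky_slope, seed = seed),
            class = "cdn_encoder_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

active_relations <- function(masks) {
  names(masks)[vapply(masks, function(m) sum(m) > 0, logical(1L))]
}

#' Initialize encoder parameters
#'
#' Glorot-uniform initialization under the configured seed. Attention
#' vectors are stored as two halves (`a1` for the source slot, `a2` for the
#' destination slot of the concatenation).
#'
#' @param graph A `cdn_graph` (determines which relations carry parameters).
#' @param n_c,n_d Numbers of circRNAs and drugs.
#' @param cfg An [encoder_config()].
#' @return Named flat list of parameter matrices.
#' @export
init_encoder_params <- function(graph, n_c, n_d, cfg) {
  set.seed(cfg$seed)
  d <- cfg$dim
  p <- list()
  p$W_intra_c <- glorot(n_d, d)
  p$W_intra_d <- glorot(n_c, d)
  rels <- list(c = active_relations(graph$intra_c),
               d = active_relations(graph$intra_d))
  for (l in seq_len(cfg$layers_intra)) {
    for (side in c("c", "d")) {
      for (r in rels[[side]]) {
        for (h in seq_len(cfg$heads)) {
          p[[sprintf("intra%d.%s.%s.h%d.a1", l, side, r, h)]] <- glorot(d, 1L)
          p[[sprintf("intra%d.%s.%s.h%d.a2", l, side, r, h)]] <- glorot(d, 1L)
        }
        p[[sprintf("intra%d.%s.%s.ln_g", l, side, r)]] <- matrix(1, 1L, d)
        p[[sprintf("intra%d.%s.%s.ln_b", l, side, r)]] <- matrix(0, 1L, d)
      }
      p[[sprintf("intra%d.%s.q1", l, side)]] <- glorot(d, 1L)
      p[[sprintf("intra%d.%s.q2", l, side)]] <- glorot(d, 1L)
      p[[sprintf("intra%d.%s.bg", l, side)]] <-
        matrix(0, length(rels[[side]]), 1L)
      p[[sprintf("intra%d.%s.t", l, side)]] <- matrix(0, 1L, 1L)
    }
  }
  irels <- active_relations(graph$inter)
  for (m in seq_len(cfg$layers_inter)) {
    p[[sprintf("inter%d.W_c", m)]] <- glorot(d, d)
    p[[sprintf("inter%d.W_d", m)]] <- glorot(d, d)
    for (r in irels) {
      for (h in seq_len(cfg$heads)) {
        p[[sprintf("inter%d.%s.h%d.a1", m, r, h)]] <- glorot(d, 1L)
        p[[sprintf("inter%d.%s.h%d.a2", m, r, h)]] <- glorot(d, 1L)
      }
      for (side in c("c", "d")) {
        p[[sprintf("inter%d.%s.%s.ln_g", m, r, side)]] <- matrix(1, 1L, d)
        p[[sprintf("inter%d.%s.%s.ln_b", m, r, side)]] <- matrix(0, 1L, d)
      }
    }
    for (side in c("c", "d")) {
      p[[sprintf("inter%d.%s.q1", m, side)]] <- glorot(d, 1L)
      p[[sprintf("inter%d.%s.q2", m, side)]] <- glorot(d, 1L)
    }
  }
  p
}

# dropout mask as a constant node factor (inverted dropout)
dropout_const <- function(tape, dim1, dim2, p) {
  keep <- matrix((stats::runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
  ad_const(tape, keep)
}

# one relation's masked multi-head attention over same-type neighbors
intra_relation_embed <- function(tape, H, mask, pn, key, cfg, training,
                                 collect = NULL) {
  slope <- cfg$leaky_slope
  acc <- NULL
  for (h in seq_len(cfg$heads)) {
    a1 <- pn[[sprintf("%s.h%d.a1", key, h)]]
    a2 <- pn[[sprintf("%s.h%d.a2", key, h)]]
    E <- ad_leaky(ad_outer_sum(ad_mm(H, a1), ad_mm(H, a2)), slope)
    A <- ad_softmax_rows(E, mask)
    if (!is.null(collect)) {
      collect$intra_attn[[sprintf("%s.h%d", key, h)]] <- A$value
    }
    if (training && cfg$dropout > 0) {
      A <- ad_emul(A, dropout_const(tape, nrow(mask), ncol(mask), cfg$dropout))
    }
    act <- ad_leaky(ad_layernorm(ad_mm(A, H),
                                 pn[[paste0(key, ".ln_g")]],
                                 pn[[paste0(key, ".ln_b")]]), slope)
    acc <- if (is.null(acc)) act else ad_add(acc, act)
  }
  out <- ad_scale(acc, 1 / cfg$heads)
  has_nb <- ad_const(tape, matrix((rowSums(mask) > 0) * 1, ncol = 1L))
  ad_rowscale(out, has_nb)   # no neighbors under this relation -> zero row
}

# relation-level fusion with global/local importance smoothing
intra_fuse <- function(tape, H, h_rels, pn, prefix, collect = NULL) {
  g <- lapply(h_rels, function(hr) {
    ad_add(ad_mm(H, pn[[paste0(prefix, ".q1")]]),
           ad_mm(hr, pn[[paste0(prefix, ".q2")]]))
  })
  B <- ad_softmax_rows(ad_cbind(g))
  bg <- ad_softmax_vec(pn[[paste0(prefix, ".bg")]])
  tt <- ad_sigmoid(pn[[paste0(prefix, ".t")]])
  ones <- ad_const(tape, matrix(1, nrow(H$value), 1L))
  BG <- ad_mm(ones, ad_t(bg))
  one <- ad_const(tape, matrix(1, 1L, 1L))
  W <- ad_add(ad_scalar_mul(BG, tt), ad_scalar_mul(B, ad_sub(one, tt)))
  if (!is.null(collect)) {
    collect$intra_local[[prefix]] <- B$value
    collect$intra_weights[[prefix]] <- W$value
  }
  z <- NULL
  for (k in seq_along(h_rels)) {
    term <- ad_rowscale(h_rels[[k]], ad_col(W, k))
    z <- if (is.null(z)) term else ad_add(z, term)
  }
  z
}

intra_layer <- function(tape, H, masks, pn, l, side, cfg, training,
                        collect = NULL) {
  rels <- active_relations(masks)
  h_rels <- lapply(rels, function(r) {
    intra_relation_embed(tape, H, masks[[r]],
                         pn, sprintf("intra%d.%s.%s", l, side, r),
                         cfg, training, collect)
  })
  intra_fuse(tape, H, h_rels, pn, sprintf("intra%d.%s", l, side), collect)
}

# one relation's cross-type attention; returns both sides' embeddings
inter_relation_embed <- function(tape, Pc, Pd, mask, pn, key, cfg, training,
                                 collect = NULL) {
  slope <- cfg$leaky_slope
  tmask <- t(mask)
  acc_c <- acc_d <- NULL
  for (h in seq_len(cfg$heads)) {
    a1 <- pn[[sprintf("%s.h%d.a1", key, h)]]
    a2 <- pn[[sprintf("%s.h%d.a2", key, h)]]
    E <- ad_leaky(ad_outer_sum(ad_mm(Pc, a1), ad_mm(Pd, a2)), slope)
    Ac <- ad_softmax_rows(E, mask)
    Ad <- ad_softmax_rows(ad_t(E), tmask)
    if (!is.null(collect)) {
      collect$inter_attn[[sprintf("%s.h%d.c", key, h)]] <- Ac$value
      collect$inter_attn[[sprintf("%s.h%d.d", key, h)]] <- Ad$value
    }
    if (training && cfg$dropout > 0) {
      Ac <- ad_emul(Ac, dropout_const(tape, nrow(mask), ncol(mask),
                                      cfg$dropout))
      Ad <- ad_emul(Ad, dropout_const(tape, ncol(mask), nrow(mask),
                                      cfg$dropout))
    }
    zc <- ad_leaky(ad_layernorm(ad_mm(Ac, Pd),
                                pn[[paste0(key, ".c.ln_g")]],
                                pn[[paste0(key, ".c.ln_b")]]), slope)
    zd <- ad_leaky(ad_layernorm(ad_mm(Ad, Pc),
                                pn[[paste0(key, ".d.ln_g")]],
                                pn[[paste0(key, ".d.ln_b")]]), slope)
    acc_c <- if (is.null(acc_c)) zc else ad_add(acc_c, zc)
    acc_d <- if (is.null(acc_d)) zd else ad_add(acc_d, zd)
  }
  has_c <- ad_const(tape, matrix((rowSums(mask) > 0) * 1, ncol = 1L))
  has_d <- ad_const(tape, matrix((colSums(mask) > 0) * 1, ncol = 1L))
  list(c = ad_rowscale(ad_scale(acc_c, 1 / cfg$heads), has_c),
       d = ad_rowscale(ad_scale(acc_d, 1 / cfg$heads), has_d))
}

inter_fuse <- function(tape, Z, z_rels, pn, prefix, collect = NULL) {
  f <- lapply(z_rels, function(zr) {
    ad_add(ad_mm(Z, pn[[paste0(prefix, ".q1")]]),
           ad_mm(zr, pn[[paste0(prefix, ".q2")]]))
  })
  Eps <- ad_softmax_rows(ad_cbind(f))
  if (!is.null(collect)) collect$inter_weights[[prefix]] <- Eps$value
  u <- NULL
  for (k in seq_along(z_rels)) {
    term <- ad_rowscale(z_rels[[k]], ad_col(Eps, k))
    u <- if (is.null(u)) term else ad_add(u, term)
  }
  u
}

inter_layer <- function(tape, Zc, Zd, masks, pn, m, cfg, training,
                        collect = NULL) {
  Pc <- ad_mm(Zc, pn[[sprintf("inter%d.W_c", m)]])
  Pd <- ad_mm(Zd, pn[[sprintf("inter%d.W_d", m)]])
  rels <- active_relations(masks)
  embeds <- lapply(rels, function(r) {
    inter_relation_embed(tape, Pc, Pd, masks[[r]], pn,
                         sprintf("inter%d.%s", m, r), cfg, training, collect)
  })
  list(c = inter_fuse(tape, Zc, lapply(embeds, `[[`, "c"), pn,
                      sprintf("inter%d.c", m), collect),
       d = inter_fuse(tape, Zd, lapply(embeds, `[[`, "d"), pn,
                      sprintf("inter%d.d", m), collect))
}

#' Run the dual hierarchical attention encoder
#'
#' Produces the per-layer embedding stacks
#' `H_c = {H0, Z1..Zt, U1..UM}` (and the drug analog): the initial
#' projections `H0_c = S_c Y_train W_c`, `H0_d = S_d t(Y_train) W_d`, then
#' `layers_intra` intra-type layers and `layers_inter` inter-type layers,
#' each consuming the previous layer's output.
#'
#' @param graph A `cdn_graph`.
#' @param S_c,S_d Fused similarity matrices.
#' @param Y_train Binary training association matrix.
#' @param params Parameter list from [init_encoder_params()].
#' @param cfg An [encoder_config()].
#' @param training Apply dropout to attention coefficients (default FALSE).
#' @param tape Optionally, an existing tape to build on.
#' @param collect Optional environment; when supplied, pre-dropout attention
#'   coefficient matrices and relation-fusion weights are recorded in it
#'   (fields `intra_attn`, `intra_local`, `intra_weights`, `inter_attn`,
#'   `inter_weights`) for inspection.
#' @return List with `tape`, `param_nodes`, and node stacks `Hc`, `Hd`.
#' @export
encoder_forward <- function(graph, S_c, S_d, Y_train, params, cfg,
                            training = FALSE, tape = NULL, collect = NULL) {
  if (is.null(tape)) tape <- ad_tape()
  if (!is.null(collect)) {
    collect$intra_attn <- list(); collect$intra_local <- list()
    collect$intra_weights <- list(); collect$inter_attn <- list()
    collect$inter_weights <- list()
  }
  pn <- lapply(params, function(v) ad_param(tape, v))
  Mc <- ad_const(tape, S_c %*% Y_train)        # constants: pre-multiplied
  Md <- ad_const(tape, S_d %*% t(Y_train))
  H0c <- ad_mm(Mc, pn$W_intra_c)
  H0d <- ad_mm(Md, pn$W_intra_d)
  Hc <- list(H0c)
  Hd <- list(H0d)
  zc <- H0c; zd <- H0d
  for (l in seq_len(cfg$layers_intra)) {
    zc_new <- intra_layer(tape, zc, graph$intra_c, pn, l, "c", cfg, training,
                          collect)
    zd_new <- intra_layer(tape, zd, graph$intra_d, pn, l, "d", cfg, training,
                          collect)
    zc <- zc_new; zd <- zd_new
    Hc <- c(Hc, list(zc)); Hd <- c(Hd, list(zd))
  }
  for (m in seq_len(cfg$layers_inter)) {
    u <- inter_layer(tape, zc, zd, graph$inter, pn, m, cfg, training,
                     collect)
    zc <- u$c; zd <- u$d
    Hc <- c(Hc, list(zc)); Hd <- c(Hd, list(zd))
  }
  list(tape = tape, param_nodes = pn, Hc = Hc, Hd = Hd)
}

#' Encoder forward pass returning plain matrices (no gradients, no dropout)
#'
#' @inheritParams encoder_forward
#' @return List of embedding-matrix stacks `Hc`, `Hd`.
#' @export
encoder_embeddings <- function(graph, S_c, S_d, Y_train, params, cfg) {
  fw <- encoder_forward(graph, S_c, S_d, Y_train, params, cfg,
                        training = FALSE)
  list(Hc = lapply(fw$Hc, function(n) n$value),
       Hd = lapply(fw$Hd, function(n) n$value))
}
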