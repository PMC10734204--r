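# Shared small graph fixture for encoder tests.
encoder_fixture <- function(seed = 51, n_c = 12L, n_d = 9L) {
  Y <- random_binary_matrix(n_c, n_d, p = 0.35, seed = seed)
  set.seed(seed + 1)
  Sc <- matrix(runif(n_c^2, 0.2, 1), n_c, n_c)
  Sc <- (Sc + t(Sc)) / 2; diag(Sc) <- 1
  Sd <- matrix(runif(n_d^2, 0.2, 1), n_d, n_d)
  Sd <- (Sd + t(Sd)) / 2; diag(Sd) <- 1
  g <- build_hetero_graph(Y, Sc, Sd, sparsify_k = 3L)
  list(Y = Y, Sc = Sc, Sd = Sd, g = g)
}

test_that("the stack has 1 + t + M embedding matrices per side", {
  fx <- encoder_fixture()
  for (tm in list(c(1L, 1L), c(2L, 1L), c(1L, 2L))) {
    cfg <- encoder_config(dim = 6L, heads = 2L, layers_intra = tm[1],
                          layers_inter = tm[2], dropout = 0, seed = 3)
    par <- init_encoder_params(fx$g, nrow(fx$Y), ncol(fx$Y), cfg)
    emb <- encoder_embeddings(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg)
    expect_length(emb$Hc, 1L + tm[1] + tm[2])
    expect_length(emb$Hd, 1L + tm[1] + tm[2])
    expect_true(all(vapply(emb$Hc, ncol, integer(1)) == 6L))
    expect_equal(nrow(emb$Hd[[1]]), ncol(fx$Y))
  }
})

test_that("initial features compose the two-step product", {
  fx <- encoder_fixture(52)
  cfg <- encoder_config(dim = 5L, heads = 1L, dropout = 0, seed = 4)
  par <- init_encoder_params(fx$g, nrow(fx$Y), ncol(fx$Y), cfg)
  emb <- encoder_embeddings(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg)
  # brute-force triple loop for H0 = S_c Y W
  n_c <- nrow(fx$Y); n_d <- ncol(fx$Y)
  H0 <- matrix(0, n_c, 5)
  for (i in 1:n_c) for (k in 1:5) {
    acc <- 0
    for (j in 1:n_d) for (l in 1:n_c) {
      acc <- acc + fx$Sc[i, l] * fx$Y[l, j] * par$W_intra_c[j, k]
    }
    H0[i, k] <- acc
  }
  expect_equal(unname(emb$Hc[[1]]), H0, tolerance = 1e-10)
  # zero training matrix gives zero initial features
  emb0 <- encoder_embeddings(fx$g, fx$Sc, fx$Sd, fx$Y * 0L, par, cfg)
  expect_equal(sum(abs(emb0$Hc[[1]])), 0)
})

test_that("attention coefficients are row-stochastic over each relation", {
  fx <- encoder_fixture(53, n_c = 30L, n_d = 20L)
  cfg <- encoder_config(dim = 8L, heads = 3L, dropout = 0, seed = 5)
  par <- init_encoder_params(fx$g, nrow(fx$Y), ncol(fx$Y), cfg)
  col <- new.env()
  encoder_forward(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg, collect = col)
  expect_gt(length(col$intra_attn), 0)
  for (A in col$intra_attn) {
    rs <- rowSums(A)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-6))
  }
  for (A in col$inter_attn) {
    rs <- rowSums(A)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-6))
  }
  # relation-fusion mixtures are convex weights
  for (W in col$intra_weights) {
    expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-6)
    expect_true(all(W >= 0))
  }
  for (E in col$inter_weights) {
    expect_equal(unname(rowSums(E)), rep(1, nrow(E)), tolerance = 1e-6)
  }
})

test_that("a single neighbor receives attention exactly 1", {
  fx <- encoder_fixture(54)
  # relation mask with exactly one neighbor for node 1
  mask <- matrix(0, 12, 12)
  mask[1, 5] <- 1
  fx$g$intra_c$r1 <- mask
  fx$g$intra_c$r2[] <- 0
  fx$g$intra_c$r3[] <- 0
  cfg <- encoder_config(dim = 4L, heads = 1L, dropout = 0, seed = 6)
  par <- init_encoder_params(fx$g, 12L, 9L, cfg)
  col <- new.env()
  encoder_forward(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg, collect = col)
  A <- col$intra_attn[["intra1.c.r1.h1"]]
  expect_equal(A[1, 5], 1)
  expect_equal(sum(A), 1)   # all other rows are isolated -> zero
})

test_that("a single relation collapses the fusion to that relation's embedding", {
  fx <- encoder_fixture(55)
  g1 <- collapse_relations(fx$g)
  cfg <- encoder_config(dim = 4L, heads = 2L, dropout = 0, seed = 7)
  par <- init_encoder_params(g1, 12L, 9L, cfg)
  fw <- encoder_forward(g1, fx$Sc, fx$Sd, fx$Y, par, cfg)
  # recompute the single relation's embedding directly: fusion weight must be 1
  tp <- fw$tape
  pn <- fw$param_nodes
  h_rel <- circdrugnet:::intra_relation_embed(
    tp, fw$Hc[[1]], g1$intra_c$r1, pn, "intra1.c.r1", cfg, FALSE)
  expect_equal(fw$Hc[[2]]$value, h_rel$value, tolerance = 1e-12)
})

test_that("multi-head output is the mean of the single-head computations", {
  fx <- encoder_fixture(56)
  cfg <- encoder_config(dim = 4L, heads = 3L, dropout = 0, seed = 8)
  par <- init_encoder_params(fx$g, 12L, 9L, cfg)
  fw <- encoder_forward(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg)
  tp <- ad_tape()
  pn1 <- lapply(par, function(v) circdrugnet:::ad_param(tp, v))
  H <- circdrugnet:::ad_mm(
    circdrugnet:::ad_const(tp, fx$Sc %*% fx$Y), pn1$W_intra_c)
  cfg1 <- cfg; cfg1$heads <- 1L
  per_head <- lapply(1:3, function(h) {
    pn_h <- pn1
    pn_h[["intra1.c.r1.h1.a1"]] <- pn1[[sprintf("intra1.c.r1.h%d.a1", h)]]
    pn_h[["intra1.c.r1.h1.a2"]] <- pn1[[sprintf("intra1.c.r1.h%d.a2", h)]]
    circdrugnet:::intra_relation_embed(
      tp, H, fx$g$intra_c$r1, pn_h, "intra1.c.r1", cfg1, FALSE)$value
  })
  multi <- circdrugnet:::intra_relation_embed(
    tp, H, fx$g$intra_c$r1, pn1, "intra1.c.r1", cfg, FALSE)$value
  expect_equal(multi, Reduce(`+`, per_head) / 3, tolerance = 1e-12)
})

test_that("embeddings are permutation-equivariant in the circRNA order", {
  fx <- encoder_fixture(57)
  cfg <- encoder_config(dim = 5L, heads = 2L, dropout = 0, seed = 9)
  set.seed(10)
  perm <- sample(nrow(fx$Y))
  g <- build_hetero_graph(fx$Y, fx$Sc, fx$Sd, K_c = 2, K_d = 2,
                          sparsify_k = 3L)
  par <- init_encoder_params(g, nrow(fx$Y), ncol(fx$Y), cfg)
  emb <- encoder_embeddings(g, fx$Sc, fx$Sd, fx$Y, par, cfg)
  Yp <- fx$Y[perm, ]
  Scp <- fx$Sc[perm, perm]
  gp <- build_hetero_graph(Yp, Scp, fx$Sd, K_c = 2, K_d = 2, sparsify_k = 3L)
  parp <- par   # same parameters; W_intra_d rows follow the circRNA order
  parp$W_intra_d <- par$W_intra_d[perm, , drop = FALSE]
  embp <- encoder_embeddings(gp, Scp, fx$Sd, Yp, parp, cfg)
  for (l in seq_along(emb$Hc)) {
    expect_equal(embp$Hc[[l]], emb$Hc[[l]][perm, ], tolerance = 1e-9)
    expect_equal(embp$Hd[[l]], emb$Hd[[l]], tolerance = 1e-9)
  }
})

test_that("the forward pass is deterministic given parameters and seed", {
  fx <- encoder_fixture(58)
  cfg <- encoder_config(dim = 4L, heads = 2L, dropout = 0, seed = 11)
  par <- init_encoder_params(fx$g, 12L, 9L, cfg)
  e1 <- encoder_embeddings(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg)
  e2 <- encoder_embeddings(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg)
  expect_identical(e1, e2)
  # dropout draws from the RNG stream: same state, same masks
  cfgd <- encoder_config(dim = 4L, heads = 2L, dropout = 0.3, seed = 11)
  set.seed(99)
  f1 <- encoder_forward(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfgd, training = TRUE)
  set.seed(99)
  f2 <- encoder_forward(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfgd, training = TRUE)
  expect_identical(f1$Hc[[3]]$value, f2$Hc[[3]]$value)
})

test_that("nodes without neighbors under a relation embed to zero", {
  fx <- encoder_fixture(59)
  iso <- which(rowSums(fx$g$intra_c$r1) == 0)
  if (length(iso) == 0) {
    fx$g$intra_c$r1[2, ] <- 0
    fx$g$intra_c$r1[, 2] <- 0
    iso <- 2L
  }
  cfg <- encoder_config(dim = 4L, heads = 2L, dropout = 0, seed = 12)
  par <- init_encoder_params(fx$g, 12L, 9L, cfg)
  fw <- encoder_forward(fx$g, fx$Sc, fx$Sd, fx$Y, par, cfg)
  h_rel <- circdrugnet:::intra_relation_embed(
    fw$tape, fw$Hc[[1]], fx$g$intra_c$r1, fw$param_nodes, "intra1.c.r1",
    cfg, FALSE)
  expect_equal(sum(abs(h_rel$value[iso, ])), 0)
})
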