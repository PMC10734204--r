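# Shared random instance: PSD kernels from random embeddings plus a random
# binary training matrix.
dlap_instance <- function(seed, n_c = NULL, n_d = NULL) {
  set.seed(seed)
  if (is.null(n_c)) n_c <- sample(4:20, 1)
  if (is.null(n_d)) n_d <- sample(4:20, 1)
  IC <- random_kernel(n_c, gamma = runif(1, 0.1, 0.6), seed = seed)
  ID <- random_kernel(n_d, gamma = runif(1, 0.1, 0.6), seed = seed + 1)
  Y <- matrix(rbinom(n_c * n_d, 1L, 0.3), n_c, n_d) * 1
  list(IC = IC, ID = ID, Y = Y,
       Lc = normalized_laplacian(IC), Ld = normalized_laplacian(ID))
}

test_that("embedding kernels match hand values and the double-loop oracle", {
  H <- rbind(c(0), c(1))
  K <- embedding_kernels(list(H), gamma = 1 / 75)[[1]]
  expect_equal(K[1, 2], exp(-1 / 75), tolerance = 1e-12)
  H2 <- rbind(c(1, 2), c(1, 2), c(0, 0))
  expect_equal(embedding_kernels(list(H2), 0.3)[[1]][1, 2], 1)
  set.seed(61)
  stack <- lapply(1:4, function(i) matrix(rnorm(30 * 5), 30, 5))
  ks <- embedding_kernels(stack, gamma = 0.2)
  expect_length(ks, 4L)
  for (K in ks) {
    expect_equal(K, gip_oracle(stack[[which(vapply(ks, identical, TRUE,
      y = K), useNames = FALSE)]], 0.2), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("kernel fusion is the uniform average with selectable layers", {
  K1 <- random_kernel(6, seed = 62)
  K2 <- random_kernel(6, seed = 63)
  K3 <- random_kernel(6, seed = 64)
  expect_equal(fuse_kernels(list(K1, K1, K1)), K1)
  expect_equal(fuse_kernels(list(K1, K2))[2, 3], (K1[2, 3] + K2[2, 3]) / 2)
  Fk <- fuse_kernels(list(K1, K2, K3))
  expect_equal(Fk, (K1 + K2 + K3) / 3)           # weights 1/(K+1), sum 1
  expect_identical(Fk, t(Fk))
  expect_gte(min(eigen(Fk, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_true(all(Fk >= 0 & Fk <= 1))
  expect_equal(fuse_kernels(list(K1, K2, K3), layers = c(1, 3)),
               (K1 + K3) / 2)
  expect_error(fuse_kernels(list()), "no kernels")
})

test_that("the normalized Laplacian has the degree-scaled nullspace and is PSD", {
  L <- normalized_laplacian(matrix(1, 2, 2))
  expect_equal(L, rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  for (seed in 65:68) {
    K <- random_kernel(10, seed = seed)
    L <- normalized_laplacian(K)
    v <- sqrt(rowSums(K))
    expect_equal(max(abs(L %*% v)), 0, tolerance = 1e-10)
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  expect_error(normalized_laplacian(matrix(0, 2, 2)), "zero row sum")
})

test_that("the objective matches a term-by-term trace oracle", {
  ins <- dlap_instance(70)
  expect_equal(dlaprls_loss(ins$Y * 0, t(ins$Y) * 0, ins$IC, ins$ID,
                            ins$Lc, ins$Ld, ins$Y * 0), 0)
  expect_equal(dlaprls_loss(ins$Y * 0, t(ins$Y) * 0, ins$IC, ins$ID,
                            ins$Lc, ins$Ld, ins$Y), 4 * sum(ins$Y))
  for (seed in 71:74) {
    ins <- dlap_instance(seed)
    set.seed(seed)
    ac <- matrix(rnorm(length(ins$Y)), nrow(ins$Y))
    ad <- matrix(rnorm(length(ins$Y)), ncol(ins$Y))
    expect_equal(
      dlaprls_loss(ac, ad, ins$IC, ins$ID, ins$Lc, ins$Ld, ins$Y, 0.3, 0.7),
      dlaprls_loss_oracle(ac, ad, ins$IC, ins$ID, ins$Lc, ins$Ld, ins$Y,
                          0.3, 0.7),
      tolerance = 1e-10)
  }
})

test_that("identity kernels with no regularization reduce the updates to
           the doubled-residual form", {
  ins <- dlap_instance(75, n_c = 8, n_d = 6)
  I_c <- diag(8); I_d <- diag(6)
  set.seed(75)
  ad <- matrix(rnorm(48, sd = 0.2), 6, 8)
  ac <- update_alpha_c(ad, I_c, I_d, ins$Lc * 0, ins$Y, phi_c = 0,
                       jitter = 0)
  expect_equal(ac, 2 * ins$Y - t(I_d %*% ad), tolerance = 1e-10)
  ac0 <- matrix(rnorm(48, sd = 0.2), 8, 6)
  ad2 <- update_alpha_d(ac0, I_c, I_d, ins$Ld * 0, ins$Y, phi_d = 0,
                        jitter = 0)
  expect_equal(ad2, 2 * t(ins$Y) - t(I_c %*% ac0), tolerance = 1e-10)
})

test_that("each closed-form update zeroes its own partial derivative", {
  for (seed in 76:80) {
    ins <- dlap_instance(seed)
    set.seed(seed)
    ad <- matrix(rnorm(length(ins$Y), sd = 0.1), ncol(ins$Y))
    ac <- update_alpha_c(ad, ins$IC, ins$ID, ins$Lc, ins$Y)
    f_c <- function(a) dlaprls_loss(matrix(a, nrow(ins$Y)), ad, ins$IC,
                                    ins$ID, ins$Lc, ins$Ld, ins$Y)
    g <- circdrugnet:::numeric_gradient(f_c, ac)
    expect_lt(norm(g, "F") / (1 + norm(ac, "F")), 1e-5)
    ad2 <- update_alpha_d(ac, ins$IC, ins$ID, ins$Ld, ins$Y)
    f_d <- function(a) dlaprls_loss(ac, matrix(a, ncol(ins$Y)), ins$IC,
                                    ins$ID, ins$Lc, ins$Ld, ins$Y)
    g2 <- circdrugnet:::numeric_gradient(f_d, ad2)
    expect_lt(norm(g2, "F") / (1 + norm(ad2, "F")), 1e-5)
  }
})

test_that("sequential exact block updates never increase the objective", {
  for (seed in 81:90) {
    ins <- dlap_instance(seed)
    set.seed(seed)
    ac <- matrix(rnorm(length(ins$Y), sd = 0.01), nrow(ins$Y))
    ad <- matrix(rnorm(length(ins$Y), sd = 0.01), ncol(ins$Y))
    J <- dlaprls_loss(ac, ad, ins$IC, ins$ID, ins$Lc, ins$Ld, ins$Y)
    for (it in 1:10) {
      ac <- update_alpha_c(ad, ins$IC, ins$ID, ins$Lc, ins$Y)
      J1 <- dlaprls_loss(ac, ad, ins$IC, ins$ID, ins$Lc, ins$Ld, ins$Y)
      expect_lte(J1, J + 1e-8 * (1 + abs(J)))
      ad <- update_alpha_d(ac, ins$IC, ins$ID, ins$Ld, ins$Y)
      J <- dlaprls_loss(ac, ad, ins$IC, ins$ID, ins$Lc, ins$Ld, ins$Y)
      expect_lte(J, J1 + 1e-8 * (1 + abs(J1)))
    }
  }
})

test_that("prediction is the halved sum of the two views and linear in alpha", {
  ins <- dlap_instance(91, n_c = 7, n_d = 5)
  expect_equal(predict_association(ins$Y * 0, t(ins$Y) * 0, ins$IC, ins$ID),
               ins$Y * 0)
  set.seed(91)
  ac <- matrix(rnorm(35), 7, 5); ad <- matrix(rnorm(35), 5, 7)
  Fhat <- predict_association(ac, ad, ins$IC, ins$ID)
  # brute-force recomputation
  manual <- (ins$IC %*% ac + t(ins$ID %*% ad)) / 2
  expect_equal(Fhat, manual, tolerance = 1e-12)
  expect_equal(predict_association(2 * ac, 2 * ad, ins$IC, ins$ID),
               2 * Fhat, tolerance = 1e-12)
  # both views solving the same target average to it
  ac_y <- solve(ins$IC, ins$Y)
  ad_y <- solve(ins$ID, t(ins$Y))
  expect_equal(predict_association(ac_y, ad_y, ins$IC, ins$ID), ins$Y,
               tolerance = 1e-8)
})

test_that("the fit is seeded, labeled, and records its objective trace", {
  ins <- dlap_instance(92, n_c = 10, n_d = 8)
  dimnames(ins$Y) <- list(paste0("c", 1:10), paste0("d", 1:8))
  f1 <- dlaprls_fit(ins$IC, ins$ID, ins$Y, seed = 5)
  f2 <- dlaprls_fit(ins$IC, ins$ID, ins$Y, seed = 5)
  expect_identical(f1$scores, f2$scores)
  expect_identical(dimnames(f1$scores), dimnames(ins$Y))
  expect_length(f1$J, 2L)
  gs <- dlaprls_fit(ins$IC, ins$ID, ins$Y, seed = 5, mode = "gauss-seidel",
                    n_pass = 5L)
  expect_true(all(diff(gs$J) <= 1e-8 * (1 + abs(gs$J[-length(gs$J)]))))
})
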