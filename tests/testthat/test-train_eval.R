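test_that("AUC agrees with the brute-force pairwise oracle, ties included", {
  expect_equal(evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))$auc, 0)
  expect_equal(evaluate_scores(c(0.6, 0.4, 0.5), c(1, 0, 1))$auc, 1)
  set.seed(101)
  for (i in 1:300) {
    n <- sample(4:25, 1)
    # coarse scores force ties; random labels with both classes
    sc <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(evaluate_scores(sc, lb)$auc, auc_bruteforce(sc, lb))
  }
  expect_error(evaluate_scores(c(1, 2), c(1, 1)), "one class")
})

test_that("AUC never decreases when every positive's score improves", {
  set.seed(102)
  for (i in 1:50) {
    n <- 30
    sc <- runif(n)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.4))
    bumped <- sc + 0.2 * (lb == 1)
    expect_gte(evaluate_scores(bumped, lb)$auc, evaluate_scores(sc, lb)$auc)
  }
})

test_that("AUPR and thresholded metrics behave at the extremes", {
  m <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$aupr, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$specificity, 1)
  # random scorer on balanced labels: AUPR near the positive prevalence
  set.seed(103)
  m2 <- evaluate_scores(runif(4000), rep(c(0, 1), 2000))
  expect_lt(abs(m2$aupr - 0.5), 0.05)
  expect_true(all(unlist(m2[, 1:7]) >= 0 & unlist(m2[, 1:7]) <= 1))
})

test_that("cross-validation returns a report per fold plus the fold mean", {
  st <- small_study(seed = 104)
  sim <- study_similarities(st)
  cv <- suppressWarnings(run_cv(st$Y, sim$CSS, sim$DSS, fast_config(104),
                                k = 3))
  expect_s3_class(cv, "cdn_cv")
  expect_equal(nrow(cv$metrics), 3L)
  expect_equal(cv$summary$auc, mean(cv$metrics$auc))
  expect_equal(glance(cv)$folds, 3L)
  expect_equal(nrow(tidy(cv)), 3L)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("identical master seeds give bitwise-identical fold metrics", {
  st <- small_study(seed = 105)
  sim <- study_similarities(st)
  cv1 <- suppressWarnings(run_cv(st$Y, sim$CSS, sim$DSS, fast_config(7), k = 3))
  cv2 <- suppressWarnings(run_cv(st$Y, sim$CSS, sim$DSS, fast_config(7), k = 3))
  expect_identical(cv1$metrics, cv2$metrics)
  cv3 <- suppressWarnings(run_cv(st$Y, sim$CSS, sim$DSS, fast_config(8), k = 3))
  expect_false(identical(cv1$metrics$auc, cv3$metrics$auc))
})

test_that("training decreases the objective on a small planted fixture", {
  st <- small_study(seed = 106)
  sim <- study_similarities(st)
  split <- make_cv_folds(st$Y, 3, 106)
  Ytr <- mask_positives(st$Y, split, 1)
  cfg <- fast_config(106, epochs = 10L)
  mask <- circdrugnet:::training_sample_mask(Ytr, split, 1)
  m <- suppressWarnings(train_model(Ytr, sim$CSS, sim$DSS, mask, cfg))
  expect_lt(m$loss[length(m$loss)], m$loss[1])
  expect_true(all(is.finite(m$loss)))
  expect_s3_class(glance(m), "tbl_df")
  expect_equal(nrow(tidy(m)), length(st$Y))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("the relation ablation collapses the graph to one relation per kind", {
  st <- small_study(seed = 107)
  sim <- study_similarities(st)
  split <- make_cv_folds(st$Y, 3, 107)
  Ytr <- mask_positives(st$Y, split, 1)
  m <- suppressWarnings(train_model(Ytr, sim$CSS, sim$DSS, NULL,
                                    fast_config(107, ablation = "multi")))
  expect_length(m$graph$inter, 1L)
  expect_length(m$graph$intra_c, 1L)
  # kernel-layer ablations select the retained stack layers
  cfg_i <- fast_config(107, ablation = "intra")
  expect_equal(circdrugnet:::fusion_layers(cfg_i), c(1L, 3L))
  cfg_e <- fast_config(107, ablation = "inter")
  expect_equal(circdrugnet:::fusion_layers(cfg_e), c(1L, 2L))
})

test_that("candidate ranking is score-ordered with lexicographic ties", {
  sc <- matrix(c(0.3, 0.9, 0.1, 0.9,
                 0.2, 0.2, 0.2, 0.2), 4, 2,
               dimnames = list(c("c_b", "c_a", "c_d", "c_c"),
                               c("drugA", "drugB")))
  r <- rank_candidates(sc, "drugA", top_n = 4)
  expect_equal(r$circRNA[1:2], c("c_a", "c_c"))   # tie at 0.9 -> id order
  expect_equal(r$rank, 1:4)
  r2 <- rank_candidates(sc, "drugB", top_n = 4)
  expect_equal(r2$circRNA, sort(rownames(sc)))    # all tied -> id order
  expect_warning(r3 <- rank_candidates(sc, "drugA", top_n = 10), "all")
  expect_equal(nrow(r3), 4L)
  expect_error(rank_candidates(sc, "nope"), "unknown drug")
  # known positives can be excluded
  Y <- matrix(0L, 4, 2, dimnames = dimnames(sc))
  Y["c_a", "drugA"] <- 1L
  r4 <- rank_candidates(sc, "drugA", top_n = 3, exclude_known = Y)
  expect_false("c_a" %in% r4$circRNA)
})

test_that("ab initio mode blanks one drug column and makes it a tail node", {
  Y <- random_binary_matrix(8, 5, p = 0.4, seed = 108)
  drug <- colnames(Y)[2]
  Y2 <- ab_initio(Y, drug)
  expect_equal(sum(Y2[, drug]), 0L)
  expect_identical(Y2[, -2], Y[, -2])
  deg <- colSums(Y2)
  expect_identical(unname(classify_head_tail(deg, K = 0)[2]), "tail")
  expect_error(ab_initio(Y, "missing"), "unknown drug")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  set.seed(109)
  for (i in 1:10) {
    sc <- round(runif(60), 2)   # rounding forces some ties
    lb <- c(0, 1, rbinom(58, 1, 0.5))
    expect_equal(
      evaluate_scores(sc, lb)$auc,
      as.numeric(pROC::auc(pROC::roc(lb, sc, direction = "<",
                                     quiet = TRUE))))
  }
})
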