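# Cross-validation, the seven evaluation metrics, candidate ranking and
# cold-start (ab initio) mode.

#' Seven evaluation metrics for scored pairs
#'
#' AUC is the rank-based probability that a random positive outscores a
#' random negative, with 0.5 credit for ties; AUPR is the area under the
#' precision-recall curve with step interpolation. The five thresholded
#' metrics cut the min-max-scaled scores at `threshold`.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels of the same length (both classes required).
#' @param threshold Decision cutoff on the scaled scores (default 0.5).
#' @return One-row tibble with `auc`, `aupr`, `f1`, `accuracy`, `recall`,
#'   `precision`, `specificity`, `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUC undefined: only one class present")

  r <- rank(scores)   # midranks give the 0.5 tie credit
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  n <- length(scores)
  tp <- cumsum(l_sorted)
  # evaluate precision/recall only at the last index of each tied group
  grp_end <- which(s_sorted != c(s_sorted[-1L], NA) | seq_len(n) == n)
  rec <- tp[grp_end] / np
  prec <- tp[grp_end] / grp_end
  aupr <- sum(diff(c(0, rec)) * prec)

  rng <- range(scores)
  scaled <- if (rng[2] > rng[1]) (scores - rng[1]) / (rng[2] - rng[1]) else
    rep(0.5, n)
  pred <- as.integer(scaled >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- TP / (TP + FN)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(auc = auc, aupr = aupr, f1 = f1,
                 accuracy = (TP + TN) / n, recall = recall,
                 precision = precision,
                 specificity = TN / (TN + FP), threshold = threshold)
}

# balanced training-sample mask for fold k: training positives plus the
# other folds' negatives
training_sample_mask <- function(Y_train, split, fold) {
  mask <- (Y_train == 1) * 1
  for (f in seq_len(split$fold_count)) {
    if (f == fold) next
    neg <- split$folds[[f]]
    neg <- neg[neg$label == 0L, , drop = FALSE]
    mask[cbind(neg$i, neg$j)] <- 1
  }
  mask
}

#' k-fold cross-validation of the full pipeline
#'
#' Positives are partitioned into `k` folds (balanced with sampled
#' negatives); for each fold the pipeline is retrained on the remaining
#' samples — interaction-profile kernels, fusion, graph typing and encoder
#' training all recomputed from the masked matrix — and the held-out fold's
#' pairs are scored from the prediction matrix.
#'
#' @param Y Binary association matrix (named rows/columns).
#' @param CSS,DSS Sequence and structural similarity matrices.
#' @param cfg A [assoc_config()]; `cfg$seed` is the master seed fanned out to
#'   fold assignment, negative sampling, initialization and dropout.
#' @param k Fold count (default 5).
#' @param part_c,part_d Optional externally supplied head/tail partitions.
#' @param keep_models Keep the per-fold `cdn_model` objects (default FALSE).
#' @return Object of class `cdn_cv` with per-fold `metrics`, their mean in
#'   `summary`, the `split`, and optionally `models`.
#' @export
run_cv <- function(Y, CSS, DSS, cfg = assoc_config(), k = 5L,
                   part_c = NULL, part_d = NULL, keep_models = FALSE) {
  split <- make_cv_folds(Y, k, seed = cfg$seed)
  metrics <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    Y_train <- mask_positives(Y, split, f)
    mask <- training_sample_mask(Y_train, split, f)
    model <- train_model(Y_train, CSS, DSS, mask, cfg,
                         part_c = part_c, part_d = part_d,
                         train_seed = cfg$seed + 1000L + f)
    held <- split$folds[[f]]
    sc <- model$scores[cbind(held$i, held$j)]
    metrics[[f]] <- dplyr::mutate(
      evaluate_scores(sc, held$label, cfg$threshold),
      fold = f, .before = 1L)
    if (keep_models) models[[f]] <- model
  }
  metrics <- dplyr::bind_rows(metrics)
  summary <- dplyr::summarise(metrics, dplyr::across(
    c("auc", "aupr", "f1", "accuracy", "recall", "precision", "specificity"),
    mean))
  structure(list(metrics = metrics, summary = summary, split = split,
                 config = cfg, models = models),
            class = "cdn_cv")
}

#' @export
print.cdn_cv <- function(x, ...) {
  cat("Cross-validation over", x$split$fold_count, "folds\n")
  print(x$summary)
  invisible(x)
}

#' Rank candidate circRNAs for one drug
#'
#' Sorts a drug's column of the prediction matrix in descending score order;
#' ties are broken lexicographically by circRNA id. Known training positives
#' can be excluded.
#'
#' @param scores Prediction matrix with dimnames.
#' @param drug_id Drug column to rank.
#' @param top_n Ranks returned (default 20; clipped with a warning).
#' @param exclude_known Optional training matrix whose positives are dropped
#'   from the ranking.
#' @return Tibble with `rank`, `circRNA`, `score`.
#' @export
rank_candidates <- function(scores, drug_id, top_n = 20L,
                            exclude_known = NULL) {
  if (!drug_id %in% colnames(scores)) stop("unknown drug id: ", drug_id)
  s <- scores[, drug_id]
  ids <- rownames(scores)
  if (!is.null(exclude_known)) {
    keep <- exclude_known[, drug_id] == 0
    s <- s[keep]
    ids <- ids[keep]
  }
  ord <- order(-s, ids)
  if (top_n > length(s)) {
    warning("top_n exceeds the number of candidates; returning all")
    top_n <- length(s)
  }
  sel <- ord[seq_len(top_n)]
  tibble::tibble(rank = seq_len(top_n), circRNA = ids[sel], score = s[sel])
}

#' Cold-start (ab initio) setup for one drug
#'
#' Zeroes the drug's entire column so it enters training as a new drug with
#' no known associations (its degree becomes 0, hence a tail node for any
#' nonnegative threshold).
#'
#' @param Y Binary association matrix.
#' @param drug_id Drug column to blank.
#' @return `Y` with that column zeroed.
#' @export
ab_initio <- function(Y, drug_id) {
  if (!drug_id %in% colnames(Y)) stop("unknown drug id: ", drug_id)
  Y[, drug_id] <- 0L
  Y
}
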