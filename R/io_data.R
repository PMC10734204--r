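# Reading/writing the external formats and building train/test material:
# the binary association matrix, masked training matrices, negative samples
# and cross-validation folds.

#' Read a labeled binary association matrix
#'
#' Reads a delimited table whose first column holds circRNA identifiers and
#' whose header row holds drug identifiers; every cell must be 0 or 1. The
#' delimiter is tab by default and a comma is auto-detected.
#'
#' @param path Path to a TSV/CSV file.
#' @return A binary integer matrix with circRNA row names and drug column
#'   names.
#' @export
read_association <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("association table is empty: ", path)
  sep <- if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("association table is empty or has no drug columns: ", path)
  }
  ids_c <- as.character(df[[1L]])
  ids_d <- colnames(df)[-1L]
  if (anyDuplicated(ids_c)) {
    stop("duplicate circRNA ids: ",
         paste(unique(ids_c[duplicated(ids_c)]), collapse = ", "))
  }
  if (anyDuplicated(ids_d)) {
    stop("duplicate drug ids: ",
         paste(unique(ids_d[duplicated(ids_d)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop("association matrix must contain only 0/1 values")
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids_c, ids_d)
  m
}

#' Write an association matrix as a labeled TSV
#'
#' @param Y Binary matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(Y, path) {
  stopifnot(!is.null(rownames(Y)), !is.null(colnames(Y)))
  df <- data.frame(id = rownames(Y), Y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load host-gene sequences for a set of circRNA ids
#'
#' FASTA headers are matched on their first whitespace-delimited token.
#' Duplicate headers keep the first record (with a warning); records not in
#' `ids` are ignored (with a warning). Missing ids are an error.
#'
#' @param path FASTA path.
#' @param ids Character vector of required entity ids.
#' @return Named character vector of sequences, in `ids` order.
#' @export
load_sequences <- function(path, ids) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(hdr)) {
    warning("duplicate FASTA headers; keeping first record of: ",
            paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
    keep <- !duplicated(hdr)
    ss <- ss[keep]
    hdr <- hdr[keep]
  }
  extra <- setdiff(hdr, ids)
  if (length(extra) > 0L) {
    warning("ignoring ", length(extra), " FASTA record(s) not in the index")
  }
  missing <- setdiff(ids, hdr)
  if (length(missing) > 0L) {
    stop("sequences missing for ids: ", paste(missing, collapse = ", "))
  }
  seqs <- as.character(ss)[match(ids, hdr)]
  if (any(!nzchar(seqs))) {
    stop("empty sequence for ids: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Load a drug SMILES table
#'
#' Two-column delimited file (id, SMILES), with or without a header line.
#'
#' @param path TSV/CSV path.
#' @return A tibble with columns `id` and `smiles`.
#' @export
load_smiles <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- any(tolower(fields) %in% c("id", "smiles", "drug"))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("SMILES table needs two columns (id, smiles)")
  out <- tibble::tibble(id = as.character(df[[1L]]),
                        smiles = as.character(df[[2L]]))
  if (anyDuplicated(out$id)) {
    stop("duplicate drug ids in SMILES table")
  }
  out
}

#' Load a user-supplied head/tail node partition
#'
#' Two-column delimited file (id, `head` or `tail`), overriding degree-based
#' typing.
#'
#' @param path TSV/CSV path.
#' @param ids Required ids (order of the returned vector).
#' @return Named character vector with values `"head"`/`"tail"`.
#' @export
load_partition <- function(path, ids) {
  first <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE)
  lab <- tolower(as.character(df[[2L]]))
  if (!all(lab %in% c("head", "tail"))) {
    stop("partition labels must be 'head' or 'tail'")
  }
  names(lab) <- as.character(df[[1L]])
  missing <- setdiff(ids, names(lab))
  if (length(missing) > 0L) {
    stop("partition missing for ids: ", paste(missing, collapse = ", "))
  }
  lab[ids]
}

#' Partition the known associations into cross-validation folds
#'
#' Positive pairs are randomly split into `k` near-equal folds; each fold is
#' paired with the same number of freshly sampled negative (zero) pairs,
#' drawn with a fold-derived seed (`seed + fold`).
#'
#' @param Y Binary association matrix.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and negatives.
#' @return An object of class `cdn_split`: a list with `fold_count`, `seed`
#'   and `folds`, where each fold is a tibble with columns `i`, `j`, `label`.
#' @export
make_cv_folds <- function(Y, k = 5L, seed = 1L) {
  if (k < 2L) stop("fold count must be at least 2")
  pos <- which(Y == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < k) stop("need at least k positive pairs")
  set.seed(seed)
  assign <- sample(rep_len(seq_len(k), n_pos))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    p <- pos[assign == f, , drop = FALSE]
    neg <- sample_negatives(Y, nrow(p), seed = seed + f)
    folds[[f]] <- tibble::tibble(
      i = unname(c(p[, 1L], neg[, 1L])),
      j = unname(c(p[, 2L], neg[, 2L])),
      label = rep(c(1L, 0L), c(nrow(p), nrow(neg)))
    )
  }
  structure(list(fold_count = k, seed = seed, folds = folds),
            class = "cdn_split")
}

#' Mask one fold's held-out positives out of the association matrix
#'
#' @param Y Binary association matrix.
#' @param split A `cdn_split` from [make_cv_folds()].
#' @param fold Fold id in `1..fold_count`.
#' @return `Y` with fold `fold`'s positive pairs set to 0.
#' @export
mask_positives <- function(Y, split, fold) {
  stopifnot(inherits(split, "cdn_split"))
  if (fold < 1L || fold > split$fold_count) stop("invalid fold id")
  f <- split$folds[[fold]]
  p <- f[f$label == 1L, , drop = FALSE]
  Y_train <- Y
  Y_train[cbind(p$i, p$j)] <- 0L
  Y_train
}

#' Sample negative (zero) pairs uniformly without replacement
#'
#' @param Y Binary association matrix.
#' @param n Number of pairs to draw.
#' @param seed Integer seed.
#' @return An `n` x 2 integer matrix of (row, column) indices.
#' @export
sample_negatives <- function(Y, n, seed = 1L) {
  zeros <- which(Y == 0)
  if (n > length(zeros)) {
    stop("requested ", n, " negatives but only ", length(zeros),
         " zero entries exist")
  }
  set.seed(seed)
  pick <- if (length(zeros) == 1L) zeros else sample(zeros, n)
  cbind(row = ((pick - 1L) %% nrow(Y)) + 1L,
        col = ((pick - 1L) %/% nrow(Y)) + 1L)
}

#' Serialize / deserialize a fold specification as JSON
#'
#' @param split A `cdn_split`.
#' @param path JSON output path.
#' @return `split_to_json()` returns `path` invisibly; `split_from_json()`
#'   returns a `cdn_split`.
#' @export
split_to_json <- function(split, path) {
  stopifnot(inherits(split, "cdn_split"))
  obj <- list(fold_count = split$fold_count, seed = split$seed,
              folds = lapply(split$folds, function(f) {
                list(i = f$i, j = f$j, label = f$label)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname split_to_json
#' @export
split_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- lapply(seq_len(obj$fold_count), function(f) {
    x <- obj$folds[[f]]
    tibble::tibble(i = as.integer(unlist(x$i)),
                   j = as.integer(unlist(x$j)),
                   label = as.integer(unlist(x$label)))
  })
  structure(list(fold_count = as.integer(obj$fold_count),
                 seed = as.integer(obj$seed), folds = folds),
            class = "cdn_split")
}

#' Detect isolated (zero-degree) nodes and optionally drop them
#'
#' Interaction-profile kernels of zero-degree nodes are uninformative; by
#' default they are kept with a warning, matching how unknown associations
#' are treated as negatives.
#'
#' @param Y Binary association matrix.
#' @param drop If `TRUE`, remove zero-degree rows/columns.
#' @return `Y`, possibly reduced.
#' @export
check_isolated <- function(Y, drop = FALSE) {
  zr <- rowSums(Y) == 0
  zc <- colSums(Y) == 0
  if (any(zr) || any(zc)) {
    msg <- paste0(sum(zr), " circRNA(s) and ", sum(zc),
                  " drug(s) have zero degree")
    if (drop) {
      warning(msg, "; dropping them")
      Y <- Y[!zr, !zc, drop = FALSE]
    } else {
      warning(msg, "; keeping them (their interaction-profile kernel rows ",
              "are uninformative)")
    }
  }
  Y
}
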