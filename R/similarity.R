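# Primary similarity matrices: host-gene sequence similarity (Levenshtein
# ratio), drug structural similarity (Tanimoto over topological
# fingerprints), and Gaussian interaction-profile (GIP) kernels computed on
# the training association matrix.

#' Levenshtein ratio between two strings
#'
#' Uses the indel-weighted convention: `1 - D(a, b) / (|a| + |b|)` where `D`
#' is the edit distance with insertion/deletion cost 1 and substitution cost
#' 2. Two empty strings are defined as identical (ratio 1).
#'
#' @param a,b Character scalars.
#' @return Similarity in `[0, 1]`.
#' @export
levenshtein_ratio <- function(a, b) {
  stopifnot(is.character(a), is.character(b), !is.na(a), !is.na(b))
  la <- nchar(a); lb <- nchar(b)
  if (la + lb == 0L) {
    message("both strings empty; ratio defined as 1")
    return(1)
  }
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1L, 1L]
  1 - d / (la + lb)
}

#' Pairwise sequence-similarity matrix (CSS)
#'
#' @param seqs Named character vector of sequences.
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
sequence_similarity <- function(seqs) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  d <- utils::adist(seqs, seqs, costs = list(ins = 1, del = 1, sub = 2))
  len <- nchar(seqs)
  denom <- outer(len, len, `+`)
  s <- ifelse(denom > 0, 1 - d / denom, 1)
  diag(s) <- 1
  dimnames(s) <- list(names(seqs), names(seqs))
  s
}

#' Topological fingerprints for a set of SMILES strings
#'
#' Converts SMILES to structures and computes fixed-length binary
#' topological (atom-pair-derived) fingerprints via ChemmineR/ChemmineOB.
#'
#' @param smiles Named character vector of SMILES (names are drug ids).
#' @param bits Fingerprint length (default 2048).
#' @return A logical matrix, one fingerprint per row.
#' @export
drug_fingerprints <- function(smiles, bits = 2048L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("drug_fingerprints() needs the ChemmineR and ChemmineOB packages")
  }
  stopifnot(!is.null(names(smiles)))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != length(smiles) ||
      !all(ChemmineR::validSDF(sdf))) {
    bad <- names(smiles)[vapply(smiles, function(s) {
      one <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
                      error = function(e) NULL)
      is.null(one) || length(one) == 0L || !all(ChemmineR::validSDF(one))
    }, logical(1L))]
    stop("unparsable SMILES for: ", paste(bad, collapse = ", "))
  }
  ap <- ChemmineR::sdf2ap(sdf)
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)   # common atom pairs
  descnames <- as.character(e$apfp$AP)[seq_len(min(bits, nrow(e$apfp)))]
  fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix")
  fp <- fp > 0
  rownames(fp) <- names(smiles)
  fp
}

#' Topological fingerprints from an SDF file
#'
#' SDF alternative to [drug_fingerprints()]: molecule titles (or `cid`s) are
#' used as drug ids.
#'
#' @param path SDF file path.
#' @param bits Fingerprint length (default 2048).
#' @return A logical matrix, one fingerprint per row.
#' @export
sdf_fingerprints <- function(path, bits = 2048L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("sdf_fingerprints() needs the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) stop("invalid molecule record(s) in ", path)
  ids <- ChemmineR::sdfid(sdf)
  ap <- ChemmineR::sdf2ap(sdf)
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  descnames <- as.character(e$apfp$AP)[seq_len(min(bits, nrow(e$apfp)))]
  fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix") > 0
  rownames(fp) <- ids
  fp
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `|A intersect B| / |A union B|`; two all-zero fingerprints are defined as
#' identical (similarity 1).
#'
#' @param fa,fb Logical/0-1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fa, fb) {
  if (length(fa) != length(fb)) stop("fingerprint lengths differ")
  fa <- as.logical(fa); fb <- as.logical(fb)
  un <- sum(fa | fb)
  if (un == 0L) {
    message("both fingerprints empty; similarity defined as 1")
    return(1)
  }
  sum(fa & fb) / un
}

#' Pairwise Tanimoto similarity matrix (DSS)
#'
#' @param fp Binary fingerprint matrix (one drug per row, rows named).
#' @return Symmetric matrix with unit diagonal.
#' @export
fingerprint_similarity <- function(fp) {
  fp <- (fp > 0) * 1
  inter <- tcrossprod(fp)
  ones <- rowSums(fp)
  un <- outer(ones, ones, `+`) - inter
  s <- ifelse(un > 0, inter / un, 1)
  diag(s) <- 1
  dimnames(s) <- list(rownames(fp), rownames(fp))
  s
}

#' GIP kernel bandwidth
#'
#' `gamma = alpha / mean(||profile||^2)` over the interaction profiles
#' (rows for circRNAs, columns for drugs) of the training matrix.
#'
#' @param Y_train Binary training association matrix.
#' @param axis `"rows"` (circRNA profiles) or `"cols"` (drug profiles).
#' @param alpha Scale factor (default 1).
#' @return The bandwidth `gamma`.
#' @export
gip_bandwidth <- function(Y_train, axis = c("rows", "cols"), alpha = 1) {
  axis <- match.arg(axis)
  stopifnot(alpha > 0)
  m <- if (axis == "rows") mean(rowSums(Y_train^2)) else mean(colSums(Y_train^2))
  if (m == 0) stop("all interaction profiles are zero; bandwidth undefined")
  alpha / m
}

#' Gaussian interaction-profile kernel (CGS or DGS)
#'
#' `K(i, j) = exp(-gamma * ||BI(i) - BI(j)||^2)` over the rows or columns of
#' the training association matrix.
#'
#' @param Y_train Binary training association matrix.
#' @param axis `"rows"` for the circRNA kernel, `"cols"` for the drug kernel.
#' @param gamma Bandwidth; defaults to [gip_bandwidth()] on the same matrix.
#' @param alpha Scale factor passed to [gip_bandwidth()] when `gamma` is NULL.
#' @return Symmetric kernel matrix with unit diagonal.
#' @export
gip_kernel <- function(Y_train, axis = c("rows", "cols"), gamma = NULL,
                       alpha = 1) {
  axis <- match.arg(axis)
  if (is.null(gamma)) gamma <- gip_bandwidth(Y_train, axis, alpha)
  P <- if (axis == "rows") Y_train else t(Y_train)
  P <- P * 1
  r <- rowSums(P^2)
  d2 <- outer(r, r, `+`) - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  diag(k) <- 1
  nm <- if (axis == "rows") rownames(Y_train) else colnames(Y_train)
  dimnames(k) <- list(nm, nm)
  k
}

# Gaussian kernel over the rows of a real-valued embedding matrix (plain,
# non-tape version; mirrors ad_gip_rows()).
embedding_gip <- function(H, gamma) {
  r <- rowSums(H^2)
  d2 <- outer(r, r, `+`) - 2 * tcrossprod(H)
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  diag(k) <- 1
  k
}

#' Read / write a labeled square similarity matrix as TSV
#'
#' @param path TSV path.
#' @return `read_similarity()` returns the matrix; `write_similarity()`
#'   returns `path` invisibly.
#' @export
read_similarity <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  m
}

#' @rdname read_similarity
#' @param S Square matrix with dimnames.
#' @export
write_similarity <- function(S, path) {
  df <- data.frame(id = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
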