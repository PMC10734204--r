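# Head/tail typing of nodes by degree and construction of the bi-typed
# multi-relational heterogeneous graph: 3 intra-type relations per side
# (head-head, head-tail, tail-tail over the similarity networks) and 4
# inter-type relations (head/tail circRNA x head/tail drug over the
# training associations).

#' Classify nodes into head and tail by degree
#'
#' A node is a tail node iff its degree does not exceed the threshold `K`;
#' otherwise it is a head node.
#'
#' @param degrees Nonnegative integer vector of node degrees.
#' @param K Degree threshold.
#' @return Character vector of `"head"`/`"tail"`, named like `degrees`.
#' @export
classify_head_tail <- function(degrees, K) {
  stopifnot(all(degrees >= 0))
  lab <- ifelse(degrees <= K, "tail", "head")
  names(lab) <- names(degrees)
  lab
}

# Resolve a threshold spec: a number, or "median" of the observed degrees.
resolve_threshold <- function(K, degrees) {
  if (is.null(K) || identical(K, "median")) {
    return(stats::median(degrees))
  }
  K
}

#' Build the typed inter-type edge masks from the training matrix
#'
#' Every training association is assigned exactly one of four relations by
#' the head/tail labels of its endpoints (circRNA side first):
#' head-head = 1, head-tail = 2, tail-head = 3, tail-tail = 4.
#'
#' @param Y_train Binary training association matrix.
#' @param part_c,part_d Head/tail labels for circRNAs and drugs.
#' @return Named list of four 0/1 masks of dim `dim(Y_train)` (relations with
#'   no edges are kept as all-zero masks).
#' @export
build_inter_edges <- function(Y_train, part_c, part_d) {
  stopifnot(length(part_c) == nrow(Y_train), length(part_d) == ncol(Y_train))
  hc <- part_c == "head"
  hd <- part_d == "head"
  Y <- (Y_train > 0) * 1
  list(
    r1 = Y * outer(hc, hd, `&`),
    r2 = Y * outer(hc, !hd, `&`),
    r3 = Y * outer(!hc, hd, `&`),
    r4 = Y * outer(!hc, !hd, `&`)
  )
}

#' Build the typed intra-type edge masks from a similarity matrix
#'
#' Each node keeps its `sparsify_k` most similar neighbors (self excluded);
#' the union over both directions gives an undirected edge set, typed by the
#' endpoint labels: head-head = 1, mixed head-tail = 2 (either orientation),
#' tail-tail = 3.
#'
#' @param S Symmetric similarity matrix.
#' @param part Head/tail labels for the nodes of this type.
#' @param sparsify_k Neighbors kept per node; `>= N` keeps all off-diagonal
#'   pairs.
#' @return Named list of three symmetric 0/1 masks.
#' @export
build_intra_edges <- function(S, part, sparsify_k = 10L) {
  n <- nrow(S)
  stopifnot(length(part) == n)
  adj <- matrix(0, n, n)
  if (sparsify_k >= n) {
    adj[] <- 1
  } else {
    for (i in seq_len(n)) {
      ord <- order(S[i, -i], decreasing = TRUE)
      others <- seq_len(n)[-i]
      adj[i, others[ord[seq_len(sparsify_k)]]] <- 1
    }
    adj <- pmax(adj, t(adj))   # undirected
  }
  diag(adj) <- 0
  h <- part == "head"
  list(
    r1 = adj * outer(h, h, `&`),
    r2 = adj * (outer(h, !h, `&`) | outer(!h, h, `&`)),
    r3 = adj * outer(!h, !h, `&`)
  )
}

#' Assemble the bi-typed multi-relational heterogeneous graph
#'
#' Degrees are computed from the masked training matrix (so head/tail labels
#' never leak held-out positives); user-supplied partitions override the
#' degree rule.
#'
#' @param Y_train Binary training association matrix.
#' @param S_c,S_d Fused similarity matrices for circRNAs and drugs.
#' @param K_c,K_d Degree thresholds; a number, or `"median"` (default) for
#'   the median training degree of that side.
#' @param sparsify_k Intra-edge neighborhood size (default 10).
#' @param part_c,part_d Optional externally supplied head/tail labels.
#' @return A list of class `cdn_graph` with partitions, thresholds and the
#'   typed intra/inter edge masks.
#' @export
build_hetero_graph <- function(Y_train, S_c, S_d, K_c = "median",
                               K_d = "median", sparsify_k = 10L,
                               part_c = NULL, part_d = NULL) {
  deg_c <- rowSums(Y_train)
  deg_d <- colSums(Y_train)
  if (is.null(part_c)) {
    K_c <- resolve_threshold(K_c, deg_c)
    part_c <- classify_head_tail(deg_c, K_c)
  } else {
    K_c <- NA
  }
  if (is.null(part_d)) {
    K_d <- resolve_threshold(K_d, deg_d)
    part_d <- classify_head_tail(deg_d, K_d)
  } else {
    K_d <- NA
  }
  structure(list(
    part_c = part_c, part_d = part_d, K_c = K_c, K_d = K_d,
    intra_c = build_intra_edges(S_c, part_c, sparsify_k),
    intra_d = build_intra_edges(S_d, part_d, sparsify_k),
    inter = build_inter_edges(Y_train, part_c, part_d)
  ), class = "cdn_graph")
}

#' Collapse all relations to a single type (relation-ablation mode)
#'
#' @param graph A `cdn_graph`.
#' @return The graph with one intra relation per side (union of the three)
#'   and one inter relation (all training edges).
#' @export
collapse_relations <- function(graph) {
  stopifnot(inherits(graph, "cdn_graph"))
  graph$intra_c <- list(r1 = pmin(Reduce(`+`, graph$intra_c), 1))
  graph$intra_d <- list(r1 = pmin(Reduce(`+`, graph$intra_d), 1))
  graph$inter <- list(r1 = pmin(Reduce(`+`, graph$inter), 1))
  graph
}

#' Export typed edge lists as a tibble
#'
#' @param graph A `cdn_graph`.
#' @return Tibble with columns `side` (`intra_c`/`intra_d`/`inter`),
#'   `relation`, `src`, `dst`.
#' @export
edge_table <- function(graph) {
  stopifnot(inherits(graph, "cdn_graph"))
  one <- function(masks, side) {
    purrr::imap_dfr(masks, function(m, nm) {
      e <- which(m > 0, arr.ind = TRUE)
      tibble::tibble(side = side, relation = as.integer(sub("^r", "", nm)),
                     src = e[, 1L], dst = e[, 2L])
    })
  }
  dplyr::bind_rows(one(graph$intra_c, "intra_c"),
                   one(graph$intra_d, "intra_d"),
                   one(graph$inter, "inter"))
}
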