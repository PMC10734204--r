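# Self-contained synthetic study generator: a planted-block bipartite
# association matrix with matching host-gene sequences and drug
# fingerprints, so the whole pipeline is testable without downloads.
# Entities in the same planted block associate more often (p_in > p_out),
# their sequences descend from a common block ancestor (mut_in per-base
# mutations) while ancestors differ strongly (mut_out from a shared root),
# and likewise for fingerprint bits.

#' Specification of a synthetic planted-block study
#'
#' @param n_circ,n_drug Entity counts (default 60 x 40).
#' @param n_blocks Planted co-modules (default 3).
#' @param p_in,p_out Association probabilities within / outside a block
#'   (defaults 0.5 / 0.05).
#' @param seq_len Host-gene sequence length (default 200).
#' @param mut_in Per-base mutation rate from the block ancestor
#'   (default 0.05).
#' @param mut_out Per-base mutation rate of block ancestors from the shared
#'   root (default 0.4).
#' @param fp_bits Fingerprint length (default 256).
#' @param seed Seed; the fixture is fully reproducible from (spec, seed).
#' @return A list of class `cdn_synth_spec`.
#' @export
synthetic_spec <- function(n_circ = 60L, n_drug = 40L, n_blocks = 3L,
                           p_in = 0.5, p_out = 0.05, seq_len = 200L,
                           mut_in = 0.05, mut_out = 0.4, fp_bits = 256L,
                           seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1, mut_in < mut_out,
            n_blocks >= 1L, n_circ >= n_blocks, n_drug >= n_blocks)
  structure(as.list(environment()), class = "cdn_synth_spec")
}

mutate_seq <- function(x, rate) {
  bases <- c("A", "C", "G", "T")
  hit <- stats::runif(length(x)) < rate
  if (any(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1L),
                     character(1L))
  }
  x
}

flip_bits <- function(x, rate) {
  hit <- stats::runif(length(x)) < rate
  xor(x, hit)
}

#' Generate a synthetic planted-block study
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `cdn_synth` with the association matrix `Y`,
#'   `sequences` (named character), `fingerprints` (logical matrix), the
#'   ground-truth block labels `blocks_c`, `blocks_d`, and `spec`.
#' @export
simulate_study <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "cdn_synth_spec"))
  set.seed(spec$seed)
  ids_c <- sprintf("circ_%03d", seq_len(spec$n_circ))
  ids_d <- sprintf("drug_%03d", seq_len(spec$n_drug))
  blocks_c <- sample(rep_len(seq_len(spec$n_blocks), spec$n_circ))
  blocks_d <- sample(rep_len(seq_len(spec$n_blocks), spec$n_drug))
  if (length(unique(blocks_c)) < spec$n_blocks ||
      length(unique(blocks_d)) < spec$n_blocks) {
    warning("empty block after assignment; resampling")
    blocks_c <- sample(rep_len(seq_len(spec$n_blocks), spec$n_circ))
    blocks_d <- sample(rep_len(seq_len(spec$n_blocks), spec$n_drug))
  }
  same <- outer(blocks_c, blocks_d, `==`)
  p <- ifelse(same, spec$p_in, spec$p_out)
  Y <- matrix(stats::rbinom(length(p), 1L, p), spec$n_circ, spec$n_drug,
              dimnames = list(ids_c, ids_d))

  bases <- c("A", "C", "G", "T")
  root <- sample(bases, spec$seq_len, replace = TRUE)
  anc_seq <- lapply(seq_len(spec$n_blocks),
                    function(b) mutate_seq(root, spec$mut_out))
  sequences <- vapply(seq_len(spec$n_circ), function(i) {
    paste(mutate_seq(anc_seq[[blocks_c[i]]], spec$mut_in), collapse = "")
  }, character(1L))
  names(sequences) <- ids_c

  root_fp <- stats::rbinom(spec$fp_bits, 1L, 0.3) == 1L
  anc_fp <- lapply(seq_len(spec$n_blocks),
                   function(b) flip_bits(root_fp, spec$mut_out))
  fingerprints <- t(vapply(seq_len(spec$n_drug), function(j) {
    flip_bits(anc_fp[[blocks_d[j]]], spec$mut_in)
  }, logical(spec$fp_bits)))
  rownames(fingerprints) <- ids_d

  structure(list(Y = Y, sequences = sequences, fingerprints = fingerprints,
                 blocks_c = blocks_c, blocks_d = blocks_d, spec = spec),
            class = "cdn_synth")
}

#' Similarity matrices of a synthetic study
#'
#' Convenience wrapper: sequence similarity for the circRNA side, Tanimoto
#' over the generated fingerprints for the drug side.
#'
#' @param study A `cdn_synth`.
#' @return List with `CSS` and `DSS`.
#' @export
study_similarities <- function(study) {
  stopifnot(inherits(study, "cdn_synth"))
  list(CSS = sequence_similarity(study$sequences),
       DSS = fingerprint_similarity(study$fingerprints))
}

#' Write a synthetic study in the formats the readers consume
#'
#' Emits `association.tsv`, `sequences.fasta`, `fingerprints.tsv` and
#' `blocks.tsv` under `dir`.
#'
#' @param study A `cdn_synth`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cdn_synth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_association(study$Y, file.path(dir, "association.tsv"))
  ss <- Biostrings::DNAStringSet(study$sequences)
  Biostrings::writeXStringSet(ss, file.path(dir, "sequences.fasta"))
  fp <- data.frame(id = rownames(study$fingerprints),
                   study$fingerprints * 1L, check.names = FALSE)
  utils::write.table(fp, file.path(dir, "fingerprints.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bl <- data.frame(id = c(rownames(study$Y), colnames(study$Y)),
                   side = rep(c("circRNA", "drug"),
                              c(nrow(study$Y), ncol(study$Y))),
                   block = c(study$blocks_c, study$blocks_d))
  utils::write.table(bl, file.path(dir, "blocks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Degree histogram of an association matrix
#'
#' Useful for choosing a head/tail threshold (e.g., the median degree).
#'
#' @param Y Binary association matrix.
#' @return Tibble with `side` (`circRNA`/`drug`), `degree`, `n`.
#' @export
degree_profile <- function(Y) {
  dc <- table(rowSums(Y))
  dd <- table(colSums(Y))
  dplyr::bind_rows(
    tibble::tibble(side = "circRNA", degree = as.integer(names(dc)),
                   n = as.integer(dc)),
    tibble::tibble(side = "drug", degree = as.integer(names(dd)),
                   n = as.integer(dd))
  )
}
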