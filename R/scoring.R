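get_row_labels <- function(matrix) {
  if (inherits(matrix, "ebc_matrix")) return(rownames(matrix$M))
  rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
}

resolve_rows <- function(labels, wanted, what) {
  idx <- match(wanted, labels)
  if (anyNA(idx)) {
    stop_ebclust(sprintf("%s not found among matrix rows: %s", what,
                         paste(head(wanted[is.na(idx)], 3), collapse = ", ")),
                 "ebclust_unknown_label")
  }
  idx
}

check_seed_set <- function(S, candidate = NULL) {
  if (length(S) == 0) {
    stop_ebclust("The seed set S must be non-empty.", "ebclust_empty_seed_set")
  }
  if (!is.null(candidate) && candidate %in% S) {
    stop_ebclust("The scored candidate must not be a member of the seed set.",
                 "ebclust_bad_argument")
  }
  invisible(TRUE)
}

# Rank values so that the largest gets rank n ("most similar = highest rank"),
# ties broken by a seeded random permutation.
rank_high <- function(values, tie_seed) {
  with_preserved_seed(tie_seed, rank(values, ties.method = "random"))
}

#' EBC rank-sum score of a candidate against a seed set
#'
#' All `n` rows are ranked by how often they co-cluster with the candidate
#' `T_i` (rank `n` = most frequent co-clusterer; ties broken by a seeded
#' random permutation). The score is the sum of the seed members' ranks:
#' `score(T_i) = sum_j j * I(R_ij in S)`. The candidate participates in its
#' own ranking (it takes the top rank via `C[T_i, T_i] = N`) but contributes
#' nothing because it cannot be in `S`. Using ranks rather than raw counts
#' makes the score invariant to each row's baseline co-clustering
#' "promiscuity".
#'
#' @param cocluster An `ebc_cocluster` from [run_ensemble()].
#' @param S Character vector of seed row labels (non-empty, not containing the
#'   candidate).
#' @param candidate Row label of the test candidate `T_i`.
#' @param tie_seed Seed for random tie-breaking.
#' @return Numeric rank-sum score.
#' @export
ebc_score <- function(cocluster, S, candidate, tie_seed = 1L) {
  stopifnot(inherits(cocluster, "ebc_cocluster"))
  check_seed_set(S, candidate)
  labels <- cocluster$labels
  ti <- resolve_rows(labels, candidate, "Candidate")
  si <- resolve_rows(labels, S, "Seed set members")
  r <- rank_high(cocluster$counts[, ti], tie_seed)
  sum(r[si])
}

row_vectors <- function(matrix) {
  M <- as_dense(matrix)
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) {
    stop_ebclust("Matrix contains all-zero rows; cosine similarity is undefined.",
                 "ebclust_bad_matrix")
  }
  list(M = M, norm = nrm)
}

#' Average-cosine baseline score
#'
#' The mean cosine similarity between the candidate's raw row vector and each
#' seed member's row vector. Unlike EBC this cannot relate rows with disjoint
#' dependency-path supports: their cosine is exactly zero.
#'
#' @inheritParams ebc_score
#' @param matrix An [ebc_matrix()] or plain binary matrix.
#' @return Mean cosine similarity (in `[0, 1]` for non-negative data).
#' @export
avg_cosine_score <- function(matrix, S, candidate) {
  check_seed_set(S, candidate)
  rv <- row_vectors(matrix)
  labels <- get_row_labels(matrix)
  ti <- resolve_rows(labels, candidate, "Candidate")
  si <- resolve_rows(labels, S, "Seed set members")
  sims <- as.vector(rv$M[si, , drop = FALSE] %*% rv$M[ti, ]) /
    (rv$norm[si] * rv$norm[ti])
  mean(sims)
}

#' Rank-sum-cosine baseline score
#'
#' Identical to [ebc_score()] except that the ranking of all `n` rows is by
#' cosine similarity to the candidate's row vector instead of co-clustering
#' frequency.
#'
#' @inheritParams avg_cosine_score
#' @param tie_seed Seed for random tie-breaking.
#' @export
ranksum_cosine_score <- function(matrix, S, candidate, tie_seed = 1L) {
  check_seed_set(S, candidate)
  rv <- row_vectors(matrix)
  labels <- get_row_labels(matrix)
  ti <- resolve_rows(labels, candidate, "Candidate")
  si <- resolve_rows(labels, S, "Seed set members")
  sims <- as.vector(rv$M %*% rv$M[ti, ]) / (rv$norm * rv$norm[ti])
  r <- rank_high(sims, tie_seed)
  sum(r[si])
}

#' Latent-semantic-analysis row embeddings
#'
#' Rank-`r` truncated singular value decomposition of the binary matrix; each
#' row is represented by its first `r` left-singular coordinates scaled by the
#' singular values, so embedded dot products reproduce the rank-`r`
#' approximation's Gram matrix. At full rank the embeddings reproduce all
#' pairwise cosines of the original rows.
#'
#' @param matrix An [ebc_matrix()] or plain binary matrix.
#' @param rank Embedding rank `1 <= r <= min(n, m)`.
#' @return Numeric `n x r` matrix of embedded row vectors (row labels kept).
#' @export
lsa_embed <- function(matrix, rank) {
  M <- as_dense(matrix)
  r <- check_scalar_count(rank, "rank")
  if (r > min(dim(M))) {
    stop_ebclust(sprintf("rank must be <= min(n, m) = %d.", min(dim(M))),
                 "ebclust_bad_argument")
  }
  sv <- svd(M, nu = r, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(r)], r, r)
  rownames(emb) <- get_row_labels(matrix)
  emb
}

#' Score all candidates against a seed set
#'
#' Applies one of the scoring functions to every matrix row outside the seed
#' set and normalises the scores to a relative certainty. Methods:
#' `"ebc"` (rank sum on co-clustering counts; needs `cocluster`),
#' `"avgcos"` (mean cosine of raw row vectors), `"ranksum"` (rank sum on
#' cosine similarity), `"lsa_avgcos"` / `"lsa_ranksum"` (the cosine methods on
#' rank-`lsa_rank` LSA embeddings).
#'
#' @param matrix An [ebc_matrix()] or plain binary matrix.
#' @param S Character vector of seed row labels.
#' @param method Scoring method (see Details).
#' @param cocluster An `ebc_cocluster`; required for `method = "ebc"`.
#' @param candidates Candidate row labels; defaults to all non-seed rows.
#' @param lsa_rank Embedding rank for the LSA methods.
#' @param tie_seed Seed for rank tie-breaking.
#' @return A tibble with columns `candidate`, `score`, `relative_certainty`,
#'   `method`, sorted by decreasing score.
#' @export
score_candidates <- function(matrix, S,
                             method = c("ebc", "avgcos", "ranksum",
                                        "lsa_avgcos", "lsa_ranksum"),
                             cocluster = NULL, candidates = NULL,
                             lsa_rank = NULL, tie_seed = 1L) {
  method <- match.arg(method)
  check_seed_set(S)
  labels <- get_row_labels(matrix)
  resolve_rows(labels, S, "Seed set members")
  if (is.null(candidates)) candidates <- setdiff(labels, S)
  if (any(candidates %in% S)) {
    stop_ebclust("Candidates must be disjoint from the seed set.",
                 "ebclust_bad_argument")
  }
  scored_matrix <- matrix
  if (startsWith(method, "lsa_")) {
    if (is.null(lsa_rank)) {
      stop_ebclust("lsa_rank is required for the LSA methods.",
                   "ebclust_bad_argument")
    }
    scored_matrix <- lsa_embed(matrix, lsa_rank)
  }
  scores <- switch(
    method,
    ebc = {
      if (is.null(cocluster)) {
        stop_ebclust("method = \"ebc\" needs a cocluster object.",
                     "ebclust_bad_argument")
      }
      vapply(seq_along(candidates), function(i) {
        ebc_score(cocluster, S, candidates[i],
                  tie_seed = derive_seed(tie_seed, i))
      }, 0)
    },
    avgcos = ,
    lsa_avgcos = vapply(candidates, function(ti) {
      avg_cosine_score(scored_matrix, S, ti)
    }, 0),
    ranksum = ,
    lsa_ranksum = vapply(seq_along(candidates), function(i) {
      ranksum_cosine_score(scored_matrix, S, candidates[i],
                           tie_seed = derive_seed(tie_seed, i))
    }, 0)
  )
  scores <- unname(scores)
  tibble(
    candidate = candidates,
    score = scores,
    relative_certainty = relative_certainty(scores),
    method = method
  ) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

#' Min-max normalised relative certainty
#'
#' `(score - min) / (max - min)`, so the top-scoring candidate always gets
#' 1.000; when all scores are equal every candidate gets 1 by convention.
#'
#' @param scores Numeric vector (length >= 1).
#' @return Numeric vector in `[0, 1]`.
#' @export
relative_certainty <- function(scores) {
  if (length(scores) == 0) {
    stop_ebclust("At least one score is required.", "ebclust_bad_argument")
  }
  rng <- range(scores)
  if (rng[1] == rng[2]) return(rep(1, length(scores)))
  (scores - rng[1]) / (rng[2] - rng[1])
}
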