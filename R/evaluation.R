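#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a randomly chosen positive is scored higher than a
#' randomly chosen negative, with ties credited 0.5 — computed exactly from
#' midranks.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop_ebclust("scores and labels must have equal length.", "ebclust_bad_argument")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_ebclust("Both classes must be present to compute an AUC.",
                 "ebclust_single_class")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sample a seed set and a disjoint labelled test set
#'
#' Draws `seed_size` positives as the seed set `S`, then a test set of
#' `n_test_pos` further positives (disjoint from `S`) and `n_test_neg`
#' negatives, all without replacement. The standard benchmark uses 100-item
#' test sets with a 50/50 composition.
#'
#' @param positives,negatives Character vectors of row labels.
#' @param seed_size Number of seed positives.
#' @param n_test_pos,n_test_neg Test-set composition.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A list with `S` (character) and `test` (tibble with `label`,
#'   `positive`).
#' @export
sample_seed_test <- function(positives, negatives, seed_size,
                             n_test_pos = 50L, n_test_neg = 50L, seed = NULL) {
  seed_size <- check_scalar_count(seed_size, "seed_size")
  if (length(positives) < seed_size + n_test_pos) {
    stop_ebclust(sprintf(
      "Need at least %d positives (seed %d + test %d); have %d.",
      seed_size + n_test_pos, seed_size, n_test_pos, length(positives)),
      "ebclust_capacity_error")
  }
  if (length(negatives) < n_test_neg) {
    stop_ebclust(sprintf("Need at least %d negatives; have %d.",
                         n_test_neg, length(negatives)),
                 "ebclust_capacity_error")
  }
  draw <- function() {
    S <- sample(positives, seed_size)
    test_pos <- sample(setdiff(positives, S), n_test_pos)
    test_neg <- sample(negatives, n_test_neg)
    list(S = S, test = tibble(
      label = c(test_pos, test_neg),
      positive = rep(c(TRUE, FALSE), c(n_test_pos, n_test_neg))
    ))
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

#' Benchmark seeded rankings by the fraction of accurate test sets
#'
#' Reproduces the seeded-ranking evaluation protocol: for each scoring method
#' and each seed-set size, draw `replicates` random seed/test splits, score
#' the test set with its seed set, compute the AUC, and report the fraction of
#' replicates with AUC strictly above `threshold`. Replicate draws are paired
#' across methods (the same seed and test sets are scored by every method),
#' with per-replicate seeds derived deterministically from `seed`.
#'
#' @param matrix An [ebc_matrix()] or plain binary matrix.
#' @param cocluster An `ebc_cocluster`; required when `"ebc"` is among the
#'   methods.
#' @param positives,negatives Character vectors of row labels.
#' @param sizes Integer vector of seed-set sizes (published protocol:
#'   1, 2, 3, 4, 5, 10, 25, 50, 100).
#' @param replicates Replicates per size (published protocol: 1000).
#' @param methods Built-in method names (see [score_candidates()]) and/or a
#'   named list mixing built-in names with custom scorer functions
#'   `function(matrix, cocluster, S, candidates, tie_seed) -> numeric`.
#' @param n_test_pos,n_test_neg Test-set composition (published protocol:
#'   50/50).
#' @param threshold AUC threshold (strict inequality).
#' @param seed Master seed.
#' @param lsa_rank Rank for LSA methods, if used.
#' @return A tibble of class `ebc_benchmark` with columns `method`,
#'   `seed_size`, `replicates`, `fraction_auc_above`, `median_auc`.
#' @export
benchmark <- function(matrix, cocluster = NULL, positives, negatives,
                      sizes = c(1, 2, 3, 4, 5, 10, 25, 50, 100),
                      replicates = 100L,
                      methods = c("ebc", "avgcos", "ranksum"),
                      n_test_pos = 50L, n_test_neg = 50L,
                      threshold = 0.7, seed = 1L, lsa_rank = NULL) {
  if (!is.list(methods)) {
    methods <- setNames(as.list(methods), methods)
  } else if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    stop_ebclust("A list of methods must be fully named.", "ebclust_bad_argument")
  }
  replicates <- check_scalar_count(replicates, "replicates")
  aucs <- array(
    NA_real_, dim = c(length(methods), length(sizes), replicates),
    dimnames = list(names(methods), as.character(sizes), NULL)
  )
  for (si in seq_along(sizes)) {
    for (rep_i in seq_len(replicates)) {
      split <- sample_seed_test(
        positives, negatives, sizes[si],
        n_test_pos = n_test_pos, n_test_neg = n_test_neg,
        seed = derive_seed(seed, si, rep_i)
      )
      for (mi in seq_along(methods)) {
        m <- methods[[mi]]
        tie_seed <- derive_seed(seed, si, rep_i, mi)
        scores <- if (is.function(m)) {
          m(matrix, cocluster, split$S, split$test$label, tie_seed)
        } else {
          score_candidates(matrix, split$S, method = m, cocluster = cocluster,
                           candidates = split$test$label, lsa_rank = lsa_rank,
                           tie_seed = tie_seed) |>
            (\(tab) tab$score[match(split$test$label, tab$candidate)])()
        }
        aucs[mi, si, rep_i] <- auc(scores, split$test$positive)
      }
    }
  }
  out <- tidyr::expand_grid(method = names(methods),
                            seed_size = as.integer(sizes)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      replicates = replicates,
      fraction_auc_above =
        mean(aucs[.data$method, as.character(.data$seed_size), ] > threshold),
      median_auc =
        median(aucs[.data$method, as.character(.data$seed_size), ])
    ) |>
    dplyr::ungroup()
  attr(out, "threshold") <- threshold
  attr(out, "auc") <- aucs
  class(out) <- c("ebc_benchmark", class(out))
  out
}

#' Seed-set bookkeeping from labelled-pair counts
#'
#' Given the total number of entity pairs in a matrix and the sizes of two
#' known-relationship seed sets plus their intersection, returns the number of
#' pairs known to neither set and the percentage overlap of the two seed sets
#' (intersection over union).
#'
#' @param n_pairs Total rows in the matrix.
#' @param n_a,n_b Sizes of the two labelled sets.
#' @param n_both Size of their intersection.
#' @return A one-row tibble with `known_neither` and `overlap_pct` (one
#'   decimal).
#' @export
seed_overlap <- function(n_pairs, n_a, n_b, n_both) {
  if (n_both > min(n_a, n_b) || n_a + n_b - n_both > n_pairs) {
    stop_ebclust("Inconsistent label counts.", "ebclust_bad_argument")
  }
  tibble(
    known_neither = n_pairs - n_a - n_b + n_both,
    overlap_pct = round(100 * n_both / (n_a + n_b - n_both), 1)
  )
}
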