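#' Cross-surface-form recovery benchmark on the synonymy scenario
#'
#' The package's central qualitative check: can each method, given seeds from
#' split A of the synonymy scenario (see [synonymy_scenario()]), rank the
#' split-B positives above the negatives — even though every seed shares *no*
#' dependency path with any split-B row? Each replicate generates a fresh
#' scenario, runs an ITCC ensemble, draws a seed set from split A, scores the
#' candidates (all split-B rows plus all negatives) with the EBC rank-sum and
#' the two cosine baselines, and records one AUC per method.
#'
#' Average cosine is analytically blind here: all candidate-to-seed cosines
#' are exactly zero, so its AUC hovers at 0.5. EBC succeeds through the
#' ensemble's corpus-level bridging evidence.
#'
#' @param replicates Number of independent replicates.
#' @param seed_size Seeds drawn from split A per replicate.
#' @param N Ensemble size per replicate.
#' @param k,l ITCC cluster numbers.
#' @param seed Master seed.
#' @param ... Passed on to [synonymy_scenario()].
#' @return A tibble with columns `replicate`, `method`
#'   (`"ebc"`, `"avgcos"`, `"ranksum"`), `auc`.
#' @export
synonymy_benchmark <- function(replicates = 25L, seed_size = 10L, N = 200L,
                               k = 3L, l = 3L, seed = 1L, ...) {
  replicates <- check_scalar_count(replicates, "replicates")
  res <- purrr::map(seq_len(replicates), function(rep_i) {
    sc <- synonymy_scenario(seed = derive_seed(seed, rep_i, 1), ...)
    cc <- run_ensemble(sc$matrix, k, l, N = N,
                       base_seed = derive_seed(seed, rep_i, 2))
    a_rows <- sc$splits$label[sc$splits$split == "A"]
    b_rows <- sc$splits$label[sc$splits$split == "B"]
    S <- with_preserved_seed(derive_seed(seed, rep_i, 3),
                             sample(a_rows, seed_size))
    candidates <- c(b_rows, sc$negatives)
    truth <- candidates %in% b_rows
    per_method <- function(method) {
      tab <- score_candidates(sc$matrix, S, method = method, cocluster = cc,
                              candidates = candidates,
                              tie_seed = derive_seed(seed, rep_i, 4))
      auc(tab$score[match(candidates, tab$candidate)], truth)
    }
    tibble(
      replicate = rep_i,
      method = c("ebc", "avgcos", "ranksum"),
      auc = c(per_method("ebc"), per_method("avgcos"), per_method("ranksum"))
    )
  })
  dplyr::bind_rows(res)
}

#' Summarise a synonymy benchmark
#'
#' Median AUC and fraction of replicates with AUC above the threshold, per
#' method.
#'
#' @param results Tibble from [synonymy_benchmark()].
#' @param threshold AUC threshold (strict).
#' @return A tibble with `method`, `median_auc`, `fraction_auc_above`.
#' @export
summarize_synonymy <- function(results, threshold = 0.7) {
  results |>
    dplyr::summarise(
      median_auc = median(.data$auc),
      fraction_auc_above = mean(.data$auc > threshold),
      .by = "method"
    )
}
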