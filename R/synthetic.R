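#' Specification of a planted block structure
#'
#' Describes a binary matrix with planted row-block x column-block Bernoulli
#' structure: cell `(y, x)` is 1 with probability `p_in` when row `y`'s block
#' is associated with column `x`'s block, and with probability `p_out`
#' otherwise.
#'
#' @param row_sizes Positive integer vector of row-block sizes.
#' @param col_sizes Positive integer vector of column-block sizes.
#' @param association Logical (or 0/1) matrix, `length(row_sizes)` x
#'   `length(col_sizes)`; defaults to the identity map when square.
#' @param p_in,p_out Within-association / background probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed Integer generation seed.
#' @return A validated list of class `ebc_planted_spec`.
#' @export
planted_spec <- function(row_sizes, col_sizes, association = NULL,
                         p_in = 0.8, p_out = 0.05, seed = 1L) {
  if (any(row_sizes < 1) || any(col_sizes < 1)) {
    stop_ebclust("Block sizes must be positive.", "ebclust_bad_spec")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop_ebclust("Need 0 <= p_out < p_in <= 1.", "ebclust_bad_spec")
  }
  if (is.null(association)) {
    if (length(row_sizes) != length(col_sizes)) {
      stop_ebclust("association defaults to identity only for equal block counts.",
                   "ebclust_bad_spec")
    }
    association <- diag(length(row_sizes)) > 0
  }
  association <- matrix(as.logical(association),
                        length(row_sizes), length(col_sizes))
  structure(list(row_sizes = as.integer(row_sizes),
                 col_sizes = as.integer(col_sizes),
                 association = association,
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "ebc_planted_spec")
}

#' Generate a binary matrix with planted bicluster structure
#'
#' Samples the matrix described by a [planted_spec()]. Rows or columns that
#' come out all-zero are resampled once; any still empty after that are
#' dropped (together with their truth labels), keeping dimensions close to the
#' specification without rejection loops. Generation is deterministic given
#' the spec's seed.
#'
#' @param spec An `ebc_planted_spec`.
#' @return A list with `matrix` (an [ebc_matrix()] whose synthetic "drugs" are
#'   the row names `r1, r2, ...` and "paths" `c1, c2, ...`), `row_blocks` and
#'   `col_blocks` (named integer vectors of true block memberships).
#' @export
planted_matrix <- function(spec) {
  stopifnot(inherits(spec, "ebc_planted_spec"))
  rb <- rep(seq_along(spec$row_sizes), spec$row_sizes)
  cb <- rep(seq_along(spec$col_sizes), spec$col_sizes)
  n <- length(rb); m <- length(cb)
  prob <- ifelse(spec$association[cbind(rep(rb, m), rep(cb, each = n))],
                 spec$p_in, spec$p_out)
  M <- with_preserved_seed(spec$seed, {
    M <- matrix(rbinom(n * m, 1, prob), n, m)
    for (pass in 1:1) {   # resample-once policy
      er <- which(rowSums(M) == 0)
      for (y in er) M[y, ] <- rbinom(m, 1, prob[(seq_len(m) - 1) * n + y])
      ec <- which(colSums(M) == 0)
      for (x in ec) M[, x] <- rbinom(n, 1, prob[(x - 1) * n + seq_len(n)])
    }
    M
  })
  keep_r <- rowSums(M) > 0
  keep_c <- colSums(M) > 0
  M <- M[keep_r, keep_c, drop = FALSE]
  rb <- rb[keep_r]; cb <- cb[keep_c]
  rows <- tibble(drug = paste0("r", which(keep_r)), gene = "synthetic",
                 occurrences = rowSums(M))
  cols <- tibble(path = paste0("c", which(keep_c)), occurrences = colSums(M))
  mat <- ebc_matrix(M, rows, cols)
  list(matrix = mat,
       row_blocks = setNames(rb, rownames(mat$M)),
       col_blocks = setNames(cb, colnames(mat$M)))
}

#' Synthetic synonymy scenario
#'
#' Emulates the central difficulty of corpus-level relationship mining: one
#' relationship class is expressed through two *disjoint* sets of surface
#' forms (column blocks A and B), and the evaluated positive rows split so
#' that half touch only block A and half only block B — so the cosine between
#' any evaluated cross-split pair of rows is exactly 0. The corpus context
#' that makes the synonymy learnable is planted alongside, mirroring real
#' literature-derived matrices:
#'
#' * `n_bridge` unlabelled rows whose relationship is documented through
#'   *both* surface forms (these connect column blocks A and B, exactly as
#'   well-studied pairs connect synonymous phrasings in a real corpus);
#' * negatives drawn from `n_bg_blocks` distinct background relationship
#'   classes, each with its own column block;
#' * `n_filler_blocks` further unlabelled relationship classes that provide
#'   the bulk of unrelated rows against which rank-sum scores discriminate
#'   (real matrices have thousands of such rows).
#'
#' Support disjointness of the two evaluated splits is structural (their
#' blocks share no columns and split rows receive no background noise) and is
#' verified on the generated matrix; `p_out` noise, when requested, is applied
#' only to background and filler rows on background and filler columns, so it
#' can never break the disjointness guarantee.
#'
#' @param rows_per_split Rows in each evaluated positive split (the positives
#'   returned are the `2 * rows_per_split` split rows).
#' @param cols_per_surface_form Columns in each of the two surface-form
#'   blocks.
#' @param p_in Within-association Bernoulli probability.
#' @param p_out Background noise probability for background/filler rows on
#'   background/filler columns.
#' @param seed Generation seed.
#' @param n_bridge Number of unlabelled bridge rows.
#' @param n_neg Total negative rows, divided evenly among the background
#'   classes.
#' @param n_bg_blocks Number of background classes (must divide `n_neg`).
#' @param cols_bg Columns per background class block.
#' @param n_filler_blocks,filler_rows,filler_cols Unlabelled filler classes.
#' @return A list with `matrix` (an [ebc_matrix()]), `positives`, `negatives`
#'   (character label vectors), `splits` (tibble: `label`, `split` in
#'   `"A"`/`"B"`), and `roles` (named character vector over all rows).
#' @export
synonymy_scenario <- function(rows_per_split = 40L, cols_per_surface_form = 10L,
                              p_in = 0.8, p_out = 0, seed = 1L,
                              n_bridge = 40L, n_neg = 40L, n_bg_blocks = 2L,
                              cols_bg = 25L, n_filler_blocks = 4L,
                              filler_rows = 30L, filler_cols = 15L) {
  rows_per_split <- check_scalar_count(rows_per_split, "rows_per_split")
  cols_per_surface_form <- check_scalar_count(cols_per_surface_form,
                                              "cols_per_surface_form")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop_ebclust("Need 0 <= p_out < p_in <= 1.", "ebclust_bad_spec")
  }
  if (n_neg %% n_bg_blocks != 0) {
    stop_ebclust("n_neg must be divisible by n_bg_blocks.", "ebclust_bad_spec")
  }
  n_per_bg <- n_neg %/% n_bg_blocks
  n <- 2 * rows_per_split + n_bridge + n_neg + n_filler_blocks * filler_rows
  m <- 2 * cols_per_surface_form + n_bg_blocks * cols_bg +
    n_filler_blocks * filler_cols

  roles <- rep(c("split_A", "split_B", "bridge",
                 paste0("background_", seq_len(n_bg_blocks)),
                 paste0("filler_", seq_len(n_filler_blocks))),
               c(rows_per_split, rows_per_split, n_bridge,
                 rep(n_per_bg, n_bg_blocks),
                 rep(filler_rows, n_filler_blocks)))
  col_role <- rep(c("sf_A", "sf_B",
                    paste0("bg_", seq_len(n_bg_blocks)),
                    paste0("fill_", seq_len(n_filler_blocks))),
                  c(cols_per_surface_form, cols_per_surface_form,
                    rep(cols_bg, n_bg_blocks),
                    rep(filler_cols, n_filler_blocks)))

  M <- with_preserved_seed(seed, {
    M <- matrix(0L, n, m)
    fill <- function(M, rr, cc, p) {
      M[rr, cc] <- rbinom(length(rr) * length(cc), 1, p)
      M
    }
    M <- fill(M, which(roles == "split_A"), which(col_role == "sf_A"), p_in)
    M <- fill(M, which(roles == "split_B"), which(col_role == "sf_B"), p_in)
    M <- fill(M, which(roles == "bridge"),
              which(col_role %in% c("sf_A", "sf_B")), p_in)
    for (b in seq_len(n_bg_blocks)) {
      M <- fill(M, which(roles == paste0("background_", b)),
                which(col_role == paste0("bg_", b)), p_in)
    }
    for (b in seq_len(n_filler_blocks)) {
      M <- fill(M, which(roles == paste0("filler_", b)),
                which(col_role == paste0("fill_", b)), p_in)
    }
    if (p_out > 0) {
      noise_rows <- which(!roles %in% c("split_A", "split_B", "bridge"))
      noise_cols <- which(!col_role %in% c("sf_A", "sf_B"))
      idx <- cbind(rep(noise_rows, length(noise_cols)),
                   rep(noise_cols, each = length(noise_rows)))
      flip <- rbinom(nrow(idx), 1, p_out) == 1
      M[idx[flip, , drop = FALSE]] <- 1L
    }
    M
  })

  keep_r <- rowSums(M) > 0
  keep_c <- colSums(M) > 0
  M <- M[keep_r, keep_c, drop = FALSE]
  roles <- roles[keep_r]

  rows <- tibble(drug = paste0("pair", which(keep_r)), gene = "synthetic",
                 occurrences = rowSums(M))
  cols <- tibble(path = paste0("path", which(keep_c)),
                 occurrences = colSums(M))
  mat <- ebc_matrix(M, rows, cols)
  labels <- rownames(mat$M)

  # verify structural support disjointness of the two evaluated splits
  sa <- M[roles == "split_A", , drop = FALSE]
  sb <- M[roles == "split_B", , drop = FALSE]
  shared <- sum((colSums(sa) > 0) & (colSums(sb) > 0))
  if (shared > 0) {
    stop_ebclust("Internal error: evaluated splits share nonzero columns.",
                 "ebclust_bad_spec")
  }

  positives <- labels[roles %in% c("split_A", "split_B")]
  list(
    matrix = mat,
    positives = positives,
    negatives = labels[startsWith(roles, "background_")],
    splits = tibble(
      label = positives,
      split = ifelse(roles[roles %in% c("split_A", "split_B")] == "split_A",
                     "A", "B")
    ),
    roles = setNames(roles, labels)
  )
}
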