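#' Normalise a co-occurrence matrix into a joint distribution
#'
#' ITCC treats the binary matrix as an empirical joint probability
#' distribution over its rows `Y` (entity pairs) and columns `X` (dependency
#' paths): `p(x, y) = M[y, x] / sum(M)`.
#'
#' @param matrix An [ebc_matrix()] or a plain numeric matrix with at least one
#'   nonzero.
#' @return A list of class `ebc_joint` with `p` (dense `n x m` matrix summing
#'   to 1), `p_y` (row marginals), `p_x` (column marginals).
#' @export
normalize_joint <- function(matrix) {
  M <- as_dense(matrix)
  if (any(M < 0)) {
    stop_ebclust("Matrix entries must be non-negative.", "ebclust_bad_matrix")
  }
  tot <- sum(M)
  if (tot <= 0) {
    stop_ebclust("Matrix has no nonzero entries.", "ebclust_empty_matrix")
  }
  p <- M / tot
  structure(list(p = p, p_y = rowSums(p), p_x = colSums(p), total = tot),
            class = "ebc_joint")
}

as_dense <- function(matrix) {
  if (inherits(matrix, "ebc_matrix")) {
    M <- as.matrix(matrix$M) * 1
  } else {
    M <- as.matrix(matrix) * 1
  }
  M
}

# Aggregate columns of `mat` by cluster assignment into `nc` groups.
agg_cols <- function(mat, assign, nc) {
  Z <- matrix(0, ncol(mat), nc)
  Z[cbind(seq_len(ncol(mat)), assign)] <- 1
  mat %*% Z
}

# Block-mass matrix q(yhat, xhat), k x l.
block_mass <- function(p, row_assign, col_assign, k, l) {
  Pyl <- agg_cols(p, col_assign, l)
  qh <- matrix(0, k, l)
  s <- rowsum(Pyl, row_assign)
  qh[as.integer(rownames(s)), ] <- s
  qh
}

group_sum <- function(x, assign, ng) {
  out <- rep(0, ng)
  s <- rowsum(x, assign)
  out[as.integer(rownames(s))] <- s
  out
}

#' Block-factorised approximation q(x, y)
#'
#' Given cluster assignments, the approximating distribution factorises as
#' `q(x, y) = q(xhat, yhat) q(x | xhat) q(y | yhat)` where `q(xhat, yhat)` is
#' the mass of the (column-cluster, row-cluster) block, `q(x | xhat) =
#' p(x)/p(xhat)` and `q(y | yhat) = p(y)/p(yhat)`. `q` preserves all row and
#' column marginals of `p` and all block masses. An empty cluster has block
#' mass 0 and its conditionals are taken to be 0.
#'
#' @param joint An `ebc_joint` from [normalize_joint()].
#' @param row_assign,col_assign Integer cluster assignments for all rows /
#'   columns.
#' @param k,l Numbers of row and column clusters.
#' @return Dense `n x m` matrix `q` summing to 1.
#' @export
compute_q <- function(joint, row_assign, col_assign, k, l) {
  stopifnot(inherits(joint, "ebc_joint"))
  n <- nrow(joint$p); m <- ncol(joint$p)
  stopifnot(length(row_assign) == n, length(col_assign) == m)
  qh <- block_mass(joint$p, row_assign, col_assign, k, l)
  p_yhat <- group_sum(joint$p_y, row_assign, k)
  p_xhat <- group_sum(joint$p_x, col_assign, l)
  ry <- ifelse(p_yhat[row_assign] > 0, joint$p_y / p_yhat[row_assign], 0)
  cx <- ifelse(p_xhat[col_assign] > 0, joint$p_x / p_xhat[col_assign], 0)
  q <- qh[cbind(rep(row_assign, m), rep(col_assign, each = n))]
  q <- matrix(q, n, m) * outer(ry, cx)
  dimnames(q) <- dimnames(joint$p)
  q
}

#' Kullback-Leibler objective of a biclustering
#'
#' `sum(p * log(p / q))` in nats, with the convention `0 * log(0 / .) = 0`.
#' Returns `Inf` when `q` is 0 somewhere `p` is positive.
#'
#' @param joint An `ebc_joint`.
#' @param q Approximating distribution (same shape as `joint$p`).
#' @return KL divergence in nats (non-negative; possibly `Inf`).
#' @export
kl_objective <- function(joint, q) {
  pos <- joint$p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(joint$p[pos] * log(joint$p[pos] / q[pos]))
}

# Fast objective using only nonzero cells and the factorised form.
kl_objective_assign <- function(joint, row_assign, col_assign, k, l, nz) {
  qh <- block_mass(joint$p, row_assign, col_assign, k, l)
  p_yhat <- group_sum(joint$p_y, row_assign, k)
  p_xhat <- group_sum(joint$p_x, col_assign, l)
  pv <- joint$p[nz]
  qv <- qh[cbind(row_assign[nz[, 1]], col_assign[nz[, 2]])] *
    (joint$p_y[nz[, 1]] / p_yhat[row_assign[nz[, 1]]]) *
    (joint$p_x[nz[, 2]] / p_xhat[col_assign[nz[, 2]]])
  if (any(qv == 0)) return(Inf)
  sum(pv * log(pv / qv))
}

# One batch reassignment of the rows of `p` (use t(p) and swapped marginals
# for the column step). Each row y moves to the cluster minimising
# KL(p(X | y) || q(X | yhat)); rows whose every candidate has infinite
# divergence keep their current assignment; ties go to the lowest index.
reassign <- function(p, p_y, p_x, row_assign, col_assign, k, l) {
  Pyl <- agg_cols(p, col_assign, l)
  qh <- matrix(0, k, l)
  s <- rowsum(Pyl, row_assign)
  qh[as.integer(rownames(s)), ] <- s
  p_xhat <- group_sum(p_x, col_assign, l)
  q_yhat <- group_sum(p_y, row_assign, k)
  W <- Pyl / p_y                              # p(xhat | y)
  G <- t(log(qh)) - log(p_xhat)               # l x k, -Inf at empty blocks
  bad <- (W > 0) %*% ((t(qh) == 0) * 1)       # n x k
  G[!is.finite(G)] <- 0
  cost <- -(W %*% G) + rep(log(q_yhat), each = nrow(W))
  cost[bad > 0] <- Inf
  cost[, q_yhat == 0] <- Inf                  # empty target cluster
  new <- max.col(-cost, ties.method = "first")
  stuck <- !is.finite(cost[cbind(seq_len(nrow(cost)), new)])
  new[stuck] <- row_assign[stuck]
  new
}

#' Information-theoretic co-clustering of a binary matrix
#'
#' Alternating minimisation of the KL divergence between the empirical joint
#' distribution `p(x, y)` and its block-factorised approximation `q(x, y)`
#' (see [compute_q()]). Starting from a uniformly random assignment of rows to
#' `k` clusters and columns to `l` clusters (driven by `seed`), each sweep
#' batch-reassigns every row to the cluster minimising
#' `KL(p(X | y) || q(X | yhat))`, recomputes `q`, then does the symmetric
#' column step. The objective is non-increasing across every step; iteration
#' stops when the relative decrease over a full sweep falls below `tol` or
#' after `max_iter` sweeps. Clusters that empty out during iteration may stay
#' empty (no reseeding). Results are bit-identical for identical
#' `(matrix, k, l, seed)`.
#'
#' @param matrix An [ebc_matrix()] or plain binary matrix.
#' @param k,l Number of row / column clusters, `1 <= k <= n`, `1 <= l <= m`.
#' @param seed Integer seed for the random initialisation.
#' @param max_iter Maximum number of full row+column sweeps.
#' @param tol Relative objective-decrease threshold for convergence.
#' @return An object of class `ebc_biclustering`: list with `row_assign`,
#'   `col_assign` (named integer vectors), `k`, `l`, `objective` (nats),
#'   `trace` (objective after initialisation and after each half-sweep),
#'   `iterations`, `seed`, `converged`.
#' @export
itcc <- function(matrix, k, l, seed = 1L, max_iter = 50L, tol = 1e-6) {
  joint <- normalize_joint(matrix)
  n <- nrow(joint$p); m <- ncol(joint$p)
  k <- check_scalar_count(k, "k"); l <- check_scalar_count(l, "l")
  if (k > n || l > m) {
    stop_ebclust(sprintf("k must be in [1, n] and l in [1, m]; got k=%d, l=%d for %d x %d.",
                         k, l, n, m), "ebclust_bad_argument")
  }
  nz <- which(joint$p > 0, arr.ind = TRUE)
  # Uniform random assignment, with one random row/column pre-seeded into
  # every cluster so none starts empty (in particular k = n begins, and
  # stays, at the exact singleton solution).
  rand_assign <- function(count, nclust) {
    a <- sample.int(nclust, count, replace = TRUE)
    a[sample.int(count, nclust)] <- sample.int(nclust)
    a
  }
  init <- with_preserved_seed(seed, list(
    row = rand_assign(n, k),
    col = rand_assign(m, l)
  ))
  ra <- init$row; ca <- init$col
  obj <- kl_objective_assign(joint, ra, ca, k, l, nz)
  trace <- obj
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    ra <- reassign(joint$p, joint$p_y, joint$p_x, ra, ca, k, l)
    trace <- c(trace, kl_objective_assign(joint, ra, ca, k, l, nz))
    ca <- reassign(t(joint$p), joint$p_x, joint$p_y, ca, ra, l, k)
    new_obj <- kl_objective_assign(joint, ra, ca, k, l, nz)
    trace <- c(trace, new_obj)
    iterations <- it
    if (is.finite(obj) && is.finite(new_obj) &&
        (obj - new_obj) < tol * max(abs(obj), .Machine$double.eps)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  row_names <- rownames(joint$p) %||% as.character(seq_len(n))
  col_names <- colnames(joint$p) %||% as.character(seq_len(m))
  structure(list(
    row_assign = setNames(ra, row_names),
    col_assign = setNames(ca, col_names),
    k = k, l = l,
    objective = obj,
    trace = trace,
    iterations = iterations,
    seed = seed,
    converged = converged
  ), class = "ebc_biclustering")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ebc_biclustering <- function(x, ...) {
  cat(sprintf(
    "<ebc_biclustering> k=%d, l=%d, objective=%.6g nats after %d sweep(s)%s (seed %d)\n",
    x$k, x$l, x$objective, x$iterations,
    if (x$converged) "" else " [max_iter reached]", x$seed
  ))
  invisible(x)
}

#' @rdname itcc
#' @param x An `ebc_biclustering`.
#' @param ... Unused.
#' @export
tidy.ebc_biclustering <- function(x, ...) {
  dplyr::bind_rows(
    tibble(label = names(x$row_assign), axis = "row",
           cluster = as.integer(x$row_assign)),
    tibble(label = names(x$col_assign), axis = "column",
           cluster = as.integer(x$col_assign))
  )
}

#' @rdname itcc
#' @export
glance.ebc_biclustering <- function(x, ...) {
  tibble(k = x$k, l = x$l, objective = x$objective,
         iterations = x$iterations, converged = x$converged, seed = x$seed)
}

#' Smoothed matrix implied by a biclustering
#'
#' The approximating distribution `q` rescaled to the original matrix's total
#' count. Cells unobserved in the data but consistent with the discovered
#' block structure are "filled in"; all row and column sums equal those of the
#' original matrix.
#'
#' @param matrix The matrix the biclustering was fitted to.
#' @param biclustering An `ebc_biclustering` from [itcc()].
#' @return Dense numeric matrix with the same dimnames as the input.
#' @export
smoothed_matrix <- function(matrix, biclustering) {
  stopifnot(inherits(biclustering, "ebc_biclustering"))
  joint <- normalize_joint(matrix)
  q <- compute_q(joint, biclustering$row_assign, biclustering$col_assign,
                 biclustering$k, biclustering$l)
  q * joint$total
}

#' Select cluster numbers over a grid by penalised objective
#'
#' For every `(k, l)` grid point, runs [itcc()] `restarts` times with
#' deterministic seeds derived from `seed` and keeps the best (lowest)
#' objective, then selects the point minimising
#' `best_objective + lambda * (k + l) / min(n, m)`. The penalty breaks ties in
#' favour of fewer clusters. This is a pragmatic substitute for choosing the
#' cluster numbers by inspection of the data; published matrices of this kind
#' have used `(k, l)` = (30, 125) for the dense preset and (7, 25) for the
#' sparse one (see [ebc_presets]).
#'
#' @param matrix An [ebc_matrix()] or plain binary matrix.
#' @param k_grid,l_grid Integer vectors of candidate cluster numbers.
#' @param restarts Random restarts per grid point.
#' @param seed Master seed for the restart schedule.
#' @param lambda Penalty weight.
#' @param max_iter,tol Passed to [itcc()].
#' @return A list with `k`, `l`, and `table` (a tibble of grid results).
#' @export
choose_kl <- function(matrix, k_grid, l_grid, restarts = 5L, seed = 1L,
                      lambda = 1, max_iter = 50L, tol = 1e-6) {
  if (length(k_grid) == 0 || length(l_grid) == 0) {
    stop_ebclust("k_grid and l_grid must be non-empty.", "ebclust_bad_argument")
  }
  joint_dims <- dim(as_dense(matrix))
  grid <- tidyr::expand_grid(k = sort(unique(as.integer(k_grid))),
                             l = sort(unique(as.integer(l_grid))))
  res <- purrr::pmap(grid, function(k, l) {
    objs <- vapply(seq_len(restarts), function(r) {
      itcc(matrix, k, l, seed = derive_seed(seed, k, l, r),
           max_iter = max_iter, tol = tol)$objective
    }, 0)
    tibble(k = k, l = l, objective = min(objs))
  })
  tab <- dplyr::bind_rows(res) |>
    dplyr::mutate(penalized = .data$objective +
                    lambda * (.data$k + .data$l) / min(joint_dims))
  best <- tab |>
    dplyr::arrange(.data$penalized, .data$k + .data$l, .data$k) |>
    dplyr::slice(1)
  list(k = best$k, l = best$l, table = tab)
}

#' Published cluster-number presets
#'
#' Row and column cluster numbers used with the two standard matrix presets:
#' dense (pairs and paths occurring at least five times) and sparse (paths at
#' least twice, all their pairs).
#'
#' @format A tibble with columns `preset`, `k`, `l`.
#' @export
ebc_presets <- tibble::tibble(
  preset = c("dense", "sparse"),
  k = c(30L, 7L),
  l = c(125L, 25L)
)
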