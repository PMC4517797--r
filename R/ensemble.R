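#' Ensemble of ITCC runs: co-clustering counts
#'
#' Runs [itcc()] `N` times at fixed `(k, l)`, with run `i` seeded
#' `base_seed + i`, and records for each pair of rows (or columns) the number
#' of runs in which they shared a cluster. The resulting symmetric `n x n`
#' integer matrix `C` — with `C[i, i] = N` and `0 <= C[i, j] <= N` — is EBC's
#' similarity representation: two entity pairs that frequently co-cluster are
#' connected by similar dependency paths, even when they share none directly.
#' The result depends only on the inputs and `base_seed`, not on execution
#' order.
#'
#' @param matrix An [ebc_matrix()] or plain binary matrix.
#' @param k,l Cluster numbers for every run.
#' @param N Number of runs (>= 1). Published analyses used N = 2000, with
#'   performance stabilising from roughly N = 1000.
#' @param base_seed Base of the per-run seed schedule.
#' @param axis `"rows"` (default), `"columns"`, or `"both"`.
#' @param max_iter,tol Passed to [itcc()].
#' @return An object of class `ebc_cocluster` (list with integer matrix
#'   `counts`, `N`, `axis`, `labels`), or for `axis = "both"` a named list of
#'   two such objects (`rows`, `columns`) computed from the same runs.
#' @export
run_ensemble <- function(matrix, k, l, N = 200L, base_seed = 1L,
                         axis = c("rows", "columns", "both"),
                         max_iter = 50L, tol = 1e-6) {
  axis <- match.arg(axis)
  N <- check_scalar_count(N, "N")
  dims <- dim(as_dense(matrix))
  n <- dims[1]; m <- dims[2]
  want_rows <- axis %in% c("rows", "both")
  want_cols <- axis %in% c("columns", "both")
  Cr <- if (want_rows) matrix(0L, n, n)
  Cc <- if (want_cols) matrix(0L, m, m)
  row_labels <- col_labels <- NULL
  for (i in seq_len(N)) {
    fit <- itcc(matrix, k, l, seed = base_seed + i,
                max_iter = max_iter, tol = tol)
    if (is.null(row_labels)) {
      row_labels <- names(fit$row_assign)
      col_labels <- names(fit$col_assign)
    }
    if (want_rows) {
      Z <- matrix(0L, n, k)
      Z[cbind(seq_len(n), fit$row_assign)] <- 1L
      Cr <- Cr + Z %*% t(Z)
    }
    if (want_cols) {
      Z <- matrix(0L, m, l)
      Z[cbind(seq_len(m), fit$col_assign)] <- 1L
      Cc <- Cc + Z %*% t(Z)
    }
  }
  make <- function(counts, labels, ax) {
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(labels, labels)
    structure(list(counts = counts, N = N, axis = ax, labels = labels),
              class = "ebc_cocluster")
  }
  if (axis == "rows") return(make(Cr, row_labels, "rows"))
  if (axis == "columns") return(make(Cc, col_labels, "columns"))
  list(rows = make(Cr, row_labels, "rows"),
       columns = make(Cc, col_labels, "columns"))
}

#' @export
print.ebc_cocluster <- function(x, ...) {
  cat(sprintf("<ebc_cocluster> %d x %d co-clustering counts over N = %d runs (%s)\n",
              nrow(x$counts), ncol(x$counts), x$N, x$axis))
  invisible(x)
}

#' Co-clustering frequencies
#'
#' Counts divided by the number of runs: `C / N`, the fraction of ensemble
#' runs in which each pair of rows (or columns) shared a cluster.
#'
#' @param cocluster An `ebc_cocluster` from [run_ensemble()].
#' @return Numeric matrix of frequencies in `[0, 1]`.
#' @export
cocluster_frequency <- function(cocluster) {
  stopifnot(inherits(cocluster, "ebc_cocluster"))
  cocluster$counts / cocluster$N
}

#' @rdname run_ensemble
#' @param x An `ebc_cocluster`.
#' @param ... Unused.
#' @export
tidy.ebc_cocluster <- function(x, ...) {
  ut <- which(upper.tri(x$counts), arr.ind = TRUE)
  tibble(
    item1 = x$labels[ut[, 1]],
    item2 = x$labels[ut[, 2]],
    count = x$counts[ut],
    frequency = x$counts[ut] / x$N
  )
}

#' Write / read co-clustering counts in a sparse text format
#'
#' Same coordinate dialect as [write_ebc_matrix()], with an `#nruns` header
#' line and `i<TAB>j<TAB>count` entries for the upper triangle (diagonal
#' implicit at N).
#'
#' @param cocluster An `ebc_cocluster`.
#' @param path Destination / source path.
#' @export
write_cocluster <- function(cocluster, path) {
  stopifnot(inherits(cocluster, "ebc_cocluster"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  n <- nrow(cocluster$counts)
  writeLines(c(sprintf("#rows %d", n),
               sprintf("#nruns %d", cocluster$N),
               sprintf("#axis %s", cocluster$axis)), con)
  writeLines(cocluster$labels, con)
  ut <- which(upper.tri(cocluster$counts) & cocluster$counts > 0, arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  writeLines(sprintf("%d\t%d\t%d", ut[ord, 1] - 1L, ut[ord, 2] - 1L,
                     cocluster$counts[ut][ord]), con)
  invisible(path)
}

#' @rdname write_cocluster
#' @export
read_cocluster <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 3 || !startsWith(lines[1], "#rows ") ||
      !startsWith(lines[2], "#nruns ") || !startsWith(lines[3], "#axis ")) {
    stop_ebclust("Bad co-cluster file header.", "ebclust_parse_error")
  }
  n <- as.integer(sub("^#rows ", "", lines[1]))
  N <- as.integer(sub("^#nruns ", "", lines[2]))
  axis <- sub("^#axis ", "", lines[3])
  labels <- lines[3 + seq_len(n)]
  counts <- matrix(0L, n, n)
  diag(counts) <- N
  entries <- lines[-seq_len(3 + n)]
  entries <- entries[nzchar(entries)]
  if (length(entries)) {
    f <- strsplit(entries, "\t", fixed = TRUE)
    i <- as.integer(vapply(f, `[[`, "", 1)) + 1L
    j <- as.integer(vapply(f, `[[`, "", 2)) + 1L
    v <- as.integer(vapply(f, `[[`, "", 3))
    if (anyNA(i) || anyNA(j) || anyNA(v) || any(i < 1 | i > n | j < 1 | j > n) ||
        any(v < 0 | v > N)) {
      stop_ebclust("Co-cluster entry out of bounds.", "ebclust_parse_error")
    }
    counts[cbind(i, j)] <- v
    counts[cbind(j, i)] <- v
  }
  dimnames(counts) <- list(labels, labels)
  structure(list(counts = counts, N = N, axis = axis, labels = labels),
            class = "ebc_cocluster")
}
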