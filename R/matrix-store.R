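#' Binary pair-by-path co-occurrence matrix
#'
#' The central data container: a binary `n x m` matrix `M` whose rows are
#' entity pairs (drug, gene) and whose columns are canonical dependency-path
#' strings. `M[i, j] = 1` when pair `i` is connected by path `j` somewhere in
#' the corpus. Corpus occurrence totals for every surviving row and column are
#' retained as metadata so that threshold filtering remains reproducible and
#' idempotent.
#'
#' @param entries A \linkS4class{ngCMatrix}-coercible sparse pattern matrix
#'   (or base logical/numeric matrix) of 0/1 entries.
#' @param rows Tibble with columns `drug`, `gene`, `occurrences` describing the
#'   matrix rows in order.
#' @param cols Tibble with columns `path`, `occurrences` describing the matrix
#'   columns in order.
#' @return An object of class `ebc_matrix` with elements `M` (ngCMatrix),
#'   `rows`, `cols`.
#' @export
ebc_matrix <- function(entries, rows, cols) {
  M <- Matrix::Matrix(entries, sparse = TRUE)
  M <- methods::as(methods::as(methods::as(M, "nMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  rows <- as_tibble(rows)
  cols <- as_tibble(cols)
  stopifnot(all(c("drug", "gene", "occurrences") %in% names(rows)),
            all(c("path", "occurrences") %in% names(cols)),
            nrow(rows) == nrow(M), nrow(cols) == ncol(M))
  lab <- pair_label(rows$drug, rows$gene)
  if (anyDuplicated(lab) || anyDuplicated(cols$path)) {
    stop_ebclust("Row and column labels must be unique.", "ebclust_bad_matrix")
  }
  dimnames(M) <- list(lab, cols$path)
  structure(list(M = M, rows = rows, cols = cols), class = "ebc_matrix")
}

pair_label <- function(drug, gene) paste(drug, gene, sep = "::")

#' @export
print.ebc_matrix <- function(x, ...) {
  s <- matrix_stats(x)
  cat(sprintf(
    "<ebc_matrix> %d entity pairs x %d dependency paths, %d nonzeros (%.1f%% sparse)\n",
    s$n, s$m, s$nnz, s$sparsity_pct
  ))
  invisible(x)
}

#' @export
dim.ebc_matrix <- function(x) dim(x$M)

#' Build a filtered binary co-occurrence matrix from triplet records
#'
#' Applies corpus-occurrence thresholds to aggregated (drug, gene, path,
#' count) records and binarises the survivors. Occurrence totals are computed
#' on the *full* record set (a pair's occurrences = the sum of its counts over
#' all paths; a path's occurrences = the sum over all pairs), mirroring
#' "occurred at least x times in the corpus" rather than filtered row sums.
#' Paths and pairs failing their thresholds are removed, then rows and columns
#' left empty are dropped once (no fixpoint iteration). Stored occurrence
#' metadata makes re-filtering with the same thresholds a no-op.
#'
#' Two standard presets are used: `"dense"` keeps pairs and paths occurring at
#' least five times; `"sparse"` keeps paths occurring at least twice together
#' with every pair they connect, even pairs seen only once.
#'
#' @param records Tibble with columns `drug`, `gene`, `path`, `count`
#'   (aggregated: no duplicate (drug, gene, path) keys; counts >= 1).
#' @param min_pair_occurrences,min_path_occurrences Corpus-occurrence
#'   thresholds. Ignored when `preset` is given.
#' @param preset Optional `"dense"` (5, 5) or `"sparse"` (1, 2) shortcut.
#' @return An [ebc_matrix()].
#' @export
build_matrix <- function(records, min_pair_occurrences = 1,
                         min_path_occurrences = 1,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("dense", "sparse"))
    if (preset == "dense") {
      min_pair_occurrences <- 5; min_path_occurrences <- 5
    } else {
      min_pair_occurrences <- 1; min_path_occurrences <- 2
    }
  }
  records <- as_tibble(records)
  stopifnot(all(c("drug", "gene", "path", "count") %in% names(records)))
  if (any(records$count < 1)) {
    stop_ebclust("Triplet counts must be >= 1.", "ebclust_bad_argument")
  }
  key <- paste(records$drug, records$gene, records$path, sep = "\r")
  if (anyDuplicated(key)) {
    stop_ebclust("Records must be aggregated: duplicate (drug, gene, path) keys found.",
                 "ebclust_bad_argument")
  }

  pair_occ <- records |>
    dplyr::summarise(occurrences = sum(.data$count), .by = c("drug", "gene"))
  path_occ <- records |>
    dplyr::summarise(occurrences = sum(.data$count), .by = "path")

  keep <- records |>
    dplyr::inner_join(dplyr::filter(pair_occ, .data$occurrences >= min_pair_occurrences),
                      by = c("drug", "gene")) |>
    dplyr::inner_join(dplyr::filter(path_occ, .data$occurrences >= min_path_occurrences),
                      by = "path", suffix = c("_pair", "_path"))
  if (nrow(keep) == 0) {
    failing <- if (max(path_occ$occurrences) < min_path_occurrences) {
      sprintf("min_path_occurrences = %d", min_path_occurrences)
    } else {
      sprintf("min_pair_occurrences = %d", min_pair_occurrences)
    }
    stop_ebclust(
      sprintf("No entries survive filtering (threshold %s emptied the matrix).", failing),
      "ebclust_empty_matrix"
    )
  }

  rows <- keep |>
    dplyr::distinct(.data$drug, .data$gene, occurrences = .data$occurrences_pair) |>
    dplyr::arrange(.data$drug, .data$gene)
  cols <- keep |>
    dplyr::distinct(.data$path, occurrences = .data$occurrences_path) |>
    dplyr::arrange(.data$path)
  i <- match(pair_label(keep$drug, keep$gene), pair_label(rows$drug, rows$gene))
  j <- match(keep$path, cols$path)
  M <- Matrix::sparseMatrix(i = i, j = j, dims = c(nrow(rows), nrow(cols)))
  ebc_matrix(M, rows, cols)
}

#' Summary statistics of a co-occurrence matrix
#'
#' @param matrix An [ebc_matrix()].
#' @return A one-row tibble with `n` (pairs), `m` (paths), `nnz` and
#'   `sparsity_pct` = `100 * (1 - nnz/(n*m))`, rounded to one decimal.
#' @export
matrix_stats <- function(matrix) {
  stopifnot(inherits(matrix, "ebc_matrix"))
  n <- nrow(matrix$M); m <- ncol(matrix$M)
  nnz <- Matrix::nnzero(matrix$M)
  tibble(n = n, m = m, nnz = nnz,
         sparsity_pct = round(100 * (1 - nnz / (n * m)), 1))
}

#' Write / read the sparse text format for co-occurrence matrices
#'
#' A plain-text interchange format: a header `#rows N` and `#cols M`, then `N`
#' row-label lines (`drug<TAB>gene<TAB>occurrences`), `M` column-label lines
#' (`path<TAB>occurrences`), then one `i<TAB>j` 0-based coordinate line per
#' nonzero. Round-trips are exact.
#'
#' @param matrix An [ebc_matrix()].
#' @param path Destination / source file path.
#' @return `write_ebc_matrix()` returns `path` invisibly; `read_ebc_matrix()`
#'   returns an [ebc_matrix()].
#' @export
write_ebc_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "ebc_matrix"))
  idx <- Matrix::summary(matrix$M)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#rows %d", nrow(matrix$M)),
               sprintf("#cols %d", ncol(matrix$M))), con)
  writeLines(sprintf("%s\t%s\t%d", matrix$rows$drug, matrix$rows$gene,
                     matrix$rows$occurrences), con)
  writeLines(sprintf("%s\t%d", matrix$cols$path, matrix$cols$occurrences), con)
  ord <- order(idx$i, idx$j)
  writeLines(sprintf("%d\t%d", idx$i[ord] - 1L, idx$j[ord] - 1L), con)
  invisible(path)
}

#' @rdname write_ebc_matrix
#' @export
read_ebc_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parse_fail <- function(lineno, why) {
    stop_ebclust(sprintf("Parse error at line %d: %s", lineno, why),
                 "ebclust_parse_error")
  }
  if (length(lines) < 2 || !startsWith(lines[1], "#rows ") ||
      !startsWith(lines[2], "#cols ")) {
    parse_fail(1, "expected '#rows N' then '#cols M' header")
  }
  n <- suppressWarnings(as.integer(sub("^#rows ", "", lines[1])))
  m <- suppressWarnings(as.integer(sub("^#cols ", "", lines[2])))
  if (is.na(n) || is.na(m) || n < 1 || m < 1) parse_fail(1, "bad dimensions")
  need <- 2 + n + m
  if (length(lines) < need) parse_fail(length(lines), "truncated label block")
  row_lines <- strsplit(lines[3:(2 + n)], "\t", fixed = TRUE)
  if (any(vapply(row_lines, length, 0L) != 3)) {
    parse_fail(2 + which(vapply(row_lines, length, 0L) != 3)[1],
               "row label lines need 3 fields")
  }
  col_lines <- strsplit(lines[(3 + n):(2 + n + m)], "\t", fixed = TRUE)
  if (any(vapply(col_lines, length, 0L) != 2)) {
    parse_fail(2 + n + which(vapply(col_lines, length, 0L) != 2)[1],
               "column label lines need 2 fields")
  }
  rows <- tibble(
    drug = vapply(row_lines, `[[`, "", 1),
    gene = vapply(row_lines, `[[`, "", 2),
    occurrences = as.integer(vapply(row_lines, `[[`, "", 3))
  )
  cols <- tibble(
    path = vapply(col_lines, `[[`, "", 1),
    occurrences = as.integer(vapply(col_lines, `[[`, "", 2))
  )
  entry_lines <- lines[-seq_len(need)]
  entry_lines <- entry_lines[nzchar(entry_lines)]
  ij <- strsplit(entry_lines, "\t", fixed = TRUE)
  if (length(ij) && any(vapply(ij, length, 0L) != 2)) {
    parse_fail(need + which(vapply(ij, length, 0L) != 2)[1],
               "coordinate lines need 2 fields")
  }
  i <- as.integer(vapply(ij, `[[`, "", 1)) + 1L
  j <- as.integer(vapply(ij, `[[`, "", 2)) + 1L
  if (length(i) == 0) parse_fail(need, "matrix has no nonzero entries")
  if (anyNA(i) || anyNA(j) || any(i < 1 | i > n) || any(j < 1 | j > m)) {
    bad <- which(is.na(i) | is.na(j) | i < 1 | i > n | j < 1 | j > m)[1]
    parse_fail(need + bad, "coordinate out of declared bounds")
  }
  if (anyDuplicated(cbind(i, j))) {
    parse_fail(need + which(duplicated(cbind(i, j)))[1], "duplicate entry")
  }
  ebc_matrix(Matrix::sparseMatrix(i = i, j = j, dims = c(n, m)), rows, cols)
}
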