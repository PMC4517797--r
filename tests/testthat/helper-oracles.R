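# Independent brute-force oracles used to validate the implementation.

# KL(p || q) by direct term-by-term summation.
brute_kl <- function(p, q) {
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        if (q[i, j] == 0) return(Inf)
        s <- s + p[i, j] * log(p[i, j] / q[i, j])
      }
    }
  }
  s
}

# q(x, y) built by literally expanding the three factors of the block
# factorisation, cell by cell.
brute_q <- function(p, ra, ca) {
  n <- nrow(p); m <- ncol(p)
  p_y <- rowSums(p); p_x <- colSums(p)
  q <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      block <- sum(p[ra == ra[i], ca == ca[j], drop = FALSE])
      p_yhat <- sum(p_y[ra == ra[i]])
      p_xhat <- sum(p_x[ca == ca[j]])
      q[i, j] <- if (p_yhat > 0 && p_xhat > 0) {
        block * (p_y[i] / p_yhat) * (p_x[j] / p_xhat)
      } else 0
    }
  }
  q
}

# Global ITCC optimum by enumerating every (row, column) assignment combo.
brute_itcc_optimum <- function(M, k, l) {
  p <- M / sum(M)
  n <- nrow(M); m <- ncol(M)
  row_assigns <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  col_assigns <- as.matrix(expand.grid(rep(list(seq_len(l)), m)))
  best <- Inf
  for (ri in seq_len(nrow(row_assigns))) {
    for (ci in seq_len(nrow(col_assigns))) {
      obj <- brute_kl(p, brute_q(p, row_assigns[ri, ], col_assigns[ci, ]))
      if (obj < best) best <- obj
    }
  }
  best
}

# Mutual information I(X; Y) from the joint, computed from marginals only.
brute_mutual_information <- function(M) {
  p <- M / sum(M)
  p_y <- rowSums(p); p_x <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (p_y[i] * p_x[j]))
    }
  }
  s
}

# Pairwise concordance AUC, counting every positive/negative pair.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Minimax linkage by exhaustively re-evaluating every candidate merge and
# prototype at every step.
brute_minimax <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  protos <- integer(0)
  merged_members <- list()
  while (length(clusters) > 1) {
    best <- list(cost = Inf)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        pts <- c(clusters[[a]], clusters[[b]])
        radii <- vapply(pts, function(p) max(D[p, pts]), 0)
        i <- which.min(radii)
        if (radii[i] < best$cost) {
          best <- list(cost = radii[i], proto = pts[i], a = a, b = b, pts = pts)
        }
      }
    }
    heights <- c(heights, best$cost)
    protos <- c(protos, best$proto)
    merged_members <- c(merged_members, list(sort(best$pts)))
    clusters[[best$a]] <- best$pts
    clusters[[best$b]] <- NULL
  }
  list(heights = heights, prototypes = protos, members = merged_members)
}

# Spearman distance via explicit ranking then Pearson correlation.
brute_spearman_distance <- function(C) {
  n <- nrow(C)
  R <- t(apply(C, 1, rank))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- 1 - stats::cor(R[i, ], R[j, ])
    }
  }
  d
}

# Members of each cluster of an ebc_protoclust merge step, as sorted leaf ids.
tree_step_members <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    get <- function(child) {
      if (child < 0) -child else members[[child]]
    }
    members[[s]] <- sort(c(get(tree$merge[s, 1]), get(tree$merge[s, 2])))
  }
  members
}

# Small deterministic random binary matrix without all-zero rows/columns.
random_binary_matrix <- function(n, m, density = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    M <- matrix(rbinom(n * m, 1, density), n, m)
    if (all(rowSums(M) > 0) && all(colSums(M) > 0)) return(M)
  }
}

# Wrap a plain binary matrix as an ebc_matrix with generic labels.
as_ebc <- function(M) {
  ebc_matrix(
    M,
    tibble::tibble(drug = paste0("d", seq_len(nrow(M))), gene = "g",
                   occurrences = rowSums(M)),
    tibble::tibble(path = paste0("p", seq_len(ncol(M))),
                   occurrences = colSums(M))
  )
}
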