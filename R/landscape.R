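#' Spearman correlation distance between co-clustering profiles
#'
#' Each row of the co-clustering count matrix `C` describes how one entity
#' pair ranks all others by co-clustering frequency. The distance between two
#' pairs is `1 - rho`, where `rho` is the Spearman correlation of their full
#' `C` rows (self columns included, average ranks for ties). Like the rank-sum
#' score, this is insensitive to each row's baseline promiscuity.
#'
#' @param cocluster An `ebc_cocluster` from [run_ensemble()] with at least 3
#'   rows.
#' @return A symmetric distance matrix with zero diagonal and entries in
#'   `[0, 2]`.
#' @export
cocluster_distance <- function(cocluster) {
  stopifnot(inherits(cocluster, "ebc_cocluster"))
  C <- cocluster$counts
  if (nrow(C) < 3) {
    stop_ebclust("At least 3 rows are needed for Spearman distances.",
                 "ebclust_bad_argument")
  }
  vars <- apply(C, 1, function(r) length(unique(r)) > 1)
  if (any(!vars)) {
    stop_ebclust(sprintf("Constant co-clustering row(s): %s",
                         paste(head(cocluster$labels[!vars], 3), collapse = ", ")),
                 "ebclust_constant_row")
  }
  rho <- cor(t(C), method = "spearman")
  d <- 1 - rho
  d[d < 0] <- 0            # clamp tiny negative round-off on the diagonal
  diag(d) <- 0
  dimnames(d) <- list(cocluster$labels, cocluster$labels)
  d
}

#' Minimax-linkage hierarchical clustering with prototypes
#'
#' Agglomerative clustering in which the cost of merging two clusters is the
#' minimax radius of their union: the smallest, over candidate prototype
#' points `p` in the union, of the maximum distance from `p` to any member.
#' At each step the pair with the smallest merge cost is joined and the
#' minimising prototype recorded, so every internal node has a representative
#' leaf whose distance to all members is at most the node height.
#'
#' @param D Symmetric distance matrix (zero diagonal), with dimnames as leaf
#'   labels.
#' @return An object of class `ebc_protoclust`: list with hclust-style
#'   `merge` (n-1 x 2, negative = leaf), `height`, `labels`, `order`, and
#'   `prototypes` (leaf index attaining the minimax radius of each merge).
#' @export
minimax_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n >= 2, isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  labels <- rownames(D) %||% as.character(seq_len(n))

  members <- as.list(seq_len(n))       # leaf indices per active cluster
  node_id <- -seq_len(n)               # hclust convention: negative leaves
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  prototypes <- integer(n - 1)

  # cost[a, b] = minimax radius of union; proto[a, b] = minimising leaf
  pair_cost <- function(a, b) {
    pts <- c(members[[a]], members[[b]])
    radii <- apply(D[pts, pts, drop = FALSE], 1, max)
    i <- which.min(radii)
    list(cost = radii[i], proto = pts[i])
  }

  active <- seq_len(n)
  cost <- matrix(Inf, n, n)
  proto <- matrix(NA_integer_, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      cost[a, b] <- D[a, b]
      proto[a, b] <- a  # either endpoint attains the radius for two leaves
    }
  }

  for (step in seq_len(n - 1)) {
    sub <- cost[active, active, drop = FALSE]
    flat <- which.min(sub)
    ai <- (flat - 1) %% length(active) + 1
    bi <- (flat - 1) %/% length(active) + 1
    a <- active[min(ai, bi)]; b <- active[max(ai, bi)]
    merge[step, ] <- c(node_id[a], node_id[b])
    height[step] <- cost[a, b]
    prototypes[step] <- proto[a, b]

    members[[a]] <- c(members[[a]], members[[b]])
    node_id[a] <- step
    active <- setdiff(active, b)
    for (o in setdiff(active, a)) {
      pc <- pair_cost(a, o)
      cost[min(a, o), max(a, o)] <- pc$cost
      proto[min(a, o), max(a, o)] <- pc$proto
    }
    cost[b, ] <- Inf; cost[, b] <- Inf
  }

  tree <- structure(
    list(merge = merge, height = height, labels = labels,
         prototypes = prototypes,
         method = "minimax", dist.method = "user"),
    class = "ebc_protoclust"
  )
  tree$order <- tree_leaf_order(merge, n)
  tree
}

# Left-to-right leaf order from the merge table (for plotting / hclust).
tree_leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' @export
print.ebc_protoclust <- function(x, ...) {
  cat(sprintf("<ebc_protoclust> minimax-linkage tree over %d leaves; height range [%.4g, %.4g]\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.ebc_protoclust <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = "minimax", call = match.call(),
         dist.method = x$dist.method),
    class = "hclust"
  )
}

#' Cut a linkage tree at a height
#'
#' Clusters are the connected components that remain after removing all merges
#' strictly above `height` (merges at exactly the cut height are kept).
#' Cluster ids are assigned in leaf order.
#'
#' @param tree An `ebc_protoclust`.
#' @param height Non-negative cut height.
#' @return Named integer vector of cluster memberships (names = leaf labels).
#' @export
cut_tree <- function(tree, height) {
  stopifnot(inherits(tree, "ebc_protoclust"), height >= 0)
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_rep <- integer(n - 1)
  for (s in seq_len(n - 1)) {
    reps <- vapply(tree$merge[s, ], function(child) {
      if (child < 0) -child else node_rep[child]
    }, 0L)
    if (tree$height[s] <= height) {
      parent[find(reps[1])] <- find(reps[2])
    }
    node_rep[s] <- find(reps[1]) # representative even if not united (arbitrary)
  }
  comp <- vapply(seq_len(n), find, 0L)
  ids <- setNames(seq_along(unique(comp[tree$order])), unique(comp[tree$order]))
  setNames(as.integer(ids[as.character(comp)]), tree$labels)
}

#' Label enrichment of tree-cut clusters
#'
#' For each cluster, the percentage of members carrying each label (for
#' example known pharmacogenomic or drug-target relationships), to one
#' decimal.
#'
#' @param assignment Named cluster membership vector from [cut_tree()].
#' @param label_sets Named list of character vectors of labelled leaf names.
#' @return A tibble with `cluster`, `size`, and one `pct_<name>` column per
#'   label set.
#' @export
cluster_enrichment <- function(assignment, label_sets) {
  stopifnot(is.list(label_sets), !is.null(names(label_sets)))
  base <- tibble(leaf = names(assignment), cluster = as.integer(assignment))
  out <- base |>
    dplyr::summarise(size = dplyr::n(), .by = "cluster") |>
    dplyr::arrange(.data$cluster)
  for (nm in names(label_sets)) {
    hits <- base |>
      dplyr::mutate(hit = .data$leaf %in% label_sets[[nm]]) |>
      dplyr::summarise(pct = round(100 * mean(.data$hit), 1), .by = "cluster")
    out[[paste0("pct_", nm)]] <- hits$pct[match(out$cluster, hits$cluster)]
  }
  out
}

#' Compare two clusters' values by the Mann-Whitney test
#'
#' Reports both medians and the two-sided Mann-Whitney (Wilcoxon rank-sum)
#' p-value: exact when both samples have at most 8 untied observations,
#' normal approximation otherwise.
#'
#' @param values_a,values_b Non-empty numeric vectors (for example the corpus
#'   co-occurrence counts of the pairs in two clusters).
#' @return A one-row tibble with `median_a`, `median_b`, `statistic` (U for
#'   sample a), `p_value`.
#' @export
compare_cluster_values <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop_ebclust("Both samples must be non-empty.", "ebclust_bad_argument")
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = !exact)
  )
  tibble(
    median_a = median(values_a),
    median_b = median(values_b),
    statistic = unname(wt$statistic),
    p_value = wt$p.value
  )
}

#' Export a linkage tree as a Newick string
#'
#' Ultrametric convention: the root sits at the final merge height and branch
#' lengths are differences between merge heights (leaves at height 0). Leaf
#' labels are sanitised for Newick (whitespace and reserved punctuation become
#' underscores). Two leaves merged at height 1 give `"(A:1,B:1);"`.
#'
#' @param tree An `ebc_protoclust`.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "ebc_protoclust"))
  labels <- gsub("[][:space:],;:()[]+", "_", tree$labels)
  n <- length(labels)
  node_str <- character(n - 1)
  for (s in seq_len(n - 1)) {
    part <- vapply(tree$merge[s, ], function(child) {
      if (child < 0) {
        sprintf("%s:%s", labels[-child], format(tree$height[s], digits = 15))
      } else {
        sprintf("%s:%s", node_str[child],
                format(tree$height[s] - tree$height[child], digits = 15))
      }
    }, "")
    node_str[s] <- sprintf("(%s)", paste(part, collapse = ","))
  }
  out <- paste0(node_str[n - 1], ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Full landscape pipeline from co-clustering counts
#'
#' Convenience wrapper: Spearman distance, minimax linkage, optional tree
#' cuts and label enrichment.
#'
#' @param cocluster An `ebc_cocluster`.
#' @param cut_heights Optional numeric vector of cut heights.
#' @param label_sets Optional named list of labelled leaf names for
#'   enrichment.
#' @return A list with `distance`, `tree`, and (when requested) `cuts` (named
#'   list of assignments) and `enrichment` (named list of tibbles).
#' @export
landscape <- function(cocluster, cut_heights = NULL, label_sets = NULL) {
  d <- cocluster_distance(cocluster)
  tree <- minimax_linkage(d)
  out <- list(distance = d, tree = tree)
  if (!is.null(cut_heights)) {
    out$cuts <- lapply(setNames(cut_heights, cut_heights),
                       function(h) cut_tree(tree, h))
    if (!is.null(label_sets)) {
      out$enrichment <- lapply(out$cuts, cluster_enrichment, label_sets = label_sets)
    }
  }
  out
}
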