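make_counts <- function(C, labels = paste0("r", seq_len(nrow(C))), N = 100L) {
  dimnames(C) <- list(labels, labels)
  structure(list(counts = C, N = N, axis = "rows", labels = labels),
            class = "ebc_cocluster")
}

test_that("Spearman distance: identical rows give 0, reversed rank order gives 2", {
  C <- rbind(c(5, 1, 2, 3, 4),
             c(5, 1, 2, 3, 4),
             c(1, 5, 4, 3, 2),
             c(2, 3, 1, 5, 4),
             c(4, 2, 5, 1, 3))
  d <- cocluster_distance(make_counts(C))
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 2)   # exactly reversed ranks
  expect_equal(diag(d), rep(0, 5), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("Spearman distance matches rank-then-Pearson brute force with ties", {
  set.seed(41)
  C <- matrix(sample(0:10, 25, TRUE), 5, 5)
  C <- C + t(C); diag(C) <- 50L
  d <- cocluster_distance(make_counts(C))
  expect_equal(unname(d), brute_spearman_distance(C), tolerance = 1e-12)

  Cc <- C; Cc[2, ] <- 7L; Cc[, 2] <- 7L; Cc[2, 2] <- 7L
  expect_error(cocluster_distance(make_counts(Cc)),
               class = "ebclust_constant_row", regexp = "r2")
})

test_that("minimax linkage handles two leaves and the 1-D {0,1,10} example", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- minimax_linkage(D2)
  expect_equal(t2$height, 3)
  expect_true(t2$prototypes %in% 1:2)

  pts <- c(0, 1, 10)
  D3 <- abs(outer(pts, pts, "-"))
  dimnames(D3) <- list(c("x0", "x1", "x10"), c("x0", "x1", "x10"))
  t3 <- minimax_linkage(D3)
  # first merge {0,1} at height 1; final merge at height 9 with prototype 1
  expect_equal(t3$height, c(1, 9))
  expect_equal(tree_step_members(t3)[[1]], c(1, 2))
  expect_equal(t3$prototypes[2], 2)   # the point at coordinate 1
})

test_that("minimax linkage matches the exhaustive brute force on random matrices", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    X <- matrix(runif(n * 2), n, 2)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    got <- minimax_linkage(D)
    want <- brute_minimax(D)
    expect_equal(got$height, want$heights)
    expect_equal(tree_step_members(got), want$members)
    expect_equal(got$prototypes, want$prototypes)
  }
})

test_that("minimax heights are non-decreasing and prototypes attain the minimal radius", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 9
    D <- as.matrix(dist(matrix(runif(n * 3), n, 3)))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    tr <- minimax_linkage(D)
    expect_true(all(diff(tr$height) >= -1e-12))
    members <- tree_step_members(tr)
    for (s in seq_along(members)) {
      pts <- members[[s]]
      radii <- vapply(pts, function(p) max(D[p, pts]), 0)
      expect_equal(max(D[tr$prototypes[s], pts]), min(radii))
    }
  }
})

test_that("tree cuts yield components below the height, and every count with distinct heights", {
  pts <- c(0, 1, 10)
  D3 <- abs(outer(pts, pts, "-"))
  dimnames(D3) <- list(c("x0", "x1", "x10"), c("x0", "x1", "x10"))
  t3 <- minimax_linkage(D3)
  cut5 <- cut_tree(t3, 5)
  expect_equal(unname(cut5[c("x0", "x1")]), c(1, 1))
  expect_equal(length(unique(cut5)), 2)
  expect_equal(length(unique(cut_tree(t3, 9))), 1)    # >= final merge height
  expect_equal(length(unique(cut_tree(t3, 0.5))), 3)  # below first merge

  set.seed(44)
  D <- as.matrix(dist(matrix(runif(14), 7, 2)))
  dimnames(D) <- list(paste0("p", 1:7), paste0("p", 1:7))
  tr <- minimax_linkage(D)
  counts <- vapply(tr$height, function(h) length(unique(cut_tree(tr, h))), 0L)
  expect_equal(sort(c(counts, 7)), 1:7)   # each internal height + singletons
})

test_that("cluster enrichment reports one-decimal label percentages", {
  assign <- setNames(c(1, 1, 1, 1, 2, 2, 2), paste0("r", 1:7))
  enr <- cluster_enrichment(assign, list(
    pgx = c("r1"),                 # 1 of 4 -> 25.0
    target = c("r5", "r6", "r7")   # cluster 2 fully labelled
  ))
  expect_equal(enr$size, c(4, 3))
  expect_equal(enr$pct_pgx, c(25.0, 0.0))
  expect_equal(enr$pct_target, c(0.0, 100.0))
})

test_that("Mann-Whitney comparison: exact p for small samples, medians by sorting", {
  res <- compare_cluster_values(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$median_a, 2)
  expect_equal(res$median_b, 11)
  expect_equal(res$statistic, 0)     # U = 0: complete separation
  expect_equal(res$p_value, 0.1)     # exact: 2 / choose(6, 3)

  same <- compare_cluster_values(1:30, 1:30)
  expect_gt(same$p_value, 0.95)
  expect_error(compare_cluster_values(numeric(0), 1),
               class = "ebclust_bad_argument")
})

test_that("Newick export uses ultrametric branch lengths and round-trips through ape", {
  D2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  nwk <- to_newick(minimax_linkage(D2))
  expect_equal(nwk, "(A:1,B:1);")

  pts <- c(0, 1, 10)
  D3 <- abs(outer(pts, pts, "-"))
  dimnames(D3) <- list(c("x0", "x1", "x10"), c("x0", "x1", "x10"))
  t3 <- minimax_linkage(D3)
  phy <- ape::read.tree(text = to_newick(t3))
  expect_setequal(phy$tip.label, c("x0", "x1", "x10"))
  # leaf depths: x0 and x1 sit under the height-1 node, 8 below the root
  depths <- ape::node.depth.edgelength(phy)[1:3]
  expect_equal(unname(depths), c(9, 9, 9)[seq_along(depths)])

  set.seed(45)
  D <- as.matrix(dist(matrix(runif(16), 8, 2)))
  dimnames(D) <- list(paste0("leaf ", 1:8), paste0("leaf ", 1:8))
  tr <- minimax_linkage(D)
  phy <- ape::read.tree(text = to_newick(tr))
  expect_setequal(phy$tip.label, paste0("leaf_", 1:8))  # sanitised labels
})

test_that("the landscape wrapper ties distance, tree, cuts and enrichment together", {
  spec <- planted_spec(row_sizes = c(6, 6), col_sizes = c(5, 5),
                       p_in = 0.95, p_out = 0.05, seed = 46)
  pm <- planted_matrix(spec)
  cc <- run_ensemble(pm$matrix, 2, 2, N = 30, base_seed = 1)
  ls <- landscape(cc, cut_heights = c(0.5),
                  label_sets = list(block1 = names(pm$row_blocks)[pm$row_blocks == 1]))
  expect_s3_class(ls$tree, "ebc_protoclust")
  expect_equal(length(ls$cuts), 1)
  expect_true(all(c("cluster", "size", "pct_block1") %in%
                    names(ls$enrichment[[1]])))
})
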