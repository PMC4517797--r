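test_that("normalisation yields a joint distribution consistent with brute-force marginals", {
  j <- normalize_joint(matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE))
  expect_equal(sum(j$p), 1)
  expect_equal(unique(j$p[j$p > 0]), 1 / 3)

  single <- normalize_joint(matrix(c(0, 0, 1, 0), 2, 2))
  expect_equal(max(single$p), 1)

  M <- random_binary_matrix(10, 10, 0.4, seed = 5)
  j <- normalize_joint(M)
  expect_equal(sum(j$p), 1)
  for (i in 1:10) expect_equal(j$p_y[i], sum(M[i, ]) / sum(M))

  expect_error(normalize_joint(matrix(0, 2, 2)), class = "ebclust_empty_matrix")
})

test_that("q reduces to p for singleton clusters and to independence for k=l=1", {
  M <- random_binary_matrix(5, 4, 0.5, seed = 2)
  j <- normalize_joint(M)
  q_id <- compute_q(j, seq_len(5), seq_len(4), 5, 4)
  expect_equal(q_id, j$p, ignore_attr = TRUE)

  q_ind <- compute_q(j, rep(1L, 5), rep(1L, 4), 1, 1)
  expect_equal(q_ind, outer(j$p_y, j$p_x), ignore_attr = TRUE)
})

test_that("q matches hand-expansion of the three factors, preserving marginals and block masses", {
  M <- random_binary_matrix(3, 3, 0.6, seed = 9)
  j <- normalize_joint(M)
  ra <- c(1L, 1L, 2L); ca <- c(1L, 2L, 2L)   # 2+1 / 1+2 assignment
  q <- compute_q(j, ra, ca, 2, 2)
  expect_equal(q, brute_q(j$p, ra, ca), ignore_attr = TRUE)
  expect_equal(rowSums(q), j$p_y, ignore_attr = TRUE)
  expect_equal(colSums(q), j$p_x, ignore_attr = TRUE)
  for (rb in 1:2) for (cb in 1:2) {
    expect_equal(sum(q[ra == rb, ca == cb]), sum(j$p[ra == rb, ca == cb]))
  }
})

test_that("marginal conservation holds for random assignments to 1e-12", {
  set.seed(21)
  for (rep in 1:20) {
    M <- random_binary_matrix(8, 6, 0.4, seed = 100 + rep)
    j <- normalize_joint(M)
    k <- sample(1:8, 1); l <- sample(1:6, 1)
    q <- compute_q(j, sample(k, 8, TRUE), sample(l, 6, TRUE), k, l)
    expect_lt(max(abs(rowSums(q) - j$p_y)), 1e-12)
    expect_lt(max(abs(colSums(q) - j$p_x)), 1e-12)
  }
})

test_that("KL objective: zero at q = p, ln 2 on the uniform diagonal at k=l=1, brute force otherwise", {
  j <- normalize_joint(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(kl_objective(j, j$p), 0)
  q1 <- compute_q(j, c(1L, 1L), c(1L, 1L), 1, 1)
  expect_equal(kl_objective(j, q1), log(2))
  # ... which equals the mutual information computed from marginals
  expect_equal(kl_objective(j, q1), brute_mutual_information(diag(2)))

  set.seed(4)
  M <- random_binary_matrix(6, 6, 0.5, seed = 4)
  j <- normalize_joint(M)
  ra <- sample(2, 6, TRUE); ca <- sample(3, 6, TRUE)
  q <- compute_q(j, ra, ca, 2, 3)
  expect_equal(kl_objective(j, q), brute_kl(j$p, q))
})

test_that("ITCC recovers exact block structure with objective zero", {
  M <- kronecker(diag(2), matrix(1, 2, 2))   # 4x4 two-block diagonal
  recovered <- FALSE
  for (s in 1:20) {
    fit <- itcc(M, 2, 2, seed = s)
    if (fit$objective < 1e-12) {
      recovered <- TRUE
      expect_equal(length(unique(fit$row_assign[1:2])), 1)
      expect_equal(length(unique(fit$row_assign[3:4])), 1)
      expect_false(fit$row_assign[1] == fit$row_assign[3])
    }
  }
  expect_true(recovered)
})

test_that("best-of-restarts reaches the enumerated global optimum on 4x4 instances", {
  for (ms in 1:3) {
    M <- random_binary_matrix(4, 4, 0.5, seed = 40 + ms)
    target <- brute_itcc_optimum(M, 2, 2)
    best <- min(vapply(1:20, function(s) itcc(M, 2, 2, seed = s)$objective, 0))
    expect_equal(best, target, tolerance = 1e-10)
  }
})

test_that("objective trace is monotone non-increasing on random matrices", {
  set.seed(99)
  for (rep in 1:100) {
    M <- random_binary_matrix(10, 10, 0.35, seed = 1000 + rep)
    fit <- itcc(M, sample(2:4, 1), sample(2:4, 1), seed = rep)
    tr <- fit$trace[is.finite(fit$trace)]
    expect_true(all(diff(tr) <= 1e-12))
    expect_gte(fit$objective, 0)
  }
})

test_that("analytic limits: objective 0 at k=n,l=m and I(X;Y) at k=1,l=1", {
  M <- random_binary_matrix(7, 5, 0.5, seed = 17)
  expect_lt(itcc(M, 7, 5, seed = 1)$objective, 1e-12)
  expect_equal(itcc(M, 1, 1, seed = 1)$objective,
               brute_mutual_information(M), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical biclusterings", {
  M <- random_binary_matrix(12, 9, 0.3, seed = 8)
  a <- itcc(M, 3, 3, seed = 123)
  b <- itcc(M, 3, 3, seed = 123)
  expect_identical(a[c("row_assign", "col_assign", "objective", "trace")],
                   b[c("row_assign", "col_assign", "objective", "trace")])
  expect_error(itcc(M, 0, 3), class = "ebclust_bad_argument")
  expect_error(itcc(M, 3, 100), class = "ebclust_bad_argument")
})

test_that("smoothed matrix preserves totals, row sums, and the hand-computed q", {
  M <- random_binary_matrix(6, 6, 0.5, seed = 33)
  fit <- itcc(M, 2, 2, seed = 1)
  sm <- smoothed_matrix(M, fit)
  expect_equal(sum(sm), sum(M))
  expect_equal(rowSums(sm), rowSums(M), ignore_attr = TRUE)
  expect_equal(colSums(sm), colSums(M), ignore_attr = TRUE)

  # perfect block structure: smoothing returns the original matrix
  B <- kronecker(diag(2), matrix(1, 2, 3))
  fitB <- NULL
  for (s in 1:20) {
    fitB <- itcc(B, 2, 2, seed = s)
    if (fitB$objective < 1e-12) break
  }
  expect_equal(smoothed_matrix(B, fitB), B, ignore_attr = TRUE)

  # scaled q from the hand-computed 3x3 case
  M3 <- random_binary_matrix(3, 3, 0.6, seed = 9)
  j3 <- normalize_joint(M3)
  fit3 <- itcc(M3, 2, 2, seed = 5)
  expect_equal(smoothed_matrix(M3, fit3),
               brute_q(j3$p, fit3$row_assign, fit3$col_assign) * sum(M3),
               ignore_attr = TRUE)
})

test_that("choose_kl selects planted block numbers and degenerate grids", {
  B <- kronecker(diag(2), matrix(1, 3, 3))  # clean 2x2 blocks, 6x6
  sel <- choose_kl(B, 1:3, 1:3, restarts = 8, seed = 2)
  expect_equal(c(sel$k, sel$l), c(2, 2))
  # KL is zero at (2,2) and positive whenever either number is 1
  tab <- sel$table
  expect_lt(tab$objective[tab$k == 2 & tab$l == 2], 1e-12)
  expect_gt(min(tab$objective[tab$k == 1 | tab$l == 1]), 0.1)

  single <- choose_kl(B, 6, 6, restarts = 1, seed = 1)
  expect_equal(c(single$k, single$l), c(6, 6))
  expect_error(choose_kl(B, integer(0), 1:2), class = "ebclust_bad_argument")
})

test_that("tidy and glance summarise a biclustering", {
  M <- as_ebc(random_binary_matrix(5, 4, 0.5, seed = 3))
  fit <- itcc(M, 2, 2, seed = 7)
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  expect_setequal(unique(td$axis), c("row", "column"))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_true(gl$objective >= 0)
})
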