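# A fixed co-clustering counts object over four labelled rows where
# C(., T1) = (N, 10, 5, 1): ranks are T1:4, a:3, b:2, c:1.
toy_counts <- function() {
  C <- matrix(c(
    20, 10, 5, 1,
    10, 20, 2, 2,
    5, 2, 20, 3,
    1, 2, 3, 20
  ), 4, 4, byrow = TRUE)
  labels <- c("T1", "a", "b", "c")
  dimnames(C) <- list(labels, labels)
  structure(list(counts = C, N = 20L, axis = "rows", labels = labels),
            class = "ebc_cocluster")
}

test_that("the rank-sum score follows the printed formula on a hand example", {
  cc <- toy_counts()
  # S = {a, c}: ranks 3 and 1 -> score 4
  expect_equal(ebc_score(cc, S = c("a", "c"), candidate = "T1"), 4)
  # the candidate occupies the top rank but contributes nothing
  expect_equal(ebc_score(cc, S = c("a", "b", "c"), candidate = "T1"), 6)
})

test_that("seed-set and membership contracts are enforced", {
  cc <- toy_counts()
  expect_error(ebc_score(cc, character(0), "T1"),
               class = "ebclust_empty_seed_set")
  expect_error(ebc_score(cc, c("a", "T1"), "T1"),
               class = "ebclust_bad_argument")
  expect_error(ebc_score(cc, "nope", "T1"), class = "ebclust_unknown_label")
})

test_that("tied co-clustering values give the expected mean score over permutations", {
  n <- 5
  C <- matrix(3L, n, n); diag(C) <- 10L
  labels <- paste0("r", 1:n)
  dimnames(C) <- list(labels, labels)
  cc <- structure(list(counts = C, N = 10L, axis = "rows", labels = labels),
                  class = "ebc_cocluster")
  S <- c("r2", "r3")
  scores <- vapply(1:2000, function(s) ebc_score(cc, S, "r1", tie_seed = s), 0)
  # all non-self rows tie: expected score = |S| * mean(1..n-1)
  expect_equal(mean(scores), 2 * mean(1:(n - 1)), tolerance = 0.02)
  # same tie seed -> identical score
  expect_identical(ebc_score(cc, S, "r1", tie_seed = 7),
                   ebc_score(cc, S, "r1", tie_seed = 7))
})

test_that("rank-sum score is invariant under strictly monotone transforms of C", {
  cc <- toy_counts()
  cc2 <- cc
  cc2$counts <- cc$counts^3 + 1   # strictly monotone on non-negative counts
  for (S in list("a", c("a", "c"), c("b", "c"))) {
    expect_equal(ebc_score(cc, S, "T1", tie_seed = 1),
                 ebc_score(cc2, S, "T1", tie_seed = 1))
  }
})

test_that("rank-sum bounds hold for every seed-set size", {
  set.seed(31)
  n <- 9
  C <- matrix(sample(0:49, n * n, TRUE), n, n)
  C <- C + t(C); diag(C) <- 100L
  labels <- paste0("r", 1:n)
  dimnames(C) <- list(labels, labels)
  cc <- structure(list(counts = C, N = 100L, axis = "rows", labels = labels),
                  class = "ebc_cocluster")
  for (s in 1:5) {
    S <- labels[1 + seq_len(s)]
    sc <- ebc_score(cc, S, "r1", tie_seed = s)
    expect_gte(sc, s * (s + 1) / 2)
    expect_lte(sc, sum((n - s):(n - 1)))  # top s ranks below the candidate's n
  }
})

test_that("average cosine matches identity, twin, and brute-force cases", {
  M <- rbind(ti = c(1, 0, 0), s1 = c(1, 0, 0), s2 = c(0, 1, 0))
  expect_equal(avg_cosine_score(M, c("s1", "s2"), "ti"), 0.5)
  expect_equal(avg_cosine_score(M, "s1", "ti"), 1.0)

  R <- random_binary_matrix(8, 6, 0.5, seed = 12)
  rownames(R) <- paste0("r", 1:8)
  S <- c("r2", "r5", "r7")
  got <- avg_cosine_score(R, S, "r1")
  manual <- mean(vapply(S, function(s) {
    sum(R["r1", ] * R[s, ]) / sqrt(sum(R["r1", ]^2) * sum(R[s, ]^2))
  }, 0))
  expect_equal(got, manual)
  expect_gte(got, 0); expect_lte(got, 1)
})

test_that("rank-sum-cosine ranks by cosine and errors on empty seeds", {
  # cosines to ti: (1, .9, .5, .1) by construction of near-duplicates
  M <- rbind(
    ti = c(10, 0, 0),
    a = c(9, 4, 0),     # high cosine
    b = c(5, 8, 0),     # middling
    c = c(1, 10, 3)     # low
  )
  expect_equal(ranksum_cosine_score(M, S = c("a", "b"), "ti"), 3 + 2)
  expect_error(ranksum_cosine_score(M, character(0), "ti"),
               class = "ebclust_empty_seed_set")
})

test_that("rank-sum-cosine equals EBC score when orderings coincide", {
  # counts ordered exactly like the cosine similarities above
  M <- rbind(ti = c(10, 0, 0), a = c(9, 4, 0), b = c(5, 8, 0), c = c(1, 10, 3))
  C <- matrix(0L, 4, 4)
  sims <- as.vector(M %*% M["ti", ]) / sqrt(rowSums(M^2) * sum(M["ti", ]^2))
  C[, 1] <- C[1, ] <- as.integer(round(100 * sims))
  diag(C) <- 100L
  dimnames(C) <- list(rownames(M), rownames(M))
  cc <- structure(list(counts = C, N = 100L, axis = "rows",
                       labels = rownames(M)), class = "ebc_cocluster")
  S <- c("a", "c")
  expect_equal(ebc_score(cc, S, "ti", tie_seed = 2),
               ranksum_cosine_score(M, S, "ti", tie_seed = 2))
})

test_that("LSA embeddings reproduce cosines at full rank and Gram matrices at low rank", {
  M <- random_binary_matrix(10, 8, 0.4, seed = 21)
  rownames(M) <- paste0("r", 1:10)

  full <- lsa_embed(M, 8)
  cos <- function(A) {
    nrm <- sqrt(rowSums(A^2))
    (A %*% t(A)) / outer(nrm, nrm)
  }
  expect_equal(cos(full), cos(M), tolerance = 1e-10, ignore_attr = TRUE)

  # rank-1 outer-product matrix is reconstructed exactly at r = 1
  O <- outer(c(1, 1, 0, 1), c(0, 1, 1)); rownames(O) <- paste0("r", 1:4)
  e1 <- lsa_embed(O, 1)
  expect_equal(e1 %*% t(e1), O %*% t(O), tolerance = 1e-10, ignore_attr = TRUE)

  # rank-3 Gram matrix equals the truncated reconstruction's Gram matrix
  e3 <- lsa_embed(M, 3)
  sv <- svd(M)
  M3 <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  expect_equal(e3 %*% t(e3), M3 %*% t(M3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(lsa_embed(M, 99), class = "ebclust_bad_argument")
})

test_that("relative certainty is min-max normalised with the stated conventions", {
  expect_equal(relative_certainty(c(10, 5, 0)), c(1, 0.5, 0))
  expect_equal(relative_certainty(3), 1)
  expect_equal(relative_certainty(c(2, 2, 2)), c(1, 1, 1))
})

test_that("score_candidates returns a ranked table with certainty 1 at the top", {
  M <- random_binary_matrix(10, 8, 0.4, seed = 30)
  rownames(M) <- paste0("r", 1:10)
  em <- as_ebc(M)
  cc <- run_ensemble(em, 2, 2, N = 10, base_seed = 4)
  S <- rownames(em$M)[1:3]
  for (method in c("avgcos", "ranksum")) {
    tab <- score_candidates(em, S, method = method)
    expect_equal(nrow(tab), 7)
    expect_equal(tab$relative_certainty[1], 1)
    expect_false(any(tab$candidate %in% S))
  }
  tab <- score_candidates(em, S, method = "ebc", cocluster = cc)
  expect_equal(tab$method[1], "ebc")
  tab_lsa <- score_candidates(em, S, method = "lsa_avgcos", lsa_rank = 3)
  expect_equal(nrow(tab_lsa), 7)
  expect_error(score_candidates(em, S, method = "ebc"),
               class = "ebclust_bad_argument")
})
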