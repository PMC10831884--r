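test_that("adjusted Rand index matches hand-computed and degenerate cases", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1) # single block twice
  expect_error(adjusted_rand_index(1:4, 1:5), "length")
  expect_error(adjusted_rand_index(1, 1), "2 items")
})

test_that("ARI agrees with independent pair counting on all small partitions", {
  parts <- all_partitions(4L, 3L)
  for (a in parts) for (b in parts) {
    expect_equal(adjusted_rand_index(a, b), ari_pair_counting(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI agrees with an independent library implementation", {
  set.seed(41)
  for (i in 1:25) {
    a <- sample(1:4, 15, replace = TRUE)
    b <- sample(1:4, 15, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI is invariant to label permutation", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    perm <- sample(3)
    expect_equal(adjusted_rand_index(a, b),
                 adjusted_rand_index(perm[a], b), tolerance = 1e-12)
  }
})

sep_clusters <- function(n_per, k = 3L, d = 4L, seed = 1L, sd = 0.05) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d, sd = 5), k, d)
  x <- centers[rep(seq_len(k), each = n_per), ] +
    matrix(rnorm(k * n_per * d, sd = sd), k * n_per, d)
  x
}

test_that("identical or near-identical latent sets give ARI 1 per k", {
  x <- sep_clusters(20)
  cc <- compare_cluster_structure(x, x, k_values = 3L, seed = 2L)
  expect_equal(cc$ari_per_k$ari, 1)

  y <- x + matrix(rnorm(length(x), sd = 1e-6 * sd(x)), nrow(x))
  cc2 <- compare_cluster_structure(x, y, k_values = 3L, seed = 3L)
  expect_equal(cc2$ari_per_k$ari, 1)
})

test_that("independent (shuffled) latent sets give ARI near zero", {
  x <- sep_clusters(20, seed = 7)
  aris <- vapply(1:20, function(s) {
    y <- with_seed(s, x[sample(nrow(x)), ])
    compare_cluster_structure(x, y, k_values = 3L, n_restarts = 10L,
                              seed = s)$ari_per_k$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("cluster comparison validates its inputs", {
  x <- sep_clusters(4)
  expect_error(compare_cluster_structure(x, x[1:5, ]), "equal timepoint")
  expect_error(compare_cluster_structure(x, x, k_values = 50L), "exceeds")
})

test_that("k-NN matching scores hand-verifiable cases", {
  a <- rbind(c(0, 0), c(1, 0), c(0, 1))
  p <- rbind(c(0.1, 0), c(0.9, 0.2), c(0, 2))
  expect_equal(knn_match(a, p, k = 1L), 1)
  expect_equal(knn_match(a, a, k = 1L), 1)
  expect_error(knn_match(a, p, k = 3L), "smaller")
})

test_that("k-NN accuracy is monotone in k and saturates for distinct vectors", {
  set.seed(9)
  for (i in 1:5) {
    a <- matrix(rnorm(20 * 3), 20, 3)
    p <- a + matrix(rnorm(60, sd = 0.8), 20, 3)
    expect_gte(knn_match(a, p, 3L), knn_match(a, p, 1L))
    expect_equal(knn_match(a, p, 19L), 1)
  }
})

test_that("nearest training frame retrieval is exact and order-insensitive", {
  train <- rbind(c(0, 0), c(2, 0), c(0, 2))
  pred <- rbind(c(0.2, 0.1), c(1.8, 0.1), c(0.1, 1.7), c(1, 0)) # last is a tie
  idx <- nearest_train_frame(pred, train)
  expect_equal(idx[1:3], 1:3)
  expect_equal(idx[4], 1L) # equidistant to rows 1 and 2: lower index wins
  perm <- c(3, 1, 2)
  idx_p <- nearest_train_frame(pred[1:3, ], train[perm, ])
  expect_equal(train[perm, ][idx_p, ], train[idx[1:3], ], ignore_attr = TRUE)
})

test_that("label overlap matches closed-form hit probabilities for a known confusion", {
  classes <- c("circle", "square", "triangle", "face")
  C <- matrix(0.1, 4, 4, dimnames = list(classes, classes))
  diag(C) <- 0.7
  C["face", ] <- c(0.2, 0.05, 0.05, 0.7)
  n <- 1000L
  set.seed(31)
  truth <- sample(classes, n, replace = TRUE)
  test_rank <- with_seed(32, mock_label_ranker(C, "sample")(truth))
  match_rank <- mock_label_ranker(C, "sort")(truth)
  for (k in c(1L, 2L)) {
    got <- label_overlap(test_rank, match_rank, top_k = k)
    expected <- mean(vapply(classes, function(cl) {
      topk <- names(sort(C[cl, ], decreasing = TRUE))[seq_len(k)]
      sum(C[cl, topk])
    }, numeric(1))[truth])
    expect_equal(got, expected, tolerance = 0.03)
  }
})

test_that("label overlap handles identical and disjoint rankings", {
  r1 <- list(data.frame(label = c("a", "b"), score = c(0.9, 0.1)))
  r2 <- list(data.frame(label = c("c", "d"), score = c(0.8, 0.2)))
  expect_equal(label_overlap(r1, r1, 1L), 1)
  expect_equal(label_overlap(r1, r1, 2L), 1)
  expect_equal(label_overlap(r1, r2, 2L), 0)
  expect_error(label_overlap(r1, list(data.frame(label = character(0),
                                                 score = numeric(0)))),
               "empty ranking")
})

test_that("ROC endpoints and a perfect detector behave as counted", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  conf <- ifelse(truth, 0.9, 0.1)
  roc <- face_roc(conf, truth, threshold_grid = c(0, 0.5, 1))
  expect_equal(roc$points$fpr, c(1, 0, 0))
  expect_equal(roc$points$tpr, c(1, 1, 0))
  expect_equal(roc$points$accuracy[2], 1)
})

test_that("ROC is monotone non-increasing in the threshold", {
  set.seed(17)
  truth <- runif(200) < 0.4
  conf <- pmin(pmax(ifelse(truth, 0.7, 0.3) + rnorm(200, sd = 0.2), 0), 1)
  roc <- face_roc(conf, truth, threshold_grid = seq(0, 1, 0.05))
  expect_true(all(diff(roc$points$fpr) <= 1e-12))
  expect_true(all(diff(roc$points$tpr) <= 1e-12))
})

test_that("single-class truth degrades to accuracy with a warning", {
  expect_warning(roc <- face_roc(c(0.9, 0.8), c(TRUE, TRUE),
                                 threshold_grid = 0.5),
                 "single class")
  expect_true(is.na(roc$points$fpr))
  expect_equal(roc$points$accuracy, 1)
})

test_that("stage-triple thresholds follow the cascade convention", {
  conf <- rbind(c(0.9, 0.9, 0.9), c(0.9, 0.5, 0.9), c(0.2, 0.9, 0.9))
  truth <- c(TRUE, TRUE, FALSE)
  grid <- rbind(c(0.5, 0.6, 0.6), c(0.95, 0.95, 0.95))
  roc <- face_roc(conf, truth, grid)
  # frame 2 fails stage 2 at the default operating point; frame 3 fails stage 1
  expect_equal(roc$points$tpr, c(0.5, 0))
  expect_equal(roc$points$fpr, c(0, 0))
  expect_error(face_roc(conf, truth, threshold_grid = 0.5), "stages")
})
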