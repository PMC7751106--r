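test_that("fused KNN agrees with exhaustive enumeration over all K", {
  ## 1-D training points 0 (pos), 10 (neg), 11 (neg); query at 1.
  train <- matrix(c(0, 10, 11), ncol = 1)
  y <- c(1L, 0L, 0L)
  ## brute force: K=1 -> pos; K=2 -> {pos,neg} tie -> nearest (pos);
  ## K=3 -> {pos,neg,neg} -> neg; majority of (1,1,0) -> pos, score 2/3
  out <- knn_vote_predict(train, y, q = 1, k_max = 10L)
  expect_equal(out$label, 1L)
  expect_equal(out$score, 2 / 3)
  expect_error(knn_vote_predict(train[0, , drop = FALSE], integer(0), 1), "empty")
})

test_that("fused KNN matches the reference KNN when all sub-votes agree", {
  skip_if_not_installed("class")
  set.seed(21)
  X <- rbind(matrix(rnorm(40, 3), 20), matrix(rnorm(40, -3), 20))
  y <- rep(c(1L, 0L), each = 20)
  q <- matrix(rnorm(10, 3), 5)
  for (i in 1:5) {
    out <- knn_vote_predict(X, y, q[i, ])
    ref <- as.integer(as.character(class::knn(X, matrix(q[i, ], 1), factor(y), k = 1)))
    expect_equal(out$label, ref)
    expect_true(out$score %in% c(0, 1))
  }
})

test_that("a tied sub-vote fusion resolves to the K=1 decision", {
  ## query 0; neighbors 1 (pos), 2..4 (neg); K votes: pos, pos, neg, neg
  train <- matrix(1:4, ncol = 1)
  y <- c(1L, 0L, 0L, 0L)
  out <- knn_vote_predict(train, y, q = 0, k_max = 4L)
  expect_equal(out$score, 0.5)
  expect_equal(out$label, 1L) # K=1 label, not the raw majority of neighbors
  oet <- oetknn_fused_predict(train, y, q = 0, k_max = 4L, gamma = c(1, 1))
  expect_equal(oet$label, 1L)
})

test_that("evidential KNN handles degenerate and reinforcing neighborhoods", {
  expect_equal(oetknn_predict(matrix(1), 1L, q = 5, K = 1)$label, 1L)
  out <- oetknn_predict(matrix(c(1, 2), ncol = 1), c(1L, 1L), q = 0, K = 2,
                        gamma = c(1, 1))
  expect_equal(out$label, 1L)
  expect_gt(out$score, 0.5)
  expect_error(oetknn_predict(matrix(1), 1L, q = 0, K = 2), "K must")
  expect_error(oetknn_predict(matrix(1), 1L, q = 0, K = 0), "K must")
})

test_that("evidential KNN equals the brute-force Dempster oracle", {
  ## the fixed 3-neighbor case: (d, class) = (1, pos), (1, neg), (2, pos)
  train <- matrix(c(1, -1, 2), ncol = 1)
  y <- c(1L, 0L, 1L)
  out <- oetknn_predict(train, y, q = 0, K = 3, alpha0 = 0.95, gamma = c(1, 1))
  betp <- bf_dempster_pignistic(c(1L, 0L, 1L), c(1, 1, 4), 0.95, c(1, 1))
  expect_equal(out$score, betp, tolerance = 1e-9)
  expect_equal(out$label, as.integer(betp > 0.5))
  ## 200 random instances, K <= 4, exact focal-set enumeration
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(4:8, 1)
    K <- sample(1:4, 1)
    X <- matrix(rnorm(n * 3), n)
    y <- sample(0:1, n, replace = TRUE)
    q <- rnorm(3)
    g <- bf_gamma(X, y)
    out <- oetknn_predict(X, y, q, K, alpha0 = 0.95, gamma = g)
    d2 <- colSums((t(X) - q)^2)
    ord <- order(d2, seq_along(d2))[seq_len(K)]
    expect_equal(out$score,
                 bf_dempster_pignistic(y[ord], d2[ord], 0.95, g),
                 tolerance = 1e-9)
  }
})

test_that("the gamma heuristic matches its definition", {
  set.seed(31)
  X <- matrix(rnorm(30), 10)
  y <- sample(0:1, 10, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(memvote:::gamma_heuristic(as.matrix(dist(X))^2, y), bf_gamma(X, y),
               tolerance = 1e-12)
})

test_that("vacuous evidence falls back to the nearest neighbor", {
  ## as gamma grows the kernel mass alpha0 * exp(-gamma d^2) vanishes, every
  ## neighbor's mass function becomes vacuous, and the pignistic probability
  ## collapses to 1/2: the tie rule must then return the K=1 label
  set.seed(13)
  X <- matrix(rnorm(20), 10)
  y <- rep(c(0L, 1L), 5)
  for (i in 1:5) {
    q <- rnorm(2)
    out <- oetknn_predict(X, y, q, K = 5, gamma = c(1e14, 1e14))
    expect_equal(out$score, 0.5, tolerance = 1e-9)
    nearest <- y[which.min(colSums((t(X) - q)^2))]
    expect_equal(out$label, nearest)
  }
})

test_that("fused evidential KNN is the majority of its per-K sub-votes", {
  set.seed(19)
  X <- matrix(rnorm(36), 12)
  y <- rep(c(0L, 1L), 6)
  g <- bf_gamma(X, y)
  for (i in 1:10) {
    q <- rnorm(3)
    subs <- vapply(1:10, function(K) {
      oetknn_predict(X, y, q, K, gamma = g)$label
    }, integer(1))
    out <- oetknn_fused_predict(X, y, q, gamma = g)
    pos <- sum(subs)
    expected <- if (pos > 5) 1L else if (pos < 5) 0L else subs[1L]
    expect_equal(out$label, expected)
    expect_equal(out$score, mean(subs))
  }
})

test_that("predictions are invariant to training-set permutation", {
  set.seed(23)
  X <- matrix(rnorm(40), 20)   # continuous features: no distance ties
  y <- rep(c(0L, 1L), 10)
  perm <- sample(20)
  for (i in 1:5) {
    q <- rnorm(2)
    expect_equal(knn_vote_predict(X, y, q), knn_vote_predict(X[perm, ], y[perm], q))
    expect_equal(oetknn_predict(X, y, q, K = 4), oetknn_predict(X[perm, ], y[perm], q, K = 4))
  }
})

test_that("adapter classifiers fit and separate toy problems", {
  set.seed(41)
  X <- rbind(matrix(rnorm(60, 4), 30), matrix(rnorm(60, -4), 30))
  y <- rep(c(1L, 0L), each = 30)
  for (alg in c("svm", "rf", "gbm")) {
    clf <- fit_adapter(alg, X, y)
    p <- predict_classifier(clf, X)
    expect_equal(mean(p$label == y), 1)
    expect_true(all(p$score >= 0 & p$score <= 1))
    expect_gt(mean(p$score[y == 1]), mean(p$score[y == 0]))
  }
  expect_error(fit_adapter("svm", X, rep(1L, 60)), "both classes")
})

test_that("grid search selects by internal CV with smallest-value ties", {
  set.seed(43)
  X <- matrix(rnorm(80), 40)
  y <- as.integer(X[, 1] > 0)
  one <- fit_adapter("svm", X, y, hyper_grid = list(cost = 7))
  expect_equal(one$params$cost, 7)
  clf <- fit_adapter("rf", X, y, hyper_grid = list(mtry = c(1, 2)))
  expect_true(clf$params$mtry %in% c(1, 2))
})

test_that("RBF-SVM separates XOR-patterned data", {
  set.seed(47)
  X <- matrix(runif(200, -1, 1), 100)
  y <- as.integer(X[, 1] * X[, 2] > 0)
  clf <- fit_adapter("svm", X, y, hyper_grid = list(cost = c(1, 10), gamma = c(0.5, 2)))
  expect_gt(mean(predict_classifier(clf, X)$label == y), 0.9)
})

test_that("classifier banks enumerate members in declared order", {
  ds <- make_synth(6L, seed = 8L)
  b50 <- train_classifier_bank(ds, "oetknn", lambda_range = 0:4, per_K = FALSE)
  expect_equal(nrow(b50$members), 5L)
  expect_equal(b50$members$id[1:2], c("l0", "l1"))
  b500 <- train_classifier_bank(ds, "oetknn", lambda_range = 0:4, per_K = TRUE)
  expect_equal(nrow(b500$members), 50L)
  expect_equal(b500$members$id[1:11], c(sprintf("l0_k%d", 1:10), "l1_k1"))
  expect_error(train_classifier_bank(ds, "svm", 0:4, per_K = TRUE), "neighbour")
  empty <- ds; empty$records <- list(); empty$ids <- character(0)
  expect_error(train_classifier_bank(empty, "oetknn", 0:4), "empty")
})

test_that("lambda exceeding a sequence length is rejected by name", {
  recs <- list(random_record("long1", 80L, 1L), random_record("tiny", 55L, 2L))
  y <- c(long1 = 1L, tiny = 0L)
  profs <- list(
    long1 = profile_matrix("long1", matrix(rnorm(80 * 20), 80)),
    tiny = profile_matrix("tiny", matrix(rnorm(55 * 20), 55)))
  ds <- labeled_dataset(recs, y, profiles = profs)
  expect_error(train_classifier_bank(ds, "oetknn", lambda_range = 0:60), "tiny")
})

test_that("leave-one-out vote fast path equals naive per-fold refitting", {
  ds <- make_synth(15L, seed = 77L)
  y <- as.integer(ds$labels)
  for (method in c("knn", "oetknn")) {
    X <- encode_dataset(ds, "psepssm", lambda = 1L)
    fast <- memvote:::loocv_neighbor_votes(X, y, k_max = 5L, method = method)
    for (i in seq_len(nrow(X))) {
      for (K in 1:5) {
        naive <- if (method == "knn") {
          ord <- memvote:::neighbor_order(X[-i, , drop = FALSE], X[i, ])
          labs <- y[-i][ord]
          memvote:::majority01(labs[seq_len(K)], labs[1L])
        } else {
          oetknn_predict(X[-i, , drop = FALSE], y[-i], X[i, ], K)$label
        }
        expect_equal(fast$per_k[i, K], naive)
      }
    }
  }
})

test_that("bank vote matrices hold held-out votes for every member", {
  ds <- make_synth(8L, seed = 15L)
  bank <- train_classifier_bank(ds, "oetknn", lambda_range = 0:2, per_K = TRUE,
                                k_max = 10L)
  vm <- loocv_vote_matrix(bank)
  expect_identical(dim(vm), c(16L, 30L))
  expect_false(anyNA(vm))
  expect_identical(attr(vm, "y"), as.integer(ds$labels))
  bank_svm <- train_classifier_bank(ds, "svm", lambda_range = 0:1)
  vm2 <- loocv_vote_matrix(bank_svm)
  expect_identical(dim(vm2), c(16L, 2L))
  expect_true(all(vm2 %in% 0:1))
})

test_that("bank prediction votes for new proteins follow the members", {
  ds <- make_synth(10L, seed = 33L)
  bank <- train_classifier_bank(ds, "oetknn", lambda_range = 0:1, per_K = FALSE)
  newds <- make_synth(3L, seed = 99L)
  vm <- predict_bank(bank, newds)
  expect_identical(dim(vm), c(6L, 2L))
  expect_true(all(vm %in% 0:1))
  ## positives should mostly be recognized given the strong class signal
  expect_gt(mean(all_vote(vm) == as.integer(newds$labels)), 0.5)
})
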