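test_that("worked vote arithmetic: 4 of 7 neighbours give certainty 0.57", {
  # seven training points at increasing distance, 4 germinated among the 7
  x <- matrix(seq(1, 7), ncol = 1)
  y <- c(1, 1, 0, 1, 0, 1, 0)
  model <- knn_model(x, y, k = 7)
  pred <- predict(model, 0)
  expect_equal(pred$score, 4 / 7)
  expect_equal(round(pred$certainty, 2), 0.57)
  expect_equal(pred$label, 1L)
})

test_that("k = 1 on a training point returns its label with certainty 1", {
  set.seed(17)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0L, 1L), 10)
  model <- knn_model(x, y, k = 1)
  for (i in c(1, 7, 20)) {
    pred <- predict(model, x[i, ])
    expect_equal(pred$label, y[i])
    expect_equal(pred$certainty, 1)
  }
})

test_that("predictions match the brute-force all-distances oracle", {
  set.seed(23)
  for (instance in 1:20) {
    n <- sample(20:200, 1)
    d <- sample(2:10, 1)
    k <- sample(c(1, 3, 5, 7, 9), 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(0:1, n, replace = TRUE)
    model <- knn_model(x, y, k = k)
    q <- matrix(rnorm(20 * d), 20, d)
    pred <- predict(model, q)
    for (j in 1:20) {
      oracle <- oracle_knn(x, y, q[j, ], k)
      expect_equal(pred$label[j], oracle$label)
      expect_equal(pred$score[j], oracle$score)
      expect_identical(sort(pred$neighbours[[j]]), sort(oracle$neighbours))
    }
  }
})

test_that("distance ties at the k-th rank resolve to the lowest row index", {
  x <- matrix(c(0, 1, 1, 2), ncol = 1)  # rows 2 and 3 tie at distance 1
  model <- knn_model(x, c(0L, 1L, 0L, 1L), k = 2)
  pred <- predict(model, 0)
  expect_identical(sort(pred$neighbours[[1]]), c(1L, 2L))
})

test_that("batch prediction equals looped single calls and permutes cleanly", {
  set.seed(29)
  x <- matrix(rnorm(120), 60, 2)
  y <- sample(0:1, 60, replace = TRUE)
  model <- knn_model(x, y, k = 7)
  q <- matrix(rnorm(30), 15, 2)
  keys <- sprintf("img%02d", 1:15)
  batch <- predict(model, q, keys = keys)
  for (j in 1:15) {
    single <- predict(model, q[j, ], keys = keys[j])
    expect_equal(batch$label[j], single$label)
    expect_equal(batch$score[j], single$score)
  }
  perm <- sample(15)
  permuted <- predict(model, q[perm, ], keys = keys[perm])
  expect_equal(permuted$label, batch$label[perm])
  expect_equal(permuted$score, batch$score[perm])
})

test_that("uniform feature scaling leaves predictions unchanged", {
  set.seed(37)
  x <- matrix(rnorm(100), 50, 2)
  y <- sample(0:1, 50, replace = TRUE)
  q <- matrix(rnorm(20), 10, 2)
  p1 <- predict(knn_model(x, y, k = 5), q)
  p2 <- predict(knn_model(x * 37.5, y, k = 5), q * 37.5)
  expect_equal(p1$label, p2$label)
  expect_equal(p1$score, p2$score)
})

test_that("odd k yields only the admissible certainty values", {
  set.seed(41)
  x <- matrix(rnorm(200), 100, 2)
  y <- sample(0:1, 100, replace = TRUE)
  pred <- predict(knn_model(x, y, k = 7), matrix(rnorm(60), 30, 2))
  expect_true(all(pred$certainty %in% (4:7 / 7)))
  expect_true(all(pred$label == (pred$score > 0.5)))
})

test_that("even-k vote ties break reproducibly per image key at certainty 0.5", {
  x <- matrix(c(0, 0, 2, 2), ncol = 1)
  y <- c(0L, 0L, 1L, 1L)
  model <- knn_model(x, y, k = 4, rng_seed = 5)
  keys <- sprintf("q%03d", 1:40)
  q <- matrix(1, 40, 1)
  pred <- predict(model, q, keys = keys)
  expect_true(all(pred$certainty == 0.5))
  again <- predict(model, q, keys = keys)
  expect_identical(pred$label, again$label)
  expect_true(all(c(0L, 1L) %in% pred$label))  # the tie really is random
})

test_that("dimension and k validation errors fire", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(0:1, 5)
  expect_error(knn_model(x, y, k = 11), "k must satisfy")
  expect_error(predict(knn_model(x, y, 3), matrix(1, 1, 3)), "dimension")
})

test_that("self-scoring separates clean clusters and wavers on contradictions", {
  set.seed(43)
  x <- rbind(matrix(rnorm(100, 0, 0.2), 50, 2),
             matrix(rnorm(100, 10, 0.2), 50, 2))
  y <- rep(c(0L, 1L), each = 50)
  loo <- self_score(x, y, k = 7, mode = "loo")
  expect_true(all(loo$certainty == 1))
  expect_identical(loo$label, y)

  # duplicated points with contradictory labels: certainty collapses to 0.5-ish
  xc <- rbind(x[1:20, ], x[1:20, ])
  yc <- c(rep(0L, 20), rep(1L, 20))
  contradiction <- self_score(xc, yc, k = 7, mode = "loo")
  expect_true(mean(contradiction$certainty) < 0.65)
})

test_that("leave-one-out equals a brute-force oracle that drops each point", {
  set.seed(47)
  x <- matrix(rnorm(200), 100, 2)
  y <- sample(0:1, 100, replace = TRUE)
  loo <- self_score(x, y, k = 5, mode = "loo")
  for (i in sample(100, 15)) {
    oracle <- oracle_knn(x[-i, , drop = FALSE], y[-i], x[i, ], 5)
    expect_equal(loo$score[i], oracle$score)
    expect_equal(loo$label[i], oracle$label)
  }
})

test_that("holdout self-scoring scores exactly the test rows", {
  set.seed(53)
  x <- matrix(rnorm(120), 60, 2)
  y <- sample(0:1, 60, replace = TRUE)
  sp <- split_dataset(60, 0.5, 7)
  hold <- self_score(x, y, k = 3, mode = "holdout", split = sp)
  expect_identical(hold$row, sp$test)
  model <- knn_model(x[sp$train, ], y[sp$train], k = 3)
  direct <- predict(model, x[sp$test, ])
  expect_equal(hold$score, direct$score)
})
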