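# GFA QSAR engine: outlier filter, splits, LOF, evolution, Y-scrambling

make_planted <- function(n = 120, p = 6, sd = 0.1, seed = 77) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- 2 * X[, 1] - 3 * X[, 3] + rnorm(n, sd = sd)
  regression_dataset(X, y)
}

test_that("kNN outlier filter removes a planted far point and nothing else", {
  set.seed(12)
  X <- rbind(matrix(rnorm(60 * 3), 60, 3), rep(10, 3))
  colnames(X) <- paste0("v", 1:3)
  d <- regression_dataset(X, rnorm(61))
  kept <- knn_outlier_filter(d, k = 3)
  expect_false(61 %in% kept)
  expect_length(kept, 60L)
  # infinite threshold removes nothing
  expect_length(knn_outlier_filter(d, k = 3, z_threshold = Inf), 61L)
  # duplicate rows share the same decision
  X2 <- rbind(X[1:10, ], X[1:10, ])
  d2 <- regression_dataset(X2, rnorm(20))
  kept2 <- knn_outlier_filter(d2, k = 2, z_threshold = 1)
  expect_equal(1:10 %in% kept2, 11:20 %in% kept2)
  expect_error(knn_outlier_filter(d, k = 0), "positive")
})

test_that("train/test splits partition the data deterministically", {
  d <- make_planted(n = 119)
  sp <- split_train_test(d, fraction = 80 / 119, seed = 4)
  expect_equal(nrow(sp$train$x), 80L)
  expect_equal(nrow(sp$test$x), 39L)
  expect_length(intersect(sp$train_idx, setdiff(1:119, sp$train_idx)), 0L)
  sp2 <- split_train_test(d, fraction = 80 / 119, seed = 4)
  expect_identical(sp$train_idx, sp2$train_idx)
  spd <- split_train_test(d, fraction = 0.8, mode = "diversity")
  expect_equal(nrow(spd$train$x), 95L)
  expect_identical(spd$train_idx, split_train_test(d, 0.8, "diversity")$train_idx)
})

test_that("LOF follows Friedman's formula", {
  expect_equal(lof_score(0, 100, 3, 4), 0)
  expect_equal(lof_score(50, 100, 5, 5, d = 1), 0.5 / 0.9^2, tolerance = 1e-12)
  l1 <- lof_score(50, 100, 2, 3)
  l2 <- lof_score(50, 100, 4, 5)
  expect_gt(l2, l1)  # complexity penalty
  expect_equal(lof_score(30, 60, 0, 0), 0.5)  # reduces to SSE/m
  expect_error(lof_score(50, 10, 5, 5), "complex")
})

test_that("GFA is reproducible under a fixed seed", {
  d <- make_planted(n = 80, p = 4)
  m1 <- gfa_evolve(d, pop_size = 20, generations = 8, seed = 3)
  m2 <- gfa_evolve(d, pop_size = 20, generations = 8, seed = 3)
  expect_identical(lapply(m1$terms, screenrank:::term_key),
                   lapply(m2$terms, screenrank:::term_key))
  expect_equal(m1$coefficients, m2$coefficients)
})

test_that("an evolved model converts to the logBB parameter format", {
  d <- make_planted(n = 100, p = 4)
  m <- gfa_evolve(d, pop_size = 30, generations = 12, seed = 6)
  lm <- as_logbb_model(m)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_logbb_model(lm, tf)
  lm2 <- read_logbb_model(tf)
  newx <- as.data.frame(d$x[1:5, , drop = FALSE])
  expect_equal(predict_logbb(newx, lm2), predict(m, d$x[1:5, , drop = FALSE]),
               tolerance = 1e-6)
})

test_that("Y-scrambling reports a distribution with defined spread", {
  d <- make_planted(n = 60, p = 4)
  sp <- split_train_test(d, 0.8, seed = 2)
  ys <- y_scramble(sp$train, sp$test, n_repeats = 3, seed = 9,
                   pop_size = 15, generations = 5)
  expect_equal(nrow(ys$runs), 3L)
  expect_true(ys$sd_defined)
  ys1 <- y_scramble(sp$train, sp$test, n_repeats = 1, seed = 9,
                    pop_size = 15, generations = 5)
  expect_false(ys1$sd_defined)
  expect_equal(ys1$sd_train, 0)
  # identical seeds give identical distributions
  ys2 <- y_scramble(sp$train, sp$test, n_repeats = 3, seed = 9,
                    pop_size = 15, generations = 5)
  expect_equal(ys$runs, ys2$runs)
})
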