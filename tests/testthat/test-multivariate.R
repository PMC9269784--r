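test_that("Z-scoring uses the population-SD convention and is exact", {
  df <- tibble::tibble(volume = c(1, 2, 3))
  p <- zscore_fit(df, "volume")
  z <- zscore_apply(p, df)$volume
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  set.seed(9)
  x <- tibble::tibble(volume = rlnorm(40, 7), surfarea = rnorm(40, 100, 5))
  zp <- zscore_fit(x)
  zx <- zscore_apply(zp, x)
  expect_equal(colMeans(as.matrix(zx)), c(volume = 0, surfarea = 0),
               tolerance = 1e-12)
  expect_equal(sqrt(colMeans(as.matrix(zx)^2)), c(volume = 1, surfarea = 1),
               tolerance = 1e-12)

  const <- tibble::tibble(volume = rep(5, 10))
  cp <- zscore_fit(const, "volume")
  expect_warning(cz <- zscore_apply(cp, const), "zero-variance")
  expect_equal(cz$volume, rep(0, 10))
  expect_error(zscore_fit(tibble::tibble(volume = 1), "volume"), "at least 2")
})

test_that("linear SVM separates separable data and respects symmetries", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, 2, 0.3), ncol = 2),
             matrix(rnorm(40, -2, 0.3), ncol = 2))
  y <- rep(c("malignant", "benign"), each = 20)
  for (c_val in c(0.01, 0.1, 1, 10)) {
    m <- train_lsvm(x, y, c = c_val)
    expect_equal(mean(predict(m, x) == y), 1)
  }

  # flipping labels flips predictions
  m1 <- train_lsvm(x, y, c = 1)
  m2 <- train_lsvm(x, rev(y), c = 1)
  xs <- matrix(rnorm(40, 0, 3), ncol = 2)
  p1 <- predict(m1, xs)
  p2 <- predict(m2, xs)
  flip <- c(benign = "malignant", malignant = "benign")
  expect_equal(unname(flip[p1]), p2)

  # a duplicated feature column does not change training predictions
  x1 <- matrix(rnorm(60), ncol = 1)
  yy <- ifelse(x1[, 1] + rnorm(60, 0, 0.5) > 0, "malignant", "benign")
  if (length(unique(yy)) == 2) {
    pa <- predict(train_lsvm(x1, yy, c = 1), x1)
    pb <- predict(train_lsvm(cbind(x1, x1), yy, c = 0.5), cbind(x1, x1))
    expect_equal(pa, pb)
  }

  expect_error(train_lsvm(x, rep("benign", 40)), "two classes")
})

test_that("SVM training is deterministic", {
  co <- simulate_cohort(load_calibration("SSR1"), seed = 5)
  r1 <- loo_eval(co, "extended", c = 1)
  r2 <- loo_eval(co, "extended", c = 1)
  expect_identical(r1$correct, r2$correct)
})

test_that("grid search ties break toward the smallest penalty", {
  co <- separable_cohort(6)
  # on the identity holdout every C reaches accuracy 1.0; smallest C wins
  best <- grid_search_c(co, "holdout",
                        classifier_config(feature_set = "base"), test = co)
  expect_equal(best$accuracy, 1)
  expect_equal(best$chosen_c, 0.01)

  one <- grid_search_c(co, "loo",
                       classifier_config(c_grid = 10, feature_set = "base"))
  expect_equal(one$chosen_c, 10)
  expect_error(grid_search_c(co, "holdout", classifier_config()),
               "requires a test cohort")
})

test_that("leave-one-out evaluates every sample and handles boundaries", {
  co <- separable_cohort(5)
  res <- loo_eval(co, "base", c = 1)
  expect_equal(res$correct, 10L)
  expect_equal(res$total, 10L)
  expect_equal(res$accuracy_pct, 100)

  tiny <- separable_cohort(2)[c(1, 2, 4), ]
  expect_equal(loo_eval(tiny, "base", c = 1)$total, 3L)
  expect_error(loo_eval(separable_cohort(1), "base"), "at least 3")

  # pure-noise features: accuracy stays near the majority rate
  set.seed(31)
  accs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    co <- tibble::tibble(label = rep(c("benign", "malignant"), c(14, 26)),
                         dataset = "null")
    for (f in feature_set_columns("base")) co[[f]] <- rnorm(40)
    loo_eval(co, "base", c = 0.1)$accuracy
  }, numeric(1))
  expect_lt(abs(median(accs) - 0.65), 0.2)
})

test_that("strict per-fold normalization is available and close to the default", {
  co <- simulate_cohort(load_calibration("SSR1"), seed = 8)[1:40, ]
  a <- loo_eval(co, "base", c = 1)
  b <- loo_eval(co, "base", c = 1, strict_normalization = TRUE)
  expect_lte(abs(a$accuracy - b$accuracy), 0.2)
})

test_that("cross-dataset evaluation normalizes each dataset independently", {
  co <- separable_cohort(6)
  idres <- cross_eval(co, co, "base", c = 1)
  # identity split equals whole-set training accuracy
  ztr <- zscore_apply(zscore_fit(co), co)
  m <- train_lsvm(as.matrix(ztr[, feature_set_columns("base")]), co$label, 1)
  train_acc <- mean(predict(m, as.matrix(ztr[, feature_set_columns("base")]))
                    == co$label)
  expect_equal(idres$accuracy, train_acc)

  other <- separable_cohort(8, dataset = "toy2")
  res <- cross_eval(co, other, "extended", c = 1)
  expect_equal(res$train, "toy")
  expect_equal(res$test, "toy2")
  expect_equal(res$accuracy, 1)

  expect_error(cross_eval(co, other[, 1:4], "base"), "missing feature")
})

test_that("accuracy and gain formatting follow the percentage (fraction) layout", {
  expect_equal(format_accuracy(41, 83), "49.4 (41/83)")
  expect_equal(format_accuracy(71, 109), "65.1 (71/109)")

  base <- lesionshape:::eval_result("A", "B", "base", 41, 83, 0.1)
  ext <- lesionshape:::eval_result("A", "B", "extended", 53, 83, 1)
  g <- gain(base, ext)
  expect_equal(g$label, "14.5 (12/83)")
  expect_equal(g$gain_pp, 100 * 12 / 83)

  b2 <- lesionshape:::eval_result("A", "A", "base", 71, 109, 1)
  e2 <- lesionshape:::eval_result("A", "A", "extended", 72, 109, 1)
  expect_equal(gain(b2, e2)$label, "0.9 (1/109)")
  expect_equal(gain(b2, b2)$gain_pp, 0)
  expect_error(gain(base, e2), "same train/test")
})

test_that("the extended feature set is the base set plus the four form factors", {
  expect_equal(feature_set_columns("base"),
               c("max3ddiam", "surfarea", "volume"))
  expect_equal(setdiff(feature_set_columns("extended"),
                       feature_set_columns("base")),
               c("afl", "aco", "kfl", "mps"))
})
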