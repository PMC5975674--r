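test_that("LGOCV splits have the contracted sizes, are disjoint, deterministic, and cover", {
  sp <- lgocv_splits(10, 0.75, iterations = 5, seed = 1)
  for (s in sp) {
    expect_length(s$train, 8L)
    expect_length(s$test, 2L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(c(s$train, s$test), 1:10)
  }
  expect_identical(lgocv_splits(10, 0.75, 5, seed = 1), sp)
  # over 100 iterations with n = 20 every sample appears in some test set
  sp2 <- lgocv_splits(20, 0.75, 100, seed = 2)
  tested <- unique(unlist(lapply(sp2, `[[`, "test")))
  expect_setequal(tested, 1:20)
  # stratification keeps every class in the training set
  y <- rep(c("a", "b", "c"), c(10, 6, 4))
  sp3 <- lgocv_splits(20, 0.6, 50, seed = 3, stratify = y)
  for (s in sp3) expect_setequal(unique(y[s$train]), c("a", "b", "c"))
})

test_that("holdout split rounds as documented and stratifies", {
  sp <- holdout_split(453, 300 / 453, seed = 1)
  expect_length(sp$train, 300L)
  expect_length(sp$test, 153L)
  sp3 <- holdout_split(3, 2 / 3, seed = 1)
  expect_length(sp3$train, 2L)
  expect_identical(holdout_split(50, 0.7, seed = 9),
                   holdout_split(50, 0.7, seed = 9))
  y <- rep(c("a", "b"), c(40, 10))
  sph <- holdout_split(50, 0.6, seed = 2, stratify_by = y)
  expect_equal(sum(y[sph$train] == "b"), 6L)
  expect_warning(holdout_split(5, 0.6, seed = 1,
                               stratify_by = c("a", "a", "a", "a", "solo")),
                 "size 1")
  expect_error(holdout_split(4, 0.01, seed = 1), "non-empty")
})

test_that("soft threshold shrinks by the (keep+1)-th magnitude and normalizes", {
  expect_equal(soft_threshold(c(3, -1, 0.5), 1, renormalize = FALSE),
               c(2, 0, 0))
  expect_equal(soft_threshold(c(3, -1, 0.5), 1), c(1, 0, 0))
  w <- soft_threshold(c(3, -1, 0.5), 3)
  expect_equal(w, c(3, -1, 0.5) / sqrt(sum(c(3, -1, 0.5)^2)))
  expect_equal(sum(soft_threshold(rnorm(10), 4) != 0), 4L)
})

test_that("RFE picks the single perfect predictor at size 1", {
  set.seed(4)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  X[, 3] <- ifelse(y == "a", -3, 3) + rnorm(n, sd = 0.01)
  r <- rfe(X, y, sizes = c(1, 2, 5),
           cv = cv_spec("lgocv", iterations = 5, seed = 4))
  expect_equal(r$chosen_size, 1L)
  expect_identical(r$chosen_features, "f3")
  expect_error(rfe(X, rep("a", n)), "2 classes")
})

test_that("RFE on pure noise settles at a small size with near-chance accuracy", {
  set.seed(5)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 30), n, 30)
  r <- rfe(X, y, sizes = c(1, 5, 10, 30),
           cv = cv_spec("lgocv", iterations = 8, seed = 5))
  expect_equal(r$chosen_size, 1L)
  expect_lt(max(r$accuracy$mean), 0.75)
})

test_that("classifier evaluation separates a separable toy and enforces the 10:1 guard", {
  set.seed(6)
  n <- 80
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(x1 = ifelse(y == "a", 0, 6) + rnorm(n),
             x2 = rnorm(n))
  tr <- seq(1, n, by = 2); te <- seq(2, n, by = 2)
  ev <- train_eval_classifier(X[tr, ], y[tr], X[te, ], y[te],
                              cv = cv_spec("lgocv", iterations = 5, seed = 6))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)
  expect_equal(sum(ev$confusion), length(te))
  # guard: 40 observations over 20 predictors is refused without the flag
  Xw <- cbind(X, matrix(rnorm(n * 18), n,
                        dimnames = list(NULL, paste0("z", 1:18))))[, 1:20]
  expect_error(train_eval_classifier(Xw[tr, ], y[tr], Xw[te, ], y[te]),
               "per predictor")
  ev2 <- train_eval_classifier(Xw[tr, ], y[tr], Xw[te, ], y[te],
                               allow_small = TRUE,
                               cv = cv_spec("lgocv", iterations = 3,
                                            seed = 6))
  expect_s3_class(ev2, "model_evaluation")
  expect_error(train_eval_classifier(X[tr, ], y[tr], X[te, ],
                                     rep("zzz", length(te))),
               "absent")
})

test_that("label-permuted data scores near the majority-class rate", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5)
  y <- sample(rep(c("a", "b"), c(72, 48)))
  sp <- holdout_split(n, 0.67, seed = 7, stratify_by = y)
  ev <- train_eval_classifier(X[sp$train, ], y[sp$train],
                              X[sp$test, ], y[sp$test],
                              cv = cv_spec("lgocv", iterations = 3, seed = 7),
                              allow_small = TRUE)
  maj <- max(table(y[sp$test])) / length(sp$test)
  se <- sqrt(maj * (1 - maj) / length(sp$test))
  expect_lt(abs(ev$accuracy - maj), 3 * se + 0.1)
})

test_that("tuning never touches the held-out test partition", {
  set.seed(8)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "a", 0, 3) + rnorm(n), rnorm(n), rnorm(n))
  tr <- 1:40; te <- 41:60
  ev1 <- train_eval_classifier(X[tr, ], y[tr], X[te, ], y[te],
                               cv = cv_spec("lgocv", iterations = 5,
                                            seed = 8), allow_small = TRUE)
  Xp <- X
  Xp[te, ] <- 1e6  # poison the test rows
  ev2 <- train_eval_classifier(Xp[tr, ], y[tr], Xp[te, ], y[te],
                               cv = cv_spec("lgocv", iterations = 5,
                                            seed = 8), allow_small = TRUE)
  expect_identical(ev1$tuned, ev2$tuned)
})

test_that("multiblock sPLS-DA reduces to dense PLS-DA scores for one block, full keep", {
  set.seed(9)
  n <- 50
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 2
  fit <- multiblock_splsda_fit(list(b1 = X), y, keepX = list(b1 = 8),
                               ncomp = 1)
  # dense weight direction: first singular direction of X'Y (up to sign)
  Xs <- scale(X)
  Yd <- scale(stats::model.matrix(~ factor(y) - 1), center = TRUE,
              scale = FALSE)
  w_ref <- svd(crossprod(Xs, Yd))$u[, 1]
  w_fit <- fit$loadings[[1]][, 1]
  agree <- abs(sum(w_ref * w_fit))
  expect_gt(agree, 0.99)
  expect_error(multiblock_splsda_fit(list(b1 = X), y,
                                     keepX = list(b1 = 99)), "width")
})

test_that("sPLS-DA tuning returns the single grid point unchanged and is deterministic", {
  set.seed(10)
  n <- 60
  y <- rep(c("a", "b", "c"), each = n / 3)
  blocks <- list(b1 = matrix(rnorm(n * 10), n, 10),
                 b2 = matrix(rnorm(n * 10), n, 10))
  blocks$b1[y == "b", 1:3] <- blocks$b1[y == "b", 1:3] + 3
  blocks$b2[y == "c", 1:3] <- blocks$b2[y == "c", 1:3] + 3
  one <- splsda_tune(blocks, y, keep_grid = list(b1 = 5, b2 = 5), ncomp = 2,
                     cv = cv_spec("repeated_kfold", folds = 3, repeats = 1,
                                  seed = 10))
  expect_equal(one$chosen$b1, 5)
  expect_equal(one$chosen$b2, 5)
  g1 <- splsda_tune(blocks, y, keep_grid = list(b1 = c(3, 5), b2 = c(3, 5)),
                    ncomp = 2,
                    cv = cv_spec("repeated_kfold", folds = 3, repeats = 1,
                                 seed = 11))
  g2 <- splsda_tune(blocks, y, keep_grid = list(b1 = c(3, 5), b2 = c(3, 5)),
                    ncomp = 2,
                    cv = cv_spec("repeated_kfold", folds = 3, repeats = 1,
                                 seed = 11))
  expect_identical(g1$surface, g2$surface)
})

test_that("adjusted Rand index has its reference values", {
  a <- rep(1:2, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, 3 - a), 1)  # label permutation
  set.seed(12)
  lab1 <- sample(1:3, 600, replace = TRUE)
  lab2 <- sample(1:3, 600, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(lab1, lab2)), 0.05)
  # cross-check against an independent implementation
  expect_equal(adjusted_rand_index(lab1, lab2),
               mclust::adjustedRandIndex(lab1, lab2), tolerance = 1e-12)
})
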