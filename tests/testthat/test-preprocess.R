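test_that("imputation methods fill missing cells with the stated values", {
  vals <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2)
  m <- toy_matrix(vals, llq = 2)
  # mean of (f2 observed) = 5
  mi <- impute_missing(m, "mean")
  expect_equal(mi$values["f2", "s1"], 5)
  expect_false(any(mi$missing_mask))
  expect_equal(nrow(attr(mi, "imputed")), 1L)
  # LLQ family: stated formulas
  expect_equal(impute_missing(m, "llq")$values["f2", "s1"], 2)
  expect_equal(impute_missing(m, "llq_half")$values["f2", "s1"], 1)
  expect_equal(impute_missing(m, "llq_sqrt2")$values["f2", "s1"], 2 / sqrt(2))
  expect_equal(impute_missing(m, "zero")$values["f2", "s1"], 0)
  m_nollq <- toy_matrix(vals)
  expect_error(impute_missing(m_nollq, "llq"), "LLQ")
})

test_that("knn_mean imputes from the brute-force nearest neighbour", {
  # f1 missing in s1; distances judged on f2, f3
  vals <- matrix(c(NA, 0, 0,
                   7, 0.1, -0.1,
                   50, 5, 5), 3, 3,
                 dimnames = list(c("f1", "f2", "f3"), c("s1", "s2", "s3")))
  m <- omics_matrix(vals, platform = "t")
  got <- impute_missing(m, "knn_mean", knn_k = 1)$values["f1", "s1"]
  # independent oracle: z-score rows on observed, RMS distance on shared
  z <- t(apply(vals, 1, function(x) (x - mean(x, na.rm = TRUE)) /
                 sd(x, na.rm = TRUE)))
  d <- function(i, j) {
    sh <- !is.na(vals[, i]) & !is.na(vals[, j])
    sqrt(mean((z[sh, i] - z[sh, j])^2))
  }
  nn <- c("s2", "s3")[which.min(c(d(1, 2), d(1, 3)))]
  expect_equal(got, vals["f1", nn])
})

test_that("missing-data policy routes by the strict 10% boundary", {
  set.seed(4)
  vals <- matrix(rnorm(10 * 20), 10, 20)
  vals[1, 1] <- NA                # 5% missing -> impute
  vals[2, 1:8] <- NA              # 40% -> binarize
  vals[3, 1:2] <- NA              # exactly 10% -> high branch
  m <- toy_matrix(vals)
  out <- apply_missing_policy(m, missing_policy(threshold = 0.10))
  expect_false("f2" %in% rownames(out$matrix$values))
  expect_false("f3" %in% rownames(out$matrix$values))
  expect_true("f1" %in% rownames(out$matrix$values))
  expect_false(any(out$matrix$missing_mask))
  expect_setequal(rownames(out$binarized), c("f2", "f3"))
  expect_equal(sum(out$binarized["f2", ] == 0), 8)
  # impute_flagged keeps everything numeric but flags the high features
  out2 <- apply_missing_policy(m, missing_policy(
    threshold = 0.10, high_action = "impute_flagged"))
  expect_true(all(c("f2", "f3") %in% rownames(out2$matrix$values)))
  expect_setequal(out2$report$flagged_features, c("f2", "f3"))
})

test_that("detection-rate chi-square matches the closed form and handles degenerate tables", {
  present <- rep(c(TRUE, FALSE, TRUE, FALSE), c(9, 1, 2, 8))
  groups <- rep(c("a", "b"), each = 10)
  r <- detection_rate_test(present, groups)
  # n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on [[9,1],[2,8]]
  expect_equal(r$statistic, 20 * (9 * 8 - 1 * 2)^2 / (10 * 10 * 11 * 9),
               tolerance = 1e-9)
  expect_equal(r$p, 0.00165, tolerance = 1e-2)
  same <- detection_rate_test(rep(c(TRUE, FALSE), 10),
                              rep(c("a", "b"), each = 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_warning(z <- detection_rate_test(rep(TRUE, 10),
                                          rep(c("a", "b"), each = 5)),
                 "degenerate")
  expect_equal(z$p, 1)
})

test_that("outlier flagging flags gross outliers, never alters values, skips MAD=0", {
  vals <- rbind(f1 = c(0, 0.1, -0.1, 0.05, 100),
                f2 = rep(3, 5))
  m <- omics_matrix(vals, platform = "t")
  expect_warning(fl <- flag_outliers(m), "MAD")
  expect_identical(fl$feature, "f1")
  expect_identical(fl$sample, "s5")
  expect_identical(m$values, omics_matrix(vals, platform = "t")$values)
  # Gaussian noise at cut 5: expect (essentially) no flags
  set.seed(7)
  g <- toy_matrix(matrix(rnorm(1000), 1, 1000))
  expect_equal(nrow(flag_outliers(g, 5)), 0)
})

test_that("batch adjustment equalizes batch means and preserves grand means", {
  set.seed(11)
  n <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  vals <- matrix(rnorm(5 * n), 5, n)
  vals[, batch == "b2"] <- vals[, batch == "b2"] + 5
  m <- toy_matrix(vals)
  grand <- rowMeans(m$values)
  adj <- adjust_batch(m, batch)
  for (f in seq_len(5)) {
    mb <- tapply(adj$values[f, ], batch, mean)
    expect_equal(unname(mb[1]), unname(mb[2]), tolerance = 1e-9)
  }
  expect_equal(rowMeans(adj$values), grand, tolerance = 1e-9)
  expect_error(adjust_batch(m, rep("b1", n)), "2 batches")
  expect_error(adjust_batch(m, c("solo", rep("b1", n - 1))), "singleton")
})

test_that("batch adjustment removes batch separation in PCA space", {
  set.seed(21)
  n <- 60
  batch <- rep(c("b1", "b2"), each = n / 2)
  vals <- matrix(rnorm(30 * n), 30, n)
  vals[, batch == "b2"] <- vals[, batch == "b2"] + 3
  adj <- adjust_batch(toy_matrix(vals), batch)
  pc1 <- prcomp(t(adj$values))$x[, 1]
  # silhouette of batch labels on PC1: near zero after adjustment
  s_between <- abs(mean(pc1[batch == "b1"]) - mean(pc1[batch == "b2"]))
  expect_lt(s_between / sd(pc1), 0.5)
})

test_that("znormalize gives mean 0 / sd 1, drops constants, is idempotent", {
  m <- toy_matrix(rbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5)))
  expect_warning(z <- znormalize(m), "constant")
  expect_equal(unname(z$values["f1", ]), c(-1, 0, 1))
  z2 <- znormalize(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
})
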