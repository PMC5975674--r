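test_that("generation is deterministic and clean specs have no missing cells", {
  g1 <- generate_cohort(synthetic_spec(seed = 3))
  g2 <- generate_cohort(synthetic_spec(seed = 3))
  expect_identical(g1$labels, g2$labels)
  for (v in seq_along(g1$dataset$views))
    expect_identical(g1$dataset$views[[v]]$values,
                     g2$dataset$views[[v]]$values)
  expect_identical(g1$dataset$clinical, g2$dataset$clinical)
  expect_false(any(sapply(g1$dataset$views, function(v) any(v$missing_mask))))
  # clinical carries both components of total days lived
  expect_true(all(c("enrolment_age_days", "post_enrolment_days") %in%
                    names(g1$dataset$clinical)))
  expect_equal(g1$dataset$clinical$survival_time_days,
               g1$dataset$clinical$enrolment_age_days +
                 g1$dataset$clinical$post_enrolment_days)
})

test_that("realized MCAR fraction concentrates at the requested rate", {
  spec <- synthetic_spec(n_samples = 150,
                         views = list(list(name = "v", n_features = 700,
                                           n_informative = 0, delta = 0,
                                           sigma = 1, separates = c(1, 2))),
                         mcar_rate = 0.05, seed = 4)
  g <- generate_cohort(spec)
  expect_equal(mean(g$dataset$views[[1]]$missing_mask), 0.05,
               tolerance = 0.01)
})

test_that("LLQ truncation records the limit and masks below-limit values", {
  spec <- synthetic_spec(llq_quantile = 0.05, seed = 5)
  g <- generate_cohort(spec)
  for (v in g$dataset$views) {
    expect_false(is.null(v$llq))
    obs <- v$values[!v$missing_mask]
    expect_true(all(obs >= v$llq))
    expect_equal(mean(v$missing_mask), 0.05, tolerance = 0.01)
  }
})

test_that("batch offsets land in the clinical table and shift view means", {
  spec <- synthetic_spec(n_batches = 2, batch_sd = 2, seed = 6)
  g <- generate_cohort(spec)
  expect_true("batch" %in% names(g$dataset$clinical))
  expect_equal(sort(unique(g$dataset$clinical$batch)), c("B1", "B2"))
  # a strong additive offset separates batch means on many features
  v <- g$dataset$views[[1]]
  b <- g$dataset$clinical$batch
  dm <- abs(rowMeans(v$values[, b == "B1"]) - rowMeans(v$values[, b == "B2"]))
  expect_gt(mean(dm), 0.5)
})

test_that("k = 1 cohorts carry no recoverable structure", {
  g <- generate_cohort(synthetic_spec(k_clusters = 1, seed = 7))
  expect_true(all(g$labels == 1))
  v <- znormalize(g$dataset$views[[1]])
  set.seed(7)
  lab <- suppressWarnings(spectral_cluster(view_affinity(v), 3))
  rand_ref <- sample(1:3, 150, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(lab, rand_ref)), 0.1)
  fr <- survival_filter(v, g$dataset$clinical)
  expect_lt(fr$n_after / fr$n_before, 0.1)
})

test_that("summaries recover censoring, effect structure and the hazard-linked KM medians", {
  # hazard ratio 4, light censoring so both medians are observed
  spec <- synthetic_spec(n_samples = 400, k_clusters = 2,
                         views = list(list(name = "v", n_features = 50,
                                           n_informative = 10, delta = 1.5,
                                           sigma = 1, separates = c(1, 2))),
                         hazards = c(1/200, 1/800),
                         censoring_fraction = 0.05, seed = 8)
  g <- generate_cohort(spec)
  sm <- summarize_cohort(g$dataset, g$labels)
  expect_equal(sm$censoring_rate, 0.05, tolerance = 0.05)
  ratio <- sm$km_median_days["cluster2"] / sm$km_median_days["cluster1"]
  expect_equal(unname(ratio), 4, tolerance = 0.35)
  expect_gt(sm$variance_ratio["v"], 0.02)
  # delta = 0 gives variance ratio ~ 0 between clusters
  spec0 <- synthetic_spec(n_samples = 200, k_clusters = 2,
                          views = list(list(name = "v", n_features = 50,
                                            n_informative = 10, delta = 0,
                                            sigma = 1, separates = c(1, 2))),
                          hazards = c(1/200, 1/800), seed = 9)
  g0 <- generate_cohort(spec0)
  sm0 <- summarize_cohort(g0$dataset, g0$labels)
  expect_lt(sm0$variance_ratio["v"], 0.05)
})

test_that("infeasible censoring is rejected", {
  expect_error(synthetic_spec(censoring_fraction = 1), "censoring_fraction")
})

test_that("survival filter enriches informative features on cluster-linked cohorts", {
  # low prior (50 of 1000), 2 subtypes with a 4-fold hazard ratio
  spec <- synthetic_spec(n_samples = 150, k_clusters = 2,
                         views = list(list(name = "v", n_features = 1000,
                                           n_informative = 50, delta = 1.5,
                                           sigma = 1, separates = c(1, 2))),
                         hazards = c(1/200, 1/800), seed = 10)
  g <- generate_cohort(spec)
  fr <- survival_filter(znormalize(g$dataset$views[[1]]),
                        g$dataset$clinical)
  precision <- mean(as.integer(sub(".*_f", "", fr$kept)) <= 50)
  prior <- 50 / 1000
  expect_gte(precision, 5 * prior)
})
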