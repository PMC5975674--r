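#' Cross-validation specification
#'
#' @param scheme `"lgocv"` (repeated random train/test partitions) or
#'   `"repeated_kfold"`.
#' @param iterations LGOCV iterations (or total repeats x folds splits).
#' @param fraction LGOCV training fraction in (0, 1).
#' @param folds,repeats for `repeated_kfold`.
#' @param seed RNG seed for split generation.
#' @return a `cv_spec`.
#' @export
cv_spec <- function(scheme = c("lgocv", "repeated_kfold"), iterations = 100L,
                    fraction = 0.75, folds = 10L, repeats = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(fraction > 0, fraction < 1, folds >= 2L)
  structure(list(scheme = scheme, iterations = as.integer(iterations),
                 fraction = fraction, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_spec")
}

# Proportional (largest-remainder) allocation of a total over strata.
.allocate <- function(counts, total) {
  raw <- counts / sum(counts) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  base
}

#' Leave-group-out (Monte-Carlo) cross-validation splits
#'
#' Each iteration draws a random training set of `round(fraction * n)`
#' samples without replacement; the complement is the test set. When
#' `stratify` labels are supplied the draw is proportional per class and
#' every class with at least one member is forced into the training set.
#'
#' @param n number of samples.
#' @param fraction training fraction; default 0.75.
#' @param iterations number of splits; default 100.
#' @param seed RNG seed.
#' @param stratify optional class label per sample.
#' @return list of `iterations` lists with integer `train` and `test`.
#' @export
lgocv_splits <- function(n, fraction = 0.75, iterations = 100L, seed = 1L,
                         stratify = NULL) {
  m <- round(fraction * n)
  stopifnot(m >= 1L, m < n)
  set.seed(seed)
  out <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    if (is.null(stratify)) {
      train <- sort(sample.int(n, m))
    } else {
      f <- as.factor(stratify)
      alloc <- pmax(.allocate(table(f), m), 1L)
      # forced >= 1 per class can overshoot by a few; trim largest strata
      while (sum(alloc) > m) {
        j <- which.max(alloc)
        alloc[j] <- alloc[j] - 1L
      }
      train <- sort(unlist(lapply(seq_along(levels(f)), function(j) {
        idx <- which(f == levels(f)[j])
        if (alloc[j] >= length(idx)) idx else sample(idx, alloc[j])
      }), use.names = FALSE))
    }
    out[[i]] <- list(train = train, test = setdiff(seq_len(n), train))
  }
  out
}

#' Repeated k-fold cross-validation splits
#'
#' @param n number of samples.
#' @param folds,repeats fold count and repeat count.
#' @param seed RNG seed.
#' @param stratify optional class label per sample (folds drawn per class).
#' @return list of splits with `train` and `test` indices.
#' @export
rkf_splits <- function(n, folds = 10L, repeats = 10L, seed = 1L,
                       stratify = NULL) {
  set.seed(seed)
  out <- list()
  for (r in seq_len(repeats)) {
    fold_id <- integer(n)
    if (is.null(stratify)) {
      fold_id <- sample(rep_len(seq_len(folds), n))
    } else {
      f <- as.factor(stratify)
      for (lv in levels(f)) {
        idx <- which(f == lv)
        fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    }
    for (k in seq_len(folds)) {
      test <- which(fold_id == k)
      if (!length(test)) next
      out[[length(out) + 1L]] <- list(train = setdiff(seq_len(n), test),
                                      test = test)
    }
  }
  out
}

.cv_splits <- function(cv, n, stratify = NULL) {
  if (cv$scheme == "lgocv")
    lgocv_splits(n, cv$fraction, cv$iterations, cv$seed, stratify)
  else
    rkf_splits(n, cv$folds, cv$repeats, cv$seed, stratify)
}

#' Stratified holdout split
#'
#' Training size is `round(train_fraction * n)`, allocated proportionally
#' across strata; a stratum of size 1 goes to the training set with a
#' warning.
#'
#' @param n number of samples.
#' @param train_fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @param stratify_by optional class label per sample.
#' @return list with integer `train` and `test` indices.
#' @export
holdout_split <- function(n, train_fraction, seed = 1L, stratify_by = NULL) {
  m <- round(train_fraction * n)
  if (m < 1L || m >= n) stop("both partitions must be non-empty")
  set.seed(seed)
  if (is.null(stratify_by)) {
    train <- sort(sample.int(n, m))
  } else {
    f <- as.factor(stratify_by)
    counts <- table(f)
    if (any(counts == 1L))
      warning("stratum(s) of size 1 assigned to the training set: ",
              paste(names(counts)[counts == 1L], collapse = ", "))
    alloc <- .allocate(counts, m)
    alloc[counts == 1L] <- 1L
    while (sum(alloc) > m) {
      j <- which.max(alloc)
      alloc[j] <- alloc[j] - 1L
    }
    train <- sort(unlist(lapply(seq_along(levels(f)), function(j) {
      idx <- which(f == levels(f)[j])
      if (alloc[j] >= length(idx)) idx else sample(idx, alloc[j])
    }), use.names = FALSE))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Linear maximum-margin ranker/classifier contract
#'
#' Wraps a linear support-vector machine as the default recursive-
#' feature-elimination ranker: per-feature importance is the squared
#' primal weight, summed over one-vs-rest machines for multi-class
#' problems.
#'
#' @param cost SVM cost parameter; default 1.
#' @return a model contract: list of `fit(X, y)`, `predict(model, X)`,
#'   `importance(model)`.
#' @export
svm_linear_model <- function(cost = 1) {
  list(
    fit = function(X, y) {
      y <- factor(y)
      fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
      w2 <- rep(0, ncol(X))
      if (nlevels(y) == 2L) {
        w <- crossprod(fit$coefs, fit$SV)
        w2 <- as.numeric(w)^2
      } else {
        for (lv in levels(y)) {
          fb <- e1071::svm(X, factor(y == lv), kernel = "linear",
                           cost = cost, scale = FALSE)
          w <- crossprod(fb$coefs, fb$SV)
          w2 <- w2 + as.numeric(w)^2
        }
      }
      list(fit = fit, importance = w2)
    },
    predict = function(model, X) as.character(predict(model$fit, X)),
    importance = function(model) model$importance
  )
}

#' Random-forest classifier contract
#'
#' @param ntree trees per forest; default 500.
#' @param mtry_grid candidate `mtry` values tuned by cross-validation;
#'   default `sqrt(p)` and `p / 3`.
#' @return a model contract with `fit(X, y, mtry)`, `predict`, `grid(p)`.
#' @export
rf_classifier <- function(ntree = 500L, mtry_grid = NULL) {
  list(
    fit = function(X, y, mtry = max(1L, floor(sqrt(ncol(X))))) {
      randomForest::randomForest(X, factor(y), ntree = ntree,
                                 mtry = min(mtry, ncol(X)))
    },
    predict = function(model, X) as.character(predict(model, X)),
    grid = function(p) {
      if (!is.null(mtry_grid)) return(mtry_grid)
      unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3))))
    }
  )
}

#' Recursive feature elimination with cross-validated size selection
#'
#' Outer cross-validation loop: on each training split the ranker is
#' fitted on all features and features are ranked by decreasing
#' importance; the model is then refitted at every candidate size on the
#' top-ranked features and scored on the held-out split. The chosen size
#' is the smallest whose mean accuracy is within one standard deviation of
#' the best mean accuracy (a standard parsimony rule). The final feature
#' set is the top of the full-data ranking at the chosen size.
#'
#' @param X sample x feature matrix (platforms already concatenated and
#'   per-platform z-scaled).
#' @param y class label per sample (>= 2 classes).
#' @param sizes candidate sizes; default 1..50 plus all features.
#' @param cv a `cv_spec`; default LGOCV.
#' @param ranker a model contract as returned by [svm_linear_model()].
#' @return an `rfe_result`: list with `sizes`, `accuracy` (mean, sd per
#'   size), `chosen_size`, `chosen_features`, `ranking`.
#' @export
rfe <- function(X, y, sizes = NULL,
                cv = cv_spec("lgocv", iterations = 10L, seed = 1L),
                ranker = svm_linear_model()) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("y must have at least 2 classes")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(sizes)) sizes <- unique(c(seq_len(min(50L, p)), p))
  sizes <- sort(unique(pmin(as.integer(sizes), p)))
  splits <- .cv_splits(cv, nrow(X), stratify = y)
  set.seed(cv$seed)
  acc <- matrix(NA_real_, length(splits), length(sizes),
                dimnames = list(NULL, as.character(sizes)))
  for (i in seq_along(splits)) {
    tr <- splits[[i]]$train; te <- splits[[i]]$test
    fit_full <- ranker$fit(X[tr, , drop = FALSE], y[tr])
    ord <- order(-ranker$importance(fit_full), colnames(X), method = "radix")
    for (j in seq_along(sizes)) {
      top <- ord[seq_len(sizes[j])]
      fs <- ranker$fit(X[tr, top, drop = FALSE], y[tr])
      pred <- ranker$predict(fs, X[te, top, drop = FALSE])
      acc[i, j] <- mean(pred == y[te])
    }
  }
  mean_acc <- colMeans(acc)
  sd_acc <- apply(acc, 2L, stats::sd)
  best_j <- which.max(mean_acc)
  thresh <- mean_acc[best_j] - sd_acc[best_j]
  chosen_j <- min(which(mean_acc >= thresh))
  chosen_size <- sizes[chosen_j]
  fit_all <- ranker$fit(X, y)
  ranking <- colnames(X)[order(-ranker$importance(fit_all), colnames(X),
                               method = "radix")]
  structure(list(sizes = sizes,
                 accuracy = data.frame(size = sizes, mean = mean_acc,
                                       sd = sd_acc, row.names = NULL),
                 chosen_size = chosen_size,
                 chosen_features = ranking[seq_len(chosen_size)],
                 ranking = ranking),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("rfe_result: chose %d feature(s); best mean CV accuracy %.3f\n",
              x$chosen_size, max(x$accuracy$mean)))
  invisible(x)
}

#' Train a classifier with CV tuning and evaluate on an untouched test set
#'
#' Tuning (over the model contract's parameter grid) uses cross-validation
#' on the training partition only; the test partition is scored exactly
#' once with the tuned model. By default the function refuses final models
#' with fewer than 10 training observations per predictor - a published
#' rule of thumb against overfitting - unless `allow_small = TRUE`.
#'
#' @param X_train,y_train training partition.
#' @param X_test,y_test test partition (classes must appear in training).
#' @param model a model contract; default [rf_classifier()].
#' @param cv a `cv_spec` used for tuning.
#' @param min_obs_per_predictor overfitting guard; default 10.
#' @param allow_small override the guard.
#' @return a `model_evaluation`: list with `accuracy`, `kappa`,
#'   `confusion` (rows = truth), `per_class` (sensitivity, specificity),
#'   `tuned`.
#' @export
train_eval_classifier <- function(X_train, y_train, X_test, y_test,
                                  model = rf_classifier(),
                                  cv = cv_spec("lgocv", iterations = 10L,
                                               seed = 1L),
                                  min_obs_per_predictor = 10,
                                  allow_small = FALSE) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y_train <- as.character(y_train); y_test <- as.character(y_test)
  if (!all(unique(y_test) %in% unique(y_train)))
    stop("class present in test but absent from training data")
  if (!allow_small &&
      nrow(X_train) < min_obs_per_predictor * ncol(X_train))
    stop(sprintf(paste0("only %.1f training observations per predictor ",
                        "(< %d); reduce predictors or set allow_small = TRUE"),
                 nrow(X_train) / ncol(X_train), min_obs_per_predictor))
  grid <- if (is.null(model$grid)) list(NULL) else model$grid(ncol(X_train))
  best_par <- NULL
  if (length(grid) > 1L) {
    splits <- .cv_splits(cv, nrow(X_train), stratify = y_train)
    cv_acc <- vapply(grid, function(par) {
      mean(vapply(splits, function(s) {
        set.seed(cv$seed)
        fit <- model$fit(X_train[s$train, , drop = FALSE], y_train[s$train],
                         par)
        mean(model$predict(fit, X_train[s$test, , drop = FALSE]) ==
               y_train[s$test])
      }, numeric(1L)))
    }, numeric(1L))
    best_par <- grid[[which.max(cv_acc)]]
  } else if (length(grid) == 1L && !is.null(grid[[1L]])) {
    best_par <- grid[[1L]]
  }
  set.seed(cv$seed)
  fit <- if (is.null(best_par)) model$fit(X_train, y_train) else
    model$fit(X_train, y_train, best_par)
  pred <- model$predict(fit, X_test)
  levs <- sort(unique(c(y_train, y_test)))
  confusion <- table(factor(y_test, levels = levs),
                     factor(pred, levels = levs))
  per_class <- t(vapply(levs, function(lv) {
    tp <- sum(pred == lv & y_test == lv)
    fn <- sum(pred != lv & y_test == lv)
    fp <- sum(pred == lv & y_test != lv)
    tn <- sum(pred != lv & y_test != lv)
    c(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp) tn / (tn + fp) else NA_real_)
  }, numeric(2L)))
  structure(list(accuracy = mean(pred == y_test),
                 kappa = cohens_kappa(confusion),
                 confusion = confusion, per_class = per_class,
                 tuned = best_par, model = fit),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("model_evaluation: accuracy %.3f, kappa %.3f\n",
              x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
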