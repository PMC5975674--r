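#' Per-feature missing fraction
#'
#' @param m an `omics_matrix`.
#' @return named numeric vector in \[0, 1\], one entry per feature.
#' @export
missingness_profile <- function(m) {
  rowMeans(m$missing_mask)
}

#' Missing-data handling policy
#'
#' Features with a missing fraction strictly below `threshold` are imputed
#' with `low_method`; features at or above it are either collapsed to a
#' presence/absence row (`high_action = "binarize"`) or imputed and flagged
#' (`"impute_flagged"`). The boundary is deliberately strict: exactly 10%
#' missing goes to the high branch.
#'
#' @param threshold fraction in (0, 1); default 0.10.
#' @param low_method one of `"mean"`, `"knn_mean"`, `"zero"`, `"llq"`,
#'   `"llq_half"`, `"llq_sqrt2"`.
#' @param high_action `"binarize"` or `"impute_flagged"`.
#' @param knn_k neighbours for `knn_mean`; default 5.
#' @return a `missing_policy` object.
#' @export
missing_policy <- function(threshold = 0.10, low_method = "mean",
                           high_action = c("binarize", "impute_flagged"),
                           knn_k = 5L) {
  stopifnot(threshold > 0, threshold < 1, knn_k >= 1L)
  low_method <- match.arg(low_method, c("mean", "knn_mean", "zero",
                                        "llq", "llq_half", "llq_sqrt2"))
  structure(list(threshold = threshold, low_method = low_method,
                 high_action = match.arg(high_action),
                 knn_k = as.integer(knn_k)),
            class = "missing_policy")
}

# Sample-by-sample distances on mutually observed, feature-z-scored values;
# used only to pick imputation neighbours.
.knn_sample_distances <- function(vals, mask) {
  mu <- rowMeans(ifelse(mask, NA, vals), na.rm = TRUE)
  sd_ <- apply(ifelse(mask, NA, vals), 1L, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  z <- (vals - mu) / sd_
  z[mask] <- NA_real_
  n <- ncol(vals)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- !mask[, i] & !mask[, j]
    if (any(shared)) {
      d <- sqrt(mean((z[shared, i] - z[shared, j])^2))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Impute missing cells of an omics matrix
#'
#' Methods: `mean` (feature mean of observed values), `knn_mean` (mean of
#' the feature's values in the `knn_k` nearest samples by Euclidean
#' distance over mutually observed z-scored features), `zero`, and the
#' below-LLQ conventions `llq`, `llq_half` (LLQ/2) and `llq_sqrt2`
#' (LLQ/sqrt(2)).
#'
#' @param m an `omics_matrix`.
#' @param method imputation method (see above).
#' @param llq LLQ value for the llq-based methods; defaults to `m$llq`.
#' @param knn_k neighbours for `knn_mean`.
#' @param features optional feature ids to treat; default all with missing.
#' @return an `omics_matrix` with treated cells filled and unmasked; the
#'   attribute `"imputed"` records (feature, sample, method, value) per cell.
#' @export
impute_missing <- function(m, method = "mean", llq = m$llq, knn_k = 5L,
                           features = NULL) {
  method <- match.arg(method, c("mean", "knn_mean", "zero",
                                "llq", "llq_half", "llq_sqrt2"))
  if (startsWith(method, "llq") && is.null(llq))
    stop("method '", method, "' requires an LLQ value")
  vals <- m$values
  mask <- m$missing_mask
  vals[mask] <- NA_real_
  if (is.null(features)) features <- rownames(vals)[rowSums(mask) > 0L]
  rec <- list()
  fill_const <- switch(method, zero = 0, llq = llq, llq_half = llq / 2,
                       llq_sqrt2 = llq / sqrt(2), NULL)
  if (method == "knn_mean" && length(features))
    D <- .knn_sample_distances(vals, mask)
  for (f in features) {
    idx <- which(mask[f, ])
    if (!length(idx)) next
    obs <- which(!mask[f, ])
    filled <- if (!is.null(fill_const)) {
      rep(fill_const, length(idx))
    } else if (method == "mean") {
      if (!length(obs)) stop("feature '", f, "' has no observed values to average")
      rep(mean(vals[f, obs]), length(idx))
    } else { # knn_mean
      if (!length(obs)) stop("feature '", f, "' has no observed values to average")
      vapply(idx, function(s) {
        cand <- obs[order(D[s, obs], decreasing = FALSE)]
        cand <- cand[is.finite(D[s, cand])]
        if (!length(cand)) return(mean(vals[f, obs]))
        mean(vals[f, cand[seq_len(min(knn_k, length(cand)))]])
      }, numeric(1L))
    }
    vals[f, idx] <- filled
    mask[f, idx] <- FALSE
    rec[[f]] <- data.frame(feature = f, sample = colnames(vals)[idx],
                           method = method, value = filled,
                           stringsAsFactors = FALSE)
  }
  out <- omics_matrix(vals, platform = m$platform, missing_mask = mask,
                      llq = m$llq)
  attr(out, "imputed") <- if (length(rec)) do.call(rbind, rec) else
    data.frame(feature = character(), sample = character(),
               method = character(), value = numeric())
  out
}

#' Apply the missing-data decision procedure
#'
#' Features whose missing fraction is strictly below the policy threshold
#' are imputed with the policy's low method; features at or above it are
#' either removed from the numeric matrix and emitted as presence/absence
#' rows (1 = observed) or imputed with a flag, per `high_action`.
#'
#' @param m an `omics_matrix`.
#' @param policy a `missing_policy`.
#' @return list with `matrix` (imputed `omics_matrix`), `binarized`
#'   (presence/absence matrix or NULL) and `report` (a `preprocess_report`).
#' @export
apply_missing_policy <- function(m, policy = missing_policy()) {
  frac <- missingness_profile(m)
  low <- names(frac)[frac > 0 & frac < policy$threshold]
  high <- names(frac)[frac >= policy$threshold]
  binarized <- NULL
  flagged <- character()
  out <- impute_missing(m, policy$low_method, knn_k = policy$knn_k,
                        features = low)
  imputed <- attr(out, "imputed")
  if (length(high)) {
    if (policy$high_action == "binarize") {
      binarized <- 1 * !m$missing_mask[high, , drop = FALSE]
      keep <- setdiff(rownames(out$values), high)
      out <- omics_matrix(out$values[keep, , drop = FALSE],
                          platform = m$platform,
                          missing_mask = out$missing_mask[keep, , drop = FALSE],
                          llq = m$llq)
    } else {
      out <- impute_missing(out, policy$low_method, knn_k = policy$knn_k,
                            features = high)
      imputed <- rbind(imputed, attr(out, "imputed"))
      flagged <- high
    }
  }
  report <- structure(list(
    missing_fraction = frac,
    n_imputed = nrow(imputed),
    imputed = imputed,
    binarized_features = if (is.null(binarized)) character() else high,
    flagged_features = flagged,
    threshold = policy$threshold,
    low_method = policy$low_method,
    high_action = policy$high_action), class = "preprocess_report")
  list(matrix = out, binarized = binarized, report = report)
}

#' Chi-square test for a difference in detection rates
#'
#' Pearson chi-square (no continuity correction, df = 1) on the 2x2
#' detected-by-group table. Used on presence/absence rows produced by the
#' missing-data procedure.
#'
#' @param present logical per sample: was the feature detected.
#' @param groups two-level factor/vector per sample.
#' @return a `handprint_test` with `statistic`, `p`, `df`.
#' @export
detection_rate_test <- function(present, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("detection_rate_test needs exactly 2 groups")
  if (any(table(groups) == 0L)) stop("both groups must be non-empty")
  tab <- table(factor(present, levels = c(FALSE, TRUE)), groups)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate 2x2 table (zero margin); p set to 1")
    return(test_result(0, 1, df = 1L))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(unname(ct$statistic), unname(ct$p.value), df = 1L)
}

#' Flag (never remove) outlying values
#'
#' A value is flagged when its robust z-score |x - median| / (1.4826 * MAD)
#' exceeds `robust_z_cut`. Values are left untouched; biological outliers
#' are retained and flagged for downstream scrutiny.
#'
#' @param m an `omics_matrix`.
#' @param robust_z_cut cut-off on the robust z; default 5.
#' @return data.frame (feature, sample, value, robust_z) of flags.
#' @export
flag_outliers <- function(m, robust_z_cut = 5) {
  vals <- m$values
  vals[m$missing_mask] <- NA_real_
  flags <- list()
  skipped <- character()
  for (f in rownames(vals)) {
    x <- vals[f, ]
    obs <- which(!is.na(x))
    if (length(obs) < 3L) next
    med <- stats::median(x[obs])
    madv <- stats::mad(x[obs])  # includes the 1.4826 consistency constant
    if (madv == 0) { skipped <- c(skipped, f); next }
    z <- abs(x[obs] - med) / madv
    hit <- obs[z > robust_z_cut]
    if (length(hit))
      flags[[f]] <- data.frame(feature = f, sample = colnames(vals)[hit],
                               value = x[hit], robust_z = z[z > robust_z_cut],
                               stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("MAD = 0 for ", length(skipped),
            " feature(s); skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  if (!length(flags))
    return(data.frame(feature = character(), sample = character(),
                      value = numeric(), robust_z = numeric()))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Location-scale batch adjustment
#'
#' Per feature, each batch is centred to the feature's grand mean and
#' scaled to the pooled within-batch standard deviation. This removes
#' additive and multiplicative batch offsets while preserving each
#' feature's grand mean exactly.
#'
#' @param m an `omics_matrix` with no missing cells.
#' @param batch batch label per sample (>= 2 batches, each >= 2 samples).
#' @return adjusted `omics_matrix`.
#' @export
adjust_batch <- function(m, batch) {
  if (any(m$missing_mask)) stop("adjust_batch requires a complete matrix")
  batch <- as.factor(batch)
  if (length(batch) != ncol(m$values))
    stop("batch length must equal sample count")
  sizes <- table(batch)
  if (nlevels(batch) < 2L) stop("need at least 2 batches")
  if (any(sizes < 2L))
    stop("singleton batch(es): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  vals <- m$values
  n <- ncol(vals)
  B <- nlevels(batch)
  out <- vals
  for (f in seq_len(nrow(vals))) {
    x <- vals[f, ]
    g <- mean(x)
    vars <- tapply(x, batch, stats::var)
    pooled <- sqrt(sum((sizes - 1L) * vars) / (n - B))
    for (b in levels(batch)) {
      idx <- which(batch == b)
      mu_b <- mean(x[idx])
      sd_b <- stats::sd(x[idx])
      out[f, idx] <- if (sd_b > 0 && pooled > 0)
        (x[idx] - mu_b) / sd_b * pooled + g else x[idx] - mu_b + g
    }
  }
  omics_matrix(out, platform = m$platform, llq = NULL)
}

#' Z-normalize features
#'
#' Each feature is centred to mean 0 and scaled to sample SD 1 (ddof = 1).
#' Constant features are dropped with a warning. Required before any
#' distance computation so that no feature dominates by scale.
#'
#' @param m an `omics_matrix` with no missing cells.
#' @return z-scored `omics_matrix` (LLQ no longer meaningful, dropped).
#' @export
znormalize <- function(m) {
  if (any(m$missing_mask)) stop("znormalize requires a complete matrix")
  vals <- m$values
  mu <- rowMeans(vals)
  sd_ <- apply(vals, 1L, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature(s)")
    vals <- vals[!const, , drop = FALSE]
    mu <- mu[!const]; sd_ <- sd_[!const]
  }
  omics_matrix((vals - mu) / sd_, platform = m$platform, llq = NULL)
}
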