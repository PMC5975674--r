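#' Survival-anchored feature filter
#'
#' For each feature, fits the linear model
#' `value ~ intercept + vital_status + survival_time` and tests the vital
#' status coefficient with a two-sided t-test. Features with a nominal
#' p strictly below `alpha` are kept. No FDR correction is applied at this
#' stage (by design, significance here is a filter, not an inference);
#' FDR enters later at the signature stage. Censored patients are included
#' with their observed time: the model is an ordinary linear model, not a
#' censoring-aware survival model.
#'
#' `survival_time` should be the total days lived (enrolment age in days
#' plus post-enrolment survival), taken from the clinical table column
#' `survival_time_days`.
#'
#' @param m a complete (no missing cells) `omics_matrix`, samples aligned
#'   with `clinical`.
#' @param clinical a `clinical_table` with the same samples in the same
#'   order.
#' @param alpha nominal significance level; default 0.05 (strict `<`).
#' @return a `filter_result`: list with `platform`, `kept` (feature ids),
#'   `stats` (feature, effect, p), `alpha`, `n_before`, `n_after`.
#' @export
survival_filter <- function(m, clinical, alpha = 0.05) {
  if (any(m$missing_mask)) stop("survival_filter requires a complete matrix")
  if (!identical(colnames(m$values), clinical$sample_id))
    stop("samples of matrix and clinical table are not aligned")
  X <- cbind(intercept = 1,
             vital_status = clinical$vital_status,
             survival_time = clinical$survival_time_days)
  sds <- apply(m$values, 1L, stats::sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant feature(s); assigned p = 1, never kept")
  r <- .ols_rows(m$values, X, coef_index = 2L)
  r$p[const] <- 1
  r$estimate[const] <- 0
  stats_df <- data.frame(feature = rownames(m$values),
                         effect = r$estimate, p = r$p,
                         stringsAsFactors = FALSE, row.names = NULL)
  kept <- stats_df$feature[stats_df$p < alpha]
  structure(list(platform = m$platform, kept = kept, stats = stats_df,
                 alpha = alpha, n_before = nrow(m$values),
                 n_after = length(kept)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result '%s': kept %d of %d features (alpha = %g)\n",
              x$platform, x$n_after, x$n_before, x$alpha))
  invisible(x)
}

#' Keep only the selected features of a matrix
#'
#' @param m an `omics_matrix`.
#' @param fr a `filter_result` (or character vector of feature ids).
#' @return the subset `omics_matrix`.
#' @export
apply_filter <- function(m, fr) {
  keep <- if (is.character(fr)) fr else fr$kept
  keep <- intersect(rownames(m$values), keep)
  omics_matrix(m$values[keep, , drop = FALSE], platform = m$platform,
               missing_mask = m$missing_mask[keep, , drop = FALSE],
               llq = m$llq)
}

#' Generic single-criterion feature filters
#'
#' * `variance_top_q`: keep the `ceiling(threshold * n)` features of
#'   highest variance (threshold is the kept fraction).
#' * `abs_foldchange`: keep features whose observed dynamic range
#'   (max - min) is at least `threshold`.
#' * `correlation_with`: keep features whose absolute Pearson correlation
#'   with `ref` is at least `threshold`.
#'
#' Ties are broken by lexicographic feature id so the result is
#' deterministic.
#'
#' @param m a complete `omics_matrix`.
#' @param criterion one of `"variance_top_q"`, `"abs_foldchange"`,
#'   `"correlation_with"`.
#' @param threshold criterion parameter (see above).
#' @param ref reference sample-length vector for `correlation_with`.
#' @return a `filter_result` (the `stats` column `score` holds the
#'   criterion value).
#' @export
generic_filter <- function(m, criterion = c("variance_top_q",
                                            "abs_foldchange",
                                            "correlation_with"),
                           threshold, ref = NULL) {
  criterion <- match.arg(criterion)
  if (any(m$missing_mask)) stop("generic_filter requires a complete matrix")
  vals <- m$values
  ord_ids <- sort(rownames(vals), method = "radix")
  if (criterion == "variance_top_q") {
    if (threshold <= 0 || threshold > 1)
      stop("variance_top_q threshold must be in (0, 1]")
    score <- apply(vals, 1L, stats::var)
    n_keep <- ceiling(threshold * nrow(vals))
    # order by decreasing score, ties by feature id
    o <- order(-score, rownames(vals), method = "radix")
    kept <- rownames(vals)[o][seq_len(n_keep)]
  } else if (criterion == "abs_foldchange") {
    if (threshold < 0) stop("abs_foldchange threshold must be nonnegative")
    score <- apply(vals, 1L, function(x) max(x) - min(x))
    kept <- rownames(vals)[score >= threshold]
  } else {
    if (is.null(ref) || length(ref) != ncol(vals))
      stop("correlation_with requires a reference vector of sample length")
    if (threshold < 0 || threshold > 1)
      stop("correlation threshold must be in [0, 1]")
    score <- apply(vals, 1L, function(x) {
      if (stats::sd(x) == 0) return(0)
      abs(stats::cor(x, ref))
    })
    kept <- rownames(vals)[score >= threshold]
  }
  kept <- kept[order(match(kept, ord_ids))]
  structure(list(platform = m$platform, kept = kept,
                 stats = data.frame(feature = rownames(vals), score = score,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 alpha = NA_real_, n_before = nrow(vals),
                 n_after = length(kept)),
            class = "filter_result")
}
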