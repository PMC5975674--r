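#' Test-result container
#'
#' @param statistic test statistic.
#' @param p p-value in \[0, 1\].
#' @param df degrees of freedom (if applicable).
#' @param ... further named fields (estimate, se, ...).
#' @return a `handprint_test` list.
#' @export
test_result <- function(statistic, p, df = NULL, ...) {
  stopifnot(p >= 0, p <= 1)
  structure(c(list(statistic = statistic, p = p, df = df), list(...)),
            class = "handprint_test")
}

#' @export
print.handprint_test <- function(x, ...) {
  cat(sprintf("statistic = %.6g, df = %s, p = %.4g\n", x$statistic,
              if (is.null(x$df)) "NA" else format(x$df), x$p))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_i is the smallest m * p_(j) / j over all
#' p_(j) >= p_i, clipped to 1, returned in the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

# Multi-response OLS: fit every row of Y (features x samples) on the same
# design and return the t-test of one coefficient per feature. Vectorized;
# this is the workhorse behind survival_filter and one_vs_rest.
.ols_rows <- function(Y, X, coef_index) {
  n <- ncol(Y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  XtXinv <- chol2inv(qr.R(qx))
  H <- XtXinv %*% t(X)                     # p x n
  B <- H %*% t(Y)                          # p x features
  fitted <- X %*% B                        # n x features
  rss <- colSums((t(Y) - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXinv[coef_index, coef_index])
  est <- B[coef_index, ]
  tstat <- est / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # (near-)perfect fits: the residual is numerical noise, so the t ratio is
  # meaningless. A coefficient at noise level gets t = 0, p = 1; a real
  # coefficient with zero residual is infinitely significant.
  mu_y <- rowMeans(Y)
  tss <- rowSums((Y - mu_y)^2)
  exact <- rss <= 1e-12 * pmax(tss, 1)
  if (any(exact)) {
    scale_y <- sqrt(pmax(tss, 1e-300) / (n - 1))
    big <- exact & abs(est) > 1e-8 * scale_y
    tstat[exact] <- 0; pval[exact] <- 1; est[exact & !big] <- 0
    tstat[big] <- Inf * sign(est[big]); pval[big] <- 0
  }
  degen <- !is.finite(tstat) & !(pval %in% c(0, 1))
  tstat[degen] <- 0; pval[degen] <- 1
  data.frame(estimate = est, se = se, t = tstat, p = pval,
             row.names = rownames(Y), stringsAsFactors = FALSE)
}

#' t-test of a single OLS coefficient
#'
#' Fits y on the given design (which must include its own intercept
#' column) and returns the two-sided t-test for the coefficient at
#' `coef_index`, with df = n - ncol(X). The t reference distribution is
#' used (not the normal) for small-n correctness.
#'
#' @param y numeric response.
#' @param X design matrix including an intercept column.
#' @param coef_index column index of the coefficient to test.
#' @return a `handprint_test` with `estimate` and `se` fields.
#' @export
ols_coef_test <- function(y, X, coef_index = 2L) {
  X <- as.matrix(X)
  r <- .ols_rows(matrix(y, nrow = 1L), X, coef_index)
  test_result(r$t, r$p, df = length(y) - ncol(X),
              estimate = r$estimate, se = r$se)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored observations reduce the risk set without contributing
#' events.
#'
#' @param time nonnegative times (days).
#' @param event logical/0-1: TRUE for an observed death.
#' @return data.frame (time, n_risk, n_event, surv) over distinct event or
#'   censoring times; `surv` is non-increasing with S(0) = 1 implied.
#' @export
km_estimate <- function(time, event) {
  stopifnot(all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test across g groups
#'
#' Standard (g - 1)-df chi-square comparing observed and expected events
#' per group, with ties handled by the hypergeometric variance.
#'
#' @param time nonnegative times.
#' @param event logical/0-1 event indicator.
#' @param groups group label per sample (>= 2 non-empty groups).
#' @return a `handprint_test`.
#' @export
log_rank_test <- function(time, event, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (sum(event) == 0L) {
    warning("no events in any group; log-rank p set to 1")
    return(test_result(0, 1, df = nlevels(groups) - 1L))
  }
  sd_ <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ groups)
  df <- length(sd_$n) - 1L
  test_result(unname(sd_$chisq),
              stats::pchisq(sd_$chisq, df, lower.tail = FALSE), df = df)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic against a chi-square with g - 1 df.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 non-empty groups).
#' @return a `handprint_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(unique(values)) == 1L) {
    warning("all values tied; Kruskal-Wallis p set to 1")
    return(test_result(0, 1, df = nlevels(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  test_result(unname(kt$statistic), unname(kt$p.value),
              df = unname(kt$parameter))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; rows/columns with a zero margin are dropped
#' with a warning before testing.
#'
#' @param tab r x c contingency table of nonnegative counts.
#' @return a `handprint_test` with df = (r - 1)(c - 1).
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2L, ncol(tab) >= 2L)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s) from the contingency table")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("degenerate table after dropping zero margins; p set to 1")
    return(test_result(0, 1, df = 1L))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(unname(ct$statistic), unname(ct$p.value),
              df = unname(ct$parameter))
}

#' Hypergeometric upper-tail probability
#'
#' P\[X >= overlap\] when `signature_size` items are drawn without
#' replacement from a universe of `universe_size` containing `set_size`
#' marked items. The enrichment p-value for a gene-set overlap.
#'
#' @param overlap observed overlap count.
#' @param set_size gene-set size (within the universe).
#' @param signature_size signature size (within the universe).
#' @param universe_size background size.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(overlap, set_size, signature_size, universe_size) {
  if (overlap > min(set_size, signature_size) ||
      set_size > universe_size || signature_size > universe_size ||
      overlap < 0)
    stop("impossible hypergeometric counts")
  stats::phyper(overlap - 1, set_size, universe_size - set_size,
                signature_size, lower.tail = FALSE)
}

#' Cohen's kappa from a confusion matrix
#'
#' @param confusion square matrix, rows = reference, columns = predicted.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}
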