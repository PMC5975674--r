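#' Specification of a synthetic multi-omics cohort
#'
#' The generator plants `k_clusters` patient subtypes expressed as
#' mean-shifted feature blocks distributed complementarily across views:
#' each view's informative features separate only the clusters listed in
#' its `separates` entry (the first listed cluster and all unlisted
#' clusters share the baseline mean), so no single view can resolve the
#' full structure but their fusion can. Survival is exponential with a
#' cluster-specific hazard on top of an enrolment age drawn in days;
#' right-censoring is administrative at the horizon that hits the
#' requested censoring fraction. Optional MCAR missingness, below-LLQ
#' truncation, and additive batch offsets complete the emulation.
#'
#' The defaults are the package's reference study conditions: 150
#' patients, 3 balanced subtypes, 3 views of 200 features with 30
#' informative each at effect size delta = 1.5 SD units over unit noise,
#' each view separating a different pair of clusters; cluster hazards
#' 1/250, 1/350 and 1/2800 per day (about 11-fold ratio between extremes,
#' unevenly spaced so every cluster's death probability differs from the
#' cohort mean by at least ~0.2) with 30% censoring; no missingness or
#' batch structure unless requested.
#'
#' @param n_samples cohort size.
#' @param k_clusters number of planted subtypes.
#' @param proportions cluster proportions (sum to 1); default balanced.
#' @param views list of per-view lists with `name`, `n_features`,
#'   `n_informative`, `delta`, `sigma`, `separates` (integer pair of
#'   cluster ids the view can tell apart).
#' @param hazards per-cluster exponential hazard (events/day).
#' @param censoring_fraction target fraction censored; default 0.3.
#' @param age_mean_days,age_sd_days enrolment-age distribution; defaults
#'   60 years +/- 10 years in days.
#' @param mcar_rate MCAR missingness rate; default 0.
#' @param llq_quantile per-view quantile below which values are censored
#'   to missing with the LLQ recorded; default 0.
#' @param n_batches,batch_sd batch count and additive offset SD; defaults
#'   1 and 0 (no batch structure).
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 150L, k_clusters = 3L,
                           proportions = NULL, views = NULL,
                           hazards = NULL, censoring_fraction = 0.3,
                           age_mean_days = 21900, age_sd_days = 3650,
                           mcar_rate = 0, llq_quantile = 0,
                           n_batches = 1L, batch_sd = 0, seed = 1L) {
  if (is.null(proportions)) proportions <- rep(1 / k_clusters, k_clusters)
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            length(proportions) == k_clusters)
  if (is.null(views)) {
    pairs <- if (k_clusters >= 3L) list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
    else if (k_clusters == 2L) list(c(1L, 2L))
    else list(c(1L, 1L))
    views <- lapply(1:3, function(v)
      list(name = c("mrna", "methylation", "mirna")[v], n_features = 200L,
           n_informative = 30L, delta = 1.5, sigma = 1,
           separates = pairs[[((v - 1L) %% length(pairs)) + 1L]]))
  }
  for (v in views) {
    stopifnot(v$n_informative <= v$n_features, v$sigma > 0)
    stopifnot(all(v$separates %in% seq_len(k_clusters)))
  }
  if (is.null(hazards)) {
    # deliberately uneven spacing: under the target censoring every
    # cluster's death probability must differ from the cohort mean by
    # >= ~0.2, otherwise that cluster's survival link vanishes (its
    # vital-status contrast is the distance from the mean death rate)
    base <- c(250, 350, 2800, 8000, 20000)
    hazards <- 1 / base[seq_len(min(k_clusters, 5L))]
    if (k_clusters > 5L)
      hazards <- c(hazards, 1 / (20000 * 2^(seq_len(k_clusters - 5L))))
  }
  stopifnot(length(hazards) == k_clusters, all(hazards > 0),
            censoring_fraction >= 0, censoring_fraction < 1,
            mcar_rate >= 0, mcar_rate < 1,
            llq_quantile >= 0, llq_quantile < 1)
  structure(list(n_samples = as.integer(n_samples),
                 k_clusters = as.integer(k_clusters),
                 proportions = proportions, views = views,
                 hazards = hazards,
                 censoring_fraction = censoring_fraction,
                 age_mean_days = age_mean_days, age_sd_days = age_sd_days,
                 mcar_rate = mcar_rate, llq_quantile = llq_quantile,
                 n_batches = as.integer(n_batches), batch_sd = batch_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Administrative horizon hitting the target censoring fraction for a
# mixture of exponentials: solve mean_c pi_c * exp(-lambda_c * H) = frac.
.censor_horizon <- function(hazards, proportions, frac) {
  if (frac == 0) return(Inf)
  f <- function(H) sum(proportions * exp(-hazards * H)) - frac
  if (f(0) < 0) stop("infeasible censoring fraction")
  stats::uniroot(f, c(0, 1e9), tol = 1e-6)$root
}

#' Generate a synthetic multi-omics cohort
#'
#' See [synthetic_spec()] for the generative model. The global seed is
#' split into fixed per-component child seeds (labels, each view,
#' survival, missingness, batch) so each component is independently
#' reproducible.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `dataset` (a `multi_omics_dataset`) and `labels`
#'   (integer planted-cluster label per sample, named by sample id).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  n <- spec$n_samples
  k <- spec$k_clusters
  ids <- sprintf("P%04d", seq_len(n))
  set.seed(spec$seed)
  labels <- sample(seq_len(k), n, replace = TRUE, prob = spec$proportions)
  # guarantee every cluster is represented
  for (cl in seq_len(k)) if (!any(labels == cl))
    labels[sample.int(n, 1L)] <- cl
  names(labels) <- ids
  views <- vector("list", length(spec$views))
  for (vi in seq_along(spec$views)) {
    v <- spec$views[[vi]]
    set.seed(spec$seed + 1000L * vi)
    vals <- matrix(stats::rnorm(v$n_features * n, sd = v$sigma),
                   v$n_features, n,
                   dimnames = list(sprintf("%s_f%04d", v$name,
                                           seq_len(v$n_features)), ids))
    # cluster-pattern: distinct offsets only for the separable pair;
    # the first listed cluster and all others sit at baseline 0.
    offsets <- rep(0, k)
    offsets[v$separates[2L]] <- v$delta
    if (v$n_informative > 0L) {
      inf_idx <- seq_len(v$n_informative)
      vals[inf_idx, ] <- vals[inf_idx, ] +
        matrix(offsets[labels], length(inf_idx), n, byrow = TRUE)
    }
    views[[vi]] <- omics_matrix(vals, platform = v$name)
  }
  # survival: total days lived = enrolment age + censored exponential time
  set.seed(spec$seed + 7919L)
  age <- pmax(stats::rnorm(n, spec$age_mean_days, spec$age_sd_days), 3650)
  post <- stats::rexp(n, rate = spec$hazards[labels])
  H <- .censor_horizon(spec$hazards, spec$proportions,
                       spec$censoring_fraction)
  event <- post <= H
  post_obs <- pmin(post, H)
  clinical <- clinical_table(
    ids, vital_status = as.integer(event),
    survival_time_days = age + post_obs,
    covariates = data.frame(enrolment_age_days = age,
                            post_enrolment_days = post_obs))
  # MCAR + below-LLQ missingness
  llqs <- vector("list", length(views))
  if (spec$mcar_rate > 0 || spec$llq_quantile > 0) {
    set.seed(spec$seed + 104729L)
    for (vi in seq_along(views)) {
      vals <- views[[vi]]$values
      mask <- views[[vi]]$missing_mask
      llq <- NULL
      if (spec$llq_quantile > 0) {
        shift <- min(vals)       # keep values nonnegative for LLQ semantics
        vals <- vals - shift
        llq <- stats::quantile(vals, spec$llq_quantile, names = FALSE)
        mask <- mask | (vals < llq)
      }
      if (spec$mcar_rate > 0)
        mask <- mask | (matrix(stats::runif(length(vals)), nrow(vals))
                        < spec$mcar_rate)
      vals[mask] <- NA_real_
      views[[vi]] <- omics_matrix(vals, platform = views[[vi]]$platform,
                                  missing_mask = mask, llq = llq)
    }
  }
  # additive batch offsets
  batch <- NULL
  if (spec$n_batches > 1L) {
    set.seed(spec$seed + 224737L)
    batch <- sprintf("B%d", sample(rep_len(seq_len(spec$n_batches), n)))
    for (vi in seq_along(views)) {
      off <- matrix(stats::rnorm(nrow(views[[vi]]$values) * spec$n_batches,
                                 sd = spec$batch_sd),
                    nrow(views[[vi]]$values), spec$n_batches)
      vals <- views[[vi]]$values +
        off[, as.integer(factor(batch, levels = sprintf("B%d", seq_len(spec$n_batches))))]
      vals[views[[vi]]$missing_mask] <- NA_real_
      views[[vi]] <- omics_matrix(vals, platform = views[[vi]]$platform,
                                  missing_mask = views[[vi]]$missing_mask,
                                  llq = views[[vi]]$llq)
    }
    clinical$batch <- batch
  }
  dataset <- align_samples(views, clinical)
  labels <- labels[dataset$clinical$sample_id]
  list(dataset = dataset, labels = labels)
}

#' Summarize a synthetic cohort against its planted structure
#'
#' @param dataset a `multi_omics_dataset`.
#' @param labels planted cluster label per sample.
#' @return list with per-view realized missing fractions, per-view
#'   between/within-cluster variance ratios, the realized censoring rate,
#'   and per-cluster Kaplan-Meier median post-enrolment survival.
#' @export
summarize_cohort <- function(dataset, labels) {
  miss <- vapply(dataset$views, function(v) mean(v$missing_mask), numeric(1L))
  names(miss) <- vapply(dataset$views, `[[`, character(1L), "platform")
  vr <- vapply(dataset$views, function(v) {
    vals <- v$values
    vals[v$missing_mask] <- NA_real_
    gm <- rowMeans(vals, na.rm = TRUE)
    cl_means <- sapply(sort(unique(labels)), function(cl)
      rowMeans(vals[, labels == cl, drop = FALSE], na.rm = TRUE))
    between <- rowMeans((cl_means - gm)^2)
    within <- apply(vals, 1L, stats::var, na.rm = TRUE)
    mean(between / within, na.rm = TRUE)
  }, numeric(1L))
  names(vr) <- names(miss)
  clin <- dataset$clinical
  post <- if ("post_enrolment_days" %in% names(clin))
    clin$post_enrolment_days else clin$survival_time_days
  med <- vapply(sort(unique(labels)), function(cl) {
    idx <- labels == cl
    km <- km_estimate(post[idx], clin$vital_status[idx])
    below <- which(km$surv <= 0.5)
    if (length(below)) km$time[min(below)] else NA_real_
  }, numeric(1L))
  names(med) <- paste0("cluster", sort(unique(labels)))
  list(missing_fraction = miss, variance_ratio = vr,
       censoring_rate = mean(clin$vital_status == 0L),
       km_median_days = med)
}
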