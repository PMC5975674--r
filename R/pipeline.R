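#' Pipeline configuration
#'
#' @param alpha_filter nominal level of the survival-anchored feature
#'   filter; default 0.05.
#' @param alpha_survival level for the cluster-number survival
#'   constraints; default 0.05.
#' @param min_cluster_size smallest admissible cluster; default 10.
#' @param k_range candidate cluster numbers; default 2:12.
#' @param snf an `snf_params` or NULL (defaults from the sample count).
#' @param consensus_B,consensus_frac consensus-clustering resample count
#'   and subsample fraction.
#' @param fdr_q FDR threshold for signature calls; default 0.05.
#' @param dis_tolerance relative DIS slack in the largest-k rule.
#' @param filter apply the survival filter (it is an optional stage).
#' @param seed master seed for all stochastic stages.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(alpha_filter = 0.05, alpha_survival = 0.05,
                            min_cluster_size = 10L, k_range = 2:12,
                            snf = NULL, consensus_B = 100L,
                            consensus_frac = 0.8, fdr_q = 0.05,
                            dis_tolerance = 0.10, filter = TRUE,
                            seed = 1L) {
  stopifnot(alpha_filter > 0, alpha_filter < 1,
            alpha_survival > 0, alpha_survival < 1,
            min_cluster_size >= 1L, all(k_range >= 2L))
  structure(list(alpha_filter = alpha_filter,
                 alpha_survival = alpha_survival,
                 min_cluster_size = as.integer(min_cluster_size),
                 k_range = as.integer(k_range), snf = snf,
                 consensus_B = as.integer(consensus_B),
                 consensus_frac = consensus_frac, fdr_q = fdr_q,
                 dis_tolerance = dis_tolerance, filter = filter,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the four-step handprint pipeline
#'
#' Chains: per-view missing-data handling and z-normalization; optional
#' survival-anchored feature filtering; per-view affinity construction and
#' similarity network fusion; subsampled consensus spectral clustering
#' with constrained selection of the cluster number; and one-vs-rest
#' differential signatures per platform. All stochastic stages derive
#' their seeds from `config$seed`, so a rerun with the same inputs is
#' byte-identical. When `out_dir` is given the labels, per-k stability
#' table and per-platform signature tables are written as TSV together
#' with a JSON manifest (parameters, seed, per-file MD5 hashes).
#'
#' @param dataset a `multi_omics_dataset` (already sample-aligned).
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @return a `handprint` object: list with `assignment`
#'   (`cluster_assignment`), `consensus` (`consensus_result`), `fused`
#'   (`affinity_matrix`), `filters`, `signatures` (per platform, per
#'   cluster), and `manifest`.
#' @export
run_handprint <- function(dataset, config = pipeline_config(),
                          out_dir = NULL) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  clinical <- dataset$clinical
  n <- nrow(clinical)
  k_range <- config$k_range[config$k_range < n]
  # Stage 1-2: missing-data handling, normalization, optional filter
  views <- lapply(dataset$views, function(v) {
    if (any(v$missing_mask))
      v <- apply_missing_policy(v, missing_policy())$matrix
    znormalize(v)
  })
  filters <- NULL
  if (config$filter) {
    filters <- lapply(views, survival_filter, clinical = clinical,
                      alpha = config$alpha_filter)
    views <- mapply(function(v, f) {
      if (f$n_after >= 2L) apply_filter(v, f) else v
    }, views, filters, SIMPLIFY = FALSE)
  }
  # Stage 3: affinities, fusion, consensus, k selection
  params <- config$snf %||% snf_params(n)
  affinities <- lapply(views, function(v)
    affinity_from_distance(pairwise_distance(v), params))
  fused <- snf(affinities, params)
  set.seed(config$seed)
  cr <- consensus_cluster(fused, k_range = k_range, B = config$consensus_B,
                          frac = config$consensus_frac, seed = config$seed)
  assignment <- select_k(cr, clinical,
                         min_cluster_size = config$min_cluster_size,
                         alpha = config$alpha_survival,
                         dis_tolerance = config$dis_tolerance)
  # Stage 4: one-vs-rest signatures per platform
  signatures <- lapply(views, function(v) {
    sigs <- lapply(sort(unique(assignment$labels)), function(cl)
      one_vs_rest(v, assignment$labels, cl, q_threshold = config$fdr_q))
    names(sigs) <- paste0("cluster", sort(unique(assignment$labels)))
    sigs
  })
  names(signatures) <- vapply(views, `[[`, character(1L), "platform")
  manifest <- list(
    seed = config$seed,
    n_samples = n,
    k_selected = assignment$k,
    k_range = k_range,
    snf_params = unclass(params),
    consensus = list(B = config$consensus_B, frac = config$consensus_frac),
    filter = config$filter,
    alpha_filter = config$alpha_filter,
    n_features = lapply(views, function(v) nrow(v$values)))
  result <- structure(list(assignment = assignment, consensus = cr,
                           fused = fused, filters = filters,
                           signatures = signatures, manifest = manifest),
                      class = "handprint")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    lab_path <- file.path(out_dir, "labels.tsv")
    utils::write.table(
      data.frame(sample_id = assignment$sample_ids,
                 cluster = assignment$labels),
      lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, lab_path)
    dis_path <- file.path(out_dir, "stability.tsv")
    utils::write.table(assignment$rationale, dis_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, dis_path)
    for (pf in names(signatures)) for (cl in names(signatures[[pf]])) {
      sp <- file.path(out_dir, sprintf("signature_%s_%s.tsv", pf, cl))
      utils::write.table(signatures[[pf]][[cl]]$stats, sp, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, sp)
    }
    manifest$files <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' @export
print.handprint <- function(x, ...) {
  cat(sprintf("handprint: k = %d clusters over %d samples\n",
              x$assignment$k, length(x$assignment$labels)))
  nsig <- vapply(x$signatures, function(pl)
    sum(vapply(pl, function(s) length(s$significant), integer(1L))),
    integer(1L))
  for (pf in names(nsig))
    cat(sprintf("  %s: %d significant one-vs-rest features\n", pf, nsig[pf]))
  invisible(x)
}

#' Reported reference-cohort bookkeeping numbers
#'
#' Reported bookkeeping numbers for the reference TCGA ovarian-carcinoma
#' (OV) cohort analysis this pipeline design targets: nine per-cluster
#' sample sizes, per-platform filtered-feature counts, and a train/test
#' partition. They are carried as data so that internal-consistency
#' checks (cohort size, feature total, holdout arithmetic) recompute the
#' sums rather than hard-code them.
#'
#' @return list with `cluster_sizes` (nine clusters), `cohort_size`,
#'   `filtered_counts` (per platform), `filtered_total`, `train_n`,
#'   `test_n`, `censor_horizon_days`.
#' @export
reference_cohort_numbers <- function() {
  list(
    cluster_sizes = c(C1 = 49L, C2 = 30L, C3 = 75L, C4 = 41L, C5 = 47L,
                      C6 = 52L, C7 = 46L, C8 = 56L, C9 = 57L),
    cohort_size = 453L,
    filtered_counts = c(methylation = 899L, mirna = 37L, mrna = 5817L),
    filtered_total = 6753L,
    train_n = 300L,
    test_n = 153L,
    censor_horizon_days = 4624L)
}
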