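#' One-vs-rest differential signature for a cluster
#'
#' Per feature, fits an ordinary linear model of the value on an intercept
#' and the cluster-membership indicator; the indicator's two-sided t-test
#' p-value (equivalent to a pooled-variance t-test) is
#' Benjamini-Hochberg-adjusted within this platform-by-contrast family.
#' Features with q strictly below `q_threshold` form the significant set;
#' the sign of the indicator coefficient gives the direction (up/down in
#' the cluster).
#'
#' @param m a complete `omics_matrix`.
#' @param labels cluster label per sample (aligned with `m`).
#' @param cluster_id the cluster to contrast against all the rest.
#' @param q_threshold FDR threshold; default 0.05.
#' @return a `signature`: list with `platform`, `cluster`, `stats`
#'   (feature, effect, p, q, direction), `significant`, `q_threshold`.
#' @export
one_vs_rest <- function(m, labels, cluster_id, q_threshold = 0.05) {
  if (any(m$missing_mask)) stop("one_vs_rest requires a complete matrix")
  if (length(labels) != ncol(m$values))
    stop("labels length must equal sample count")
  ind <- as.numeric(labels == cluster_id)
  n_in <- sum(ind)
  if (n_in == 0L || n_in == length(ind))
    stop("cluster must be non-empty and not all samples")
  if (n_in == 1L || length(ind) - n_in == 1L)
    stop("cluster or complement of size 1: no within-group variance")
  X <- cbind(intercept = 1, in_cluster = ind)
  r <- .ols_rows(m$values, X, coef_index = 2L)
  q <- bh_adjust(r$p)
  stats_df <- data.frame(feature = rownames(m$values), effect = r$estimate,
                         p = r$p, q = q,
                         direction = ifelse(r$estimate >= 0, "up", "down"),
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(platform = m$platform, cluster = cluster_id,
                 stats = stats_df,
                 significant = stats_df$feature[stats_df$q < q_threshold],
                 q_threshold = q_threshold),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature '%s' cluster %s vs rest: %d significant at q < %g\n",
              x$platform, x$cluster, length(x$significant), x$q_threshold))
  invisible(x)
}

#' Hypergeometric gene-set enrichment of a signature
#'
#' Each gene set is first intersected with the universe (all measured,
#' mapped genes of the platform - not the whole genome - to control
#' detection bias); terms that become empty are dropped with a warning.
#' For each remaining term the upper hypergeometric tail of the observed
#' overlap is computed and Benjamini-Hochberg-adjusted across terms. The
#' q-value is the minimal false-discovery rate at which the term may be
#' called significant.
#'
#' @param signature_genes character set of signature genes (subset of
#'   `universe`).
#' @param gs a `gene_set_collection`.
#' @param universe character background set.
#' @param q_threshold used only to flag the `significant` column.
#' @return data.frame (term, set_size, overlap, p, q, significant) sorted
#'   by q then term name.
#' @export
enrich <- function(signature_genes, gs, universe, q_threshold = 0.05) {
  signature_genes <- unique(as.character(signature_genes))
  universe <- unique(as.character(universe))
  if (!all(signature_genes %in% universe))
    stop("signature genes must be contained in the universe")
  empty <- data.frame(term = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      significant = logical())
  if (length(signature_genes) == 0L) {
    warning("empty signature; returning empty enrichment table")
    return(empty)
  }
  members <- lapply(gs, function(s) intersect(s$members, universe))
  drop <- lengths(members) == 0L
  if (any(drop)) {
    warning(sum(drop), " term(s) disjoint from the universe dropped")
    members <- members[!drop]
  }
  if (!length(members)) return(empty)
  tab <- data.frame(term = names(members),
                    set_size = lengths(members),
                    overlap = vapply(members, function(mm)
                      length(intersect(mm, signature_genes)), integer(1L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$p <- mapply(hypergeom_tail, tab$overlap, tab$set_size,
                  MoreArgs = list(signature_size = length(signature_genes),
                                  universe_size = length(universe)))
  tab$q <- bh_adjust(tab$p)
  tab$significant <- tab$q < q_threshold
  tab[order(tab$q, tab$term, method = "radix"), , drop = FALSE]
}

#' Map feature ids (e.g. probes) to gene symbols
#'
#' Many-to-one mapping is allowed; duplicate identical rows are ignored.
#'
#' @param feature_ids character vector of features to map.
#' @param mapping 2-column data.frame: feature id, gene symbol.
#' @return character vector of unique mapped genes; attribute
#'   `"n_unmapped"` counts features without a mapping.
#' @export
map_features_to_genes <- function(feature_ids, mapping) {
  mapping <- unique(as.data.frame(mapping)[, 1:2])
  names(mapping) <- c("feature", "gene")
  hit <- mapping$feature %in% feature_ids
  genes <- unique(as.character(mapping$gene[hit]))
  n_unmapped <- length(setdiff(feature_ids, mapping$feature))
  if (length(genes) == 0L)
    warning("none of the ", length(feature_ids), " features could be mapped")
  structure(genes, n_unmapped = n_unmapped)
}
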