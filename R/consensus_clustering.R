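# Connected components of an undirected adjacency (logical matrix), by BFS.
.n_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
  }
  comps
}

# Spectral embedding of an affinity matrix: eigenvectors of the normalized
# affinity D^{-1/2} W D^{-1/2} for its kmax largest eigenvalues (equivalent
# to the bottom eigenvectors of the symmetric normalized Laplacian).
.spectral_embed <- function(W, kmax) {
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  A <- W * outer(dinv, dinv)
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  list(vectors = es$vectors[, seq_len(kmax), drop = FALSE],
       values = es$values)
}

# kmeans++ seeding: first centre uniform, later centres with probability
# proportional to squared distance to the nearest chosen centre.
.kmeanspp_centers <- function(E, k) {
  n <- nrow(E)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((E - matrix(E[centers[1L], ], n, ncol(E), byrow = TRUE))^2)
  if (k > 1L) for (j in 2L:k) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((E - matrix(E[centers[j], ], n, ncol(E),
                                       byrow = TRUE))^2))
  }
  E[centers, , drop = FALSE]
}

# Row-normalized k leading eigenvectors clustered by k-means with seeded
# kmeans++ initialization and nstart restarts; best inertia kept.
.cluster_embedding <- function(vectors, k, nstart = 10L) {
  E <- vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(E^2))
  nrm[nrm == 0] <- 1
  E <- E / nrm
  best <- NULL
  for (r in seq_len(nstart)) {
    ctr <- .kmeanspp_centers(E, k)
    ctr <- ctr + matrix(stats::rnorm(length(ctr), sd = 1e-10), nrow(ctr))
    km <- suppressWarnings(stats::kmeans(E, centers = ctr, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

#' Normalized spectral clustering of an affinity matrix
#'
#' Computes the symmetric normalized Laplacian
#' `L = I - D^{-1/2} W D^{-1/2}`, takes its bottom k eigenvectors,
#' row-normalizes them to the unit sphere, and clusters the rows with
#' k-means (seeded k-means++ initialization, 10 restarts, best inertia
#' kept). Clustering is driven by R's RNG; set a seed for reproducibility.
#'
#' @param W an `affinity_matrix` or plain symmetric matrix.
#' @param k number of clusters, 2 <= k < n.
#' @param nstart k-means restarts; default 10.
#' @return integer cluster labels (1..k), named by sample id.
#' @export
spectral_cluster <- function(W, k, nstart = 10L) {
  M <- if (inherits(W, "affinity_matrix")) W$W else as.matrix(W)
  n <- nrow(M)
  stopifnot(k >= 2L, k < n)
  emb <- .spectral_embed(M, k)
  n_comp <- .n_components(M > 0)
  if (n_comp > k)
    warning("affinity graph has ", n_comp,
            " connected components, more than k = ", k)
  labels <- .cluster_embedding(emb$vectors, k, nstart)
  names(labels) <- rownames(M)
  labels
}

#' Subsampled consensus clustering over a range of k
#'
#' Draws `B` subsamples of `round(frac * n)` samples without replacement,
#' spectral-clusters each subsample's affinity submatrix at every k in
#' `k_range`, and records for every sample pair the fraction of co-sampled
#' runs in which the pair co-clustered. Pairs never co-sampled have an
#' undefined consensus entry (NaN) and are excluded from the stability
#' statistic. Full-data labels are also computed per k.
#'
#' @param W an `affinity_matrix` (or matrix).
#' @param k_range integer vector of cluster numbers, e.g. `2:6`.
#' @param B number of subsamples; default 100.
#' @param frac subsample fraction; default 0.8. Requires
#'   `round(frac * n) >= max(k_range) + 1`.
#' @param seed integer seed controlling subsampling and k-means.
#' @return a `consensus_result`: list with `k_range`, `consensus` (list of
#'   n x n matrices), `dis` (named numeric), `labels` (n x length(k_range)
#'   matrix), `B`, `frac`, `seed`.
#' @export
consensus_cluster <- function(W, k_range = 2:6, B = 100L, frac = 0.8,
                              seed = 1L) {
  M <- if (inherits(W, "affinity_matrix")) W$W else as.matrix(W)
  n <- nrow(M)
  k_range <- sort(unique(as.integer(k_range)))
  m_sub <- round(frac * n)
  if (m_sub < max(k_range) + 1L)
    stop("subsample size ", m_sub, " too small for k = ", max(k_range))
  set.seed(seed)
  kmax <- max(k_range)
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  cosampled <- matrix(0, n, n)
  for (b in seq_len(B)) {
    idx <- sort(sample.int(n, m_sub))
    cosampled[idx, idx] <- cosampled[idx, idx] + 1
    emb <- .spectral_embed(M[idx, idx], kmax)
    for (k in k_range) {
      lab <- .cluster_embedding(emb$vectors, k)
      for (cl in unique(lab)) {
        members <- idx[lab == cl]
        conn[[as.character(k)]][members, members] <-
          conn[[as.character(k)]][members, members] + 1
      }
    }
  }
  uncovered <- sum(cosampled[upper.tri(cosampled)] == 0)
  if (uncovered > 0)
    warning(uncovered, " sample pair(s) never co-sampled; ",
            "increase B for full pair coverage")
  consensus <- lapply(conn, function(cm) {
    out <- cm / cosampled
    out[cosampled == 0] <- NaN
    diag(out) <- 1
    dimnames(out) <- dimnames(M)
    out
  })
  labels <- sapply(k_range, function(k) spectral_cluster(M, k))
  colnames(labels) <- as.character(k_range)
  rownames(labels) <- rownames(M)
  disv <- vapply(consensus, dis, numeric(1L))
  structure(list(k_range = k_range, consensus = consensus, dis = disv,
                 labels = labels, B = as.integer(B), frac = frac,
                 seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k =", paste(x$k_range, collapse = ", "),
      sprintf("(B = %d, frac = %g)\n", x$B, x$frac))
  print(round(x$dis, 4))
  invisible(x)
}

#' Deviation from ideal stability (DIS)
#'
#' Under perfect stability every consensus entry is 0 or 1 and the
#' consensus CDF is horizontal between its endpoints. DIS measures the
#' deviation from that ideal as the mean, over defined off-diagonal pairs,
#' of `2 * min(m, 1 - m)`: 0 iff all entries are in \{0, 1\}, 1 when all
#' entries sit at the maximally ambiguous 0.5.
#'
#' @param M consensus matrix with entries in \[0, 1\] (NaN = pair never
#'   co-sampled, excluded).
#' @return DIS in \[0, 1\].
#' @export
dis <- function(M) {
  M <- as.matrix(M)
  v <- M[upper.tri(M)]
  v <- v[!is.nan(v)]
  if (!length(v)) stop("no defined off-diagonal consensus pairs")
  if (any(v < -1e-12 | v > 1 + 1e-12)) stop("consensus entries must be in [0,1]")
  v <- pmin(pmax(v, 0), 1)
  mean(2 * pmin(v, 1 - v))
}

#' Constrained selection of the number of clusters
#'
#' A value of k is feasible when (i) its smallest full-data cluster has at
#' least `min_cluster_size` patients, (ii) vital status differs across
#' clusters (chi-square, p < alpha), and (iii) survival differs across
#' clusters (log-rank, p < alpha). Among feasible k whose DIS is within
#' `dis_tolerance` (relative) of the smallest feasible DIS, the largest k
#' is returned: distinguishing more clusters is clinically preferable when
#' stability is comparable. If no k passes the survival constraints the
#' selection falls back to size + DIS feasibility with a prominent warning.
#'
#' @param cr a `consensus_result`.
#' @param clinical a `clinical_table` aligned with the clustered samples.
#' @param min_cluster_size smallest admissible cluster; default 10.
#' @param alpha level for the survival constraints; default 0.05.
#' @param dis_tolerance relative DIS slack for the largest-k tie rule;
#'   default 0.10.
#' @return a `cluster_assignment`: list with `sample_ids`, `labels`, `k`,
#'   and a per-k `rationale` table (dis, min_size, p_status, p_logrank,
#'   feasible).
#' @export
select_k <- function(cr, clinical, min_cluster_size = 10L, alpha = 0.05,
                     dis_tolerance = 0.10) {
  ks <- cr$k_range
  diag_tab <- data.frame(k = ks, dis = unname(cr$dis[as.character(ks)]),
                         min_size = NA_integer_, p_status = NA_real_,
                         p_logrank = NA_real_)
  for (i in seq_along(ks)) {
    lab <- cr$labels[, as.character(ks[i])]
    diag_tab$min_size[i] <- min(table(lab))
    tab <- table(factor(clinical$vital_status, levels = 0:1), lab)
    diag_tab$p_status[i] <- tryCatch(
      suppressWarnings(chi_square_independence(tab)$p), error = function(e) 1)
    diag_tab$p_logrank[i] <- tryCatch(
      suppressWarnings(log_rank_test(clinical$survival_time_days,
                                     clinical$vital_status, lab)$p),
      error = function(e) 1)
  }
  diag_tab$size_ok <- diag_tab$min_size >= min_cluster_size
  diag_tab$feasible <- diag_tab$size_ok &
    diag_tab$p_status < alpha & diag_tab$p_logrank < alpha
  feas <- diag_tab$feasible
  if (!any(feas)) {
    warning("no k satisfies the survival constraints; ",
            "falling back to cluster-size + DIS feasibility only")
    feas <- diag_tab$size_ok
  }
  if (!any(feas)) {
    print(diag_tab)
    stop("no feasible number of clusters in the supplied range")
  }
  dmin <- min(diag_tab$dis[feas])
  cand <- which(feas & diag_tab$dis <= (1 + dis_tolerance) * dmin)
  chosen_i <- cand[which.max(diag_tab$k[cand])]
  k <- diag_tab$k[chosen_i]
  labels <- cr$labels[, as.character(k)]
  stopifnot(min(table(labels)) >= min_cluster_size)
  structure(list(sample_ids = names(labels), labels = labels, k = k,
                 rationale = diag_tab),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: k = %d over %d samples\n", x$k,
              length(x$labels)))
  print(table(x$labels))
  invisible(x)
}
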