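#' Similarity-network-fusion parameters
#'
#' @param n number of samples (used only for the K default).
#' @param K neighbourhood size; default `max(10, round(n / 10))`, capped at
#'   `n - 1`.
#' @param mu kernel bandwidth scaling; the method's recommended range is
#'   \[0.3, 0.8\], default 0.5 (midpoint).
#' @param t number of cross-diffusion iterations; default 20.
#' @param convergence_tol stop early when the max-abs change between
#'   iterations falls below this; default 1e-6.
#' @return an `snf_params` list.
#' @export
snf_params <- function(n = NULL, K = NULL, mu = 0.5, t = 20L,
                       convergence_tol = 1e-6) {
  if (is.null(K)) {
    if (is.null(n)) stop("provide n or K")
    K <- max(10L, round(n / 10))
  }
  if (!is.null(n)) K <- min(K, n - 1L)
  stopifnot(K >= 1L, mu > 0, t >= 1L)
  structure(list(K = as.integer(K), mu = mu, t = as.integer(t),
                 convergence_tol = convergence_tol), class = "snf_params")
}

#' Sample-by-sample affinity matrix
#'
#' @param W symmetric nonnegative matrix with sample ids as dimnames.
#' @return an `affinity_matrix`.
#' @export
affinity_matrix <- function(W) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-10) stop("affinity matrix must be symmetric")
  if (any(W < 0) || any(!is.finite(W)))
    stop("affinity matrix must be nonnegative and finite")
  if (is.null(rownames(W))) {
    ids <- paste0("s", seq_len(nrow(W)))
    dimnames(W) <- list(ids, ids)
  }
  structure(list(sample_ids = rownames(W), W = W), class = "affinity_matrix")
}

#' Euclidean sample-sample distances
#'
#' @param m a complete `omics_matrix`; features should be z-normalized
#'   first so no feature dominates by scale.
#' @return symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
pairwise_distance <- function(m) {
  if (any(m$missing_mask)) stop("pairwise_distance requires a complete matrix")
  if (ncol(m$values) < 2L) stop("need at least 2 samples")
  D <- as.matrix(stats::dist(t(m$values), method = "euclidean"))
  diag(D) <- 0
  D
}

#' Scaled-exponential affinity kernel
#'
#' W(i, j) = exp(-D(i, j)^2 / (mu * eps_ij)) with the locally adaptive
#' bandwidth eps_ij = (mean K-NN distance of i + mean K-NN distance of j
#' + D(i, j)) / 3. Symmetric by construction.
#'
#' @param D distance matrix (symmetric, zero diagonal).
#' @param params an `snf_params` (K and mu are used).
#' @return an `affinity_matrix`.
#' @export
affinity_from_distance <- function(D, params = snf_params(nrow(D))) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D))
  K <- min(params$K, n - 1L)
  # mean distance to the K nearest other samples
  eps_i <- vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i], method = "radix")[seq_len(K)]
    mean(d)
  }, numeric(1L))
  Eps <- (outer(eps_i, eps_i, `+`) + D) / 3
  if (any(Eps == 0)) {
    warning("coincident points give zero kernel bandwidth; flooring at 1e-12")
    Eps[Eps == 0] <- 1e-12
  }
  W <- exp(-D^2 / (params$mu * Eps))
  W <- (W + t(W)) / 2   # remove last-digit asymmetry
  if (!is.null(rownames(D))) dimnames(W) <- dimnames(D)
  affinity_matrix(W)
}

# Stabilized full-kernel normalization: off-diagonal rows sum to 1/2,
# diagonal 1/2. Guarantees the cross-diffusion iteration stays bounded.
.full_kernel <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# Sparse kernel: row-normalized restriction of W to each sample's K
# nearest neighbours (by affinity, excluding self).
.sparse_kernel <- function(W, K) {
  n <- nrow(W)
  K <- min(K, n - 1L)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nn <- order(w, decreasing = TRUE)[seq_len(K)]
    s <- W[i, nn]
    tot <- sum(s)
    if (tot > 0) S[i, nn] <- s / tot
  }
  S
}

#' Similarity network fusion (cross-diffusion)
#'
#' Fuses per-view patient affinity matrices into a single matrix by
#' iterated cross-diffusion: each view's full kernel is propagated through
#' its own K-nearest-neighbour sparse kernel against the average of the
#' other views' kernels,
#' `P(v) <- S(v) %*% mean(P(-v)) %*% t(S(v))`,
#' re-stabilized each round, until `params$t` iterations or until the
#' max-abs change drops below `params$convergence_tol`. The fused matrix is
#' the average of the final kernels, symmetrized, with the diagonal set to
#' each row's off-diagonal maximum so self-similarity does not dominate
#' the spectral step. A single view returns its stabilized full kernel.
#'
#' @param affinities list of `affinity_matrix` objects on identical,
#'   identically ordered samples.
#' @param params an `snf_params`.
#' @return an `affinity_matrix`; attribute `"delta"` logs the per-iteration
#'   max-abs change.
#' @export
snf <- function(affinities, params = NULL) {
  if (inherits(affinities, "affinity_matrix")) affinities <- list(affinities)
  stopifnot(length(affinities) >= 1L)
  ids <- affinities[[1L]]$sample_ids
  for (a in affinities)
    if (!identical(a$sample_ids, ids))
      stop("all views must share an identical ordered sample set")
  n <- length(ids)
  if (is.null(params)) params <- snf_params(n)
  V <- length(affinities)
  P <- lapply(affinities, function(a) .full_kernel(a$W))
  if (V == 1L) {
    out <- (P[[1L]] + t(P[[1L]])) / 2   # row kernel symmetrized
    dimnames(out) <- list(ids, ids)
    return(affinity_matrix(out))
  }
  S <- lapply(affinities, function(a) .sparse_kernel(a$W, params$K))
  deltas <- numeric(0)
  for (it in seq_len(params$t)) {
    Pnew <- vector("list", V)
    for (v in seq_len(V)) {
      Pbar <- Reduce(`+`, P[-v]) / (V - 1L)
      Q <- S[[v]] %*% Pbar %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      Pnew[[v]] <- .full_kernel(Q)
    }
    delta <- max(vapply(seq_len(V),
                        function(v) max(abs(Pnew[[v]] - P[[v]])),
                        numeric(1L)))
    deltas <- c(deltas, delta)
    P <- Pnew
    if (delta < params$convergence_tol) break
  }
  Wf <- Reduce(`+`, P) / V
  Wf <- (Wf + t(Wf)) / 2
  diag(Wf) <- 0
  diag(Wf) <- apply(Wf, 1L, max)
  dimnames(Wf) <- list(ids, ids)
  out <- affinity_matrix(Wf)
  attr(out, "delta") <- deltas
  out
}

#' Build a per-view affinity from a matrix in one call
#'
#' Convenience wrapper: z-normalize, pairwise Euclidean distance, scaled
#' exponential kernel.
#'
#' @param m a complete `omics_matrix`.
#' @param params an `snf_params` (defaults from the sample count).
#' @return an `affinity_matrix`.
#' @export
view_affinity <- function(m, params = snf_params(ncol(m$values))) {
  affinity_from_distance(pairwise_distance(znormalize(m)), params)
}
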