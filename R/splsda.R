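#' Soft-threshold a weight vector to a fixed support size
#'
#' Shrinks every coordinate toward zero by the (keep + 1)-th largest
#' absolute value, so exactly `keep` coordinates survive (up to ties), and
#' renormalizes to unit length. The sparsity operator of sparse PLS.
#'
#' @param w numeric weight vector.
#' @param keep number of coordinates to keep (1 <= keep <= length(w)).
#' @param renormalize rescale the result to unit Euclidean norm
#'   (default TRUE).
#' @return the thresholded vector.
#' @export
soft_threshold <- function(w, keep, renormalize = TRUE) {
  stopifnot(keep >= 1L, keep <= length(w))
  a <- abs(w)
  lambda <- if (keep >= length(w)) 0 else sort(a, decreasing = TRUE)[keep + 1L]
  out <- sign(w) * pmax(a - lambda, 0)
  if (renormalize) {
    nrm <- sqrt(sum(out^2))
    if (nrm > 0) out <- out / nrm
  }
  out
}

# Center/scale columns, guarding zero-variance columns.
.scale_block <- function(X, center = NULL, scale_ = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale_)) {
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  }
  list(X = sweep(sweep(X, 2L, center), 2L, scale_, "/"),
       center = center, scale = scale_)
}

.dummy_matrix <- function(y) {
  y <- factor(y)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  Y
}

#' Fit a multi-block sparse PLS discriminant model
#'
#' Iterative multi-block sparse PLS with a dummy-coded class response:
#' per component, each block's weight vector maximizes the design-weighted
#' sum of covariances between its scores, the other blocks' scores and the
#' response scores; sparsity is enforced by soft-thresholding each weight
#' vector to its per-block keep-count, and each block is deflated by its
#' own scores. Prediction assigns, per block, the class of the nearest
#' centroid in component-score space and combines blocks by a
#' design-weighted vote (ties broken by the smallest total distance).
#'
#' @param blocks named list of sample x feature matrices on identical
#'   samples.
#' @param y class label per sample.
#' @param keepX named list: per block, a vector of keep-counts per
#'   component (recycled to `ncomp`).
#' @param ncomp number of components; default 2.
#' @param design between-block connection weights in \[0, 1\]: a single
#'   number (default 1, the full design) or a V x V matrix; every block is
#'   always connected to the response with weight 1.
#' @param max_iter,tol inner-loop controls.
#' @return a `multiblock_splsda` model.
#' @export
multiblock_splsda_fit <- function(blocks, y, keepX, ncomp = 2L, design = 1,
                                  max_iter = 100L, tol = 1e-6) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  V <- length(blocks)
  n <- nrow(blocks[[1L]])
  for (b in blocks) stopifnot(nrow(b) == n)
  y <- factor(y)
  classes <- levels(y)
  stopifnot(length(classes) >= 2L)
  scaled <- lapply(blocks, .scale_block)
  Xs <- lapply(scaled, `[[`, "X")
  Y <- scale(.dummy_matrix(y), center = TRUE, scale = FALSE)
  if (length(design) == 1L) {
    D <- matrix(design, V, V)
    diag(D) <- 0
  } else {
    D <- as.matrix(design)
    stopifnot(all(dim(D) == V))
  }
  dy <- rep(1, V)   # every block tied to the response
  keepX <- lapply(seq_len(V), function(v) {
    kx <- rep_len(keepX[[names(blocks)[v]]] %||% keepX[[v]], ncomp)
    if (any(kx > ncol(blocks[[v]])))
      stop("keep-count exceeds width of block '", names(blocks)[v], "'")
    as.integer(kx)
  })
  loadings <- lapply(seq_len(V), function(v)
    matrix(0, ncol(blocks[[v]]), ncomp,
           dimnames = list(colnames(blocks[[v]]), NULL)))
  defl <- lapply(seq_len(V), function(v)
    matrix(0, ncol(blocks[[v]]), ncomp))
  scores <- lapply(seq_len(V), function(v) matrix(0, n, ncomp))
  for (h in seq_len(ncomp)) {
    ty <- svd(Y, nu = 1L, nv = 0L)$u[, 1L]
    tlist <- lapply(Xs, function(X) as.numeric(X %*% rep(0, ncol(X))))
    # initialize block scores from the response direction
    for (v in seq_len(V)) {
      w0 <- soft_threshold(crossprod(Xs[[v]], ty)[, 1L], keepX[[v]][h])
      tlist[[v]] <- as.numeric(Xs[[v]] %*% w0)
    }
    wlist <- vector("list", V)
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (v in seq_len(V)) {
        drive <- dy[v] * ty
        for (j in seq_len(V)) if (j != v && D[v, j] > 0)
          drive <- drive + D[v, j] * tlist[[j]]
        z <- crossprod(Xs[[v]], drive)[, 1L]
        w <- soft_threshold(z, keepX[[v]][h])
        if (all(w == 0)) {  # degenerate direction: fall back to densest
          w <- z / sqrt(sum(z^2))
        }
        if (!is.null(wlist[[v]])) delta <- max(delta, max(abs(w - wlist[[v]])))
        else delta <- Inf
        wlist[[v]] <- w
        tlist[[v]] <- as.numeric(Xs[[v]] %*% w)
      }
      cy <- crossprod(Y, Reduce(`+`, tlist))[, 1L]
      nrm <- sqrt(sum(cy^2))
      if (nrm > 0) cy <- cy / nrm
      ty <- as.numeric(Y %*% cy)
      if (is.finite(delta) && delta < tol) break
    }
    for (v in seq_len(V)) {
      w <- wlist[[v]]
      # deterministic sign: largest-magnitude loading positive
      s <- sign(w[which.max(abs(w))])
      if (s < 0) { w <- -w; tlist[[v]] <- -tlist[[v]] }
      tv <- tlist[[v]]
      pv <- crossprod(Xs[[v]], tv)[, 1L] / sum(tv^2)
      loadings[[v]][, h] <- w
      defl[[v]][, h] <- pv
      scores[[v]][, h] <- tv
      Xs[[v]] <- Xs[[v]] - tcrossprod(tv, pv)
    }
    tbar <- Reduce(`+`, lapply(scores, function(s) s[, h])) / V
    if (sum(tbar^2) > 0)
      Y <- Y - tcrossprod(tbar, crossprod(Y, tbar)[, 1L] / sum(tbar^2))
  }
  centroids <- lapply(seq_len(V), function(v) {
    t(vapply(classes, function(cl)
      colMeans(scores[[v]][y == cl, , drop = FALSE]), numeric(ncomp)))
  })
  structure(list(blocks = names(blocks), classes = classes, ncomp = ncomp,
                 keepX = keepX, design = D,
                 center = lapply(scaled, `[[`, "center"),
                 scale = lapply(scaled, `[[`, "scale"),
                 loadings = loadings, deflation = defl,
                 scores = scores, centroids = centroids, y = y),
            class = "multiblock_splsda")
}

#' @export
print.multiblock_splsda <- function(x, ...) {
  cat(sprintf("multiblock_splsda: %d block(s), %d classes, %d component(s)\n",
              length(x$blocks), length(x$classes), x$ncomp))
  invisible(x)
}

#' Predict class membership from a multi-block sPLS-DA model
#'
#' @param object a `multiblock_splsda` model.
#' @param newdata named list of blocks matching the training blocks.
#' @param ... unused.
#' @return character vector of predicted classes; attribute
#'   `"per_block"` holds each block's own vote.
#' @export
predict.multiblock_splsda <- function(object, newdata, ...) {
  V <- length(object$blocks)
  stopifnot(length(newdata) == V)
  if (!is.null(names(newdata))) newdata <- newdata[object$blocks]
  n <- nrow(newdata[[1L]])
  dist_block <- vector("list", V)
  per_block <- matrix(NA_character_, n, V,
                      dimnames = list(NULL, object$blocks))
  for (v in seq_len(V)) {
    X <- .scale_block(newdata[[v]], object$center[[v]], object$scale[[v]])$X
    Tn <- matrix(0, n, object$ncomp)
    for (h in seq_len(object$ncomp)) {
      Tn[, h] <- X %*% object$loadings[[v]][, h]
      X <- X - tcrossprod(Tn[, h], object$deflation[[v]][, h])
    }
    Dm <- vapply(seq_along(object$classes), function(ci)
      sqrt(rowSums(sweep(Tn, 2L, object$centroids[[v]][ci, ])^2)),
      numeric(n))
    Dm <- matrix(Dm, nrow = n)
    dist_block[[v]] <- Dm
    per_block[, v] <- object$classes[apply(Dm, 1L, which.min)]
  }
  total_dist <- Reduce(`+`, dist_block)
  pred <- character(n)
  for (i in seq_len(n)) {
    votes <- table(factor(per_block[i, ], levels = object$classes))
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else
      top[which.min(total_dist[i, match(top, object$classes)])]
  }
  attr(pred, "per_block") <- per_block
  pred
}

#' Balanced error rate
#'
#' Mean over classes of the per-class error rate; insensitive to class
#' imbalance.
#'
#' @param truth,pred label vectors.
#' @return BER in \[0, 1\].
#' @export
balanced_error_rate <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  mean(vapply(unique(truth), function(cl)
    mean(pred[truth == cl] != cl), numeric(1L)))
}

#' Tune sPLS-DA keep-counts by repeated k-fold cross-validation
#'
#' Evaluates every point of the per-block keep-count grid by repeated
#' k-fold CV balanced error rate and returns the minimizer; ties are
#' broken toward the fewest total features.
#'
#' @param blocks named list of sample x feature matrices.
#' @param y class labels.
#' @param keep_grid named list: per block, candidate keep-counts.
#' @param ncomp components; default 2.
#' @param cv a `cv_spec`; default 10 repeats of 10-fold CV.
#' @param design passed to [multiblock_splsda_fit()].
#' @return list with `chosen` (named keep-counts), `surface`
#'   (grid + mean BER), `cv`.
#' @export
splsda_tune <- function(blocks, y, keep_grid, ncomp = 2L,
                        cv = cv_spec("repeated_kfold", folds = 10L,
                                     repeats = 10L, seed = 1L),
                        design = 1) {
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  grid <- expand.grid(keep_grid[names(blocks)], KEEP.OUT.ATTRS = FALSE)
  splits <- .cv_splits(cv, nrow(blocks[[1L]]), stratify = y)
  y <- as.character(y)
  ber <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    kx <- as.list(grid[g, , drop = FALSE])
    ber[g] <- mean(vapply(splits, function(s) {
      fit <- multiblock_splsda_fit(
        lapply(blocks, function(b) b[s$train, , drop = FALSE]),
        y[s$train], keepX = kx, ncomp = ncomp, design = design)
      pred <- predict(fit, lapply(blocks, function(b)
        b[s$test, , drop = FALSE]))
      balanced_error_rate(y[s$test], pred)
    }, numeric(1L)))
  }
  surface <- cbind(grid, ber = ber)
  o <- order(ber, rowSums(as.matrix(grid)))
  chosen <- as.list(grid[o[1L], , drop = FALSE])
  list(chosen = chosen, surface = surface, cv = cv)
}
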