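# NIPALS PLS1 on a centered/scaled X and centered +/-1 response.
# For a single response the per-component weight has a closed form
# (w_a = X_a' y_a normalized), so no inner iteration is needed.
nipalsPls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- X; yd <- y
  A <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pa <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pa)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; q[a] <- qa
    A <- a
  }
  list(W = W[, seq_len(A), drop = FALSE],
    P = P[, seq_len(A), drop = FALSE],
    Tm = Tm[, seq_len(A), drop = FALSE], q = q[seq_len(A)], ncomp = A)
}

# regression coefficients on the scaled X scale
plsCoef <- function(fit) {
  drop(fit$W %*% solve(crossprod(fit$P, fit$W), fit$q))
}

autoscale <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[scale < 1e-12] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
    center = center, scale = scale)
}

#' Fit a cross-validated PLS-DA model on voxel data
#'
#' Fits NIPALS partial least squares discriminant analysis with the
#' diagnosis coded +/-1 and predictors autoscaled (mean-centered, unit
#' variance). The number of components is chosen by stratified k-fold
#' cross-validation (default threefold) maximizing mean balanced
#' accuracy, with ties resolved toward fewer components; the model is
#' then refit on all subjects at that size.
#'
#' @param X subject x voxel matrix (e.g. [extractVoxelMatrix()]).
#' @param y two-level factor of diagnoses aligned with rows; the first
#'   level is the control/reference class.
#' @param kFolds folds for cross-validation (default 3).
#' @param maxComponents largest component count tried (default 5;
#'   clipped to the data rank with a warning).
#' @param seed RNG seed for the fold assignment.
#' @return a [PlsdaModel].
#' @export
fitPlsdaCV <- function(X, y, kFolds = 3, maxComponents = 5, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    stop("input error: y must have exactly two classes present")
  yNum <- ifelse(y == levels(y)[2], 1, -1)
  maxRank <- min(nrow(X) - 1, ncol(X))
  if (maxComponents > maxRank) {
    warning("maxComponents clipped to the data rank (", maxRank, ")")
    maxComponents <- maxRank
  }
  set.seed(seed)
  fold <- stratifiedFolds(y, kFolds)

  acc <- matrix(NA_real_, kFolds, maxComponents)
  for (f in seq_len(kFolds)) {
    tr <- fold != f
    sc <- autoscale(X[tr, , drop = FALSE])
    yTr <- yNum[tr] - mean(yNum[tr])
    fit <- nipalsPls1(sc$X, yTr, maxComponents)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, sc$center), 2,
      sc$scale, "/")
    for (a in seq_len(fit$ncomp)) {
      sub <- list(W = fit$W[, 1:a, drop = FALSE],
        P = fit$P[, 1:a, drop = FALSE], q = fit$q[1:a])
      beta <- plsCoef(sub)
      fitted <- drop(sc$X %*% beta) + mean(yNum[tr])
      thr <- (mean(fitted[yNum[tr] == 1]) +
        mean(fitted[yNum[tr] == -1])) / 2
      pred <- drop(Xte %*% beta) + mean(yNum[tr])
      predClass <- ifelse(pred > thr, 1, -1)
      sens <- mean(predClass[yNum[!tr] == 1] == 1)
      spec <- mean(predClass[yNum[!tr] == -1] == -1)
      acc[f, a] <- (sens + spec) / 2
    }
  }
  meanAcc <- colMeans(acc)
  meanAcc[is.na(meanAcc)] <- 0
  best <- which.max(meanAcc)  # which.max takes the first maximum: fewer comps

  sc <- autoscale(X)
  yc <- yNum - mean(yNum)
  fit <- nipalsPls1(sc$X, yc, best)
  beta <- plsCoef(fit)
  fitted <- drop(sc$X %*% beta) + mean(yNum)
  thr <- (mean(fitted[yNum == 1]) + mean(fitted[yNum == -1])) / 2
  rownames(fit$W) <- rownames(fit$P) <- colnames(X)
  new("PlsdaModel", weights = fit$W, xLoadings = fit$P,
    scores = fit$Tm, yLoadings = fit$q, nComponents = fit$ncomp,
    cvCurve = data.frame(ncomp = seq_len(maxComponents),
      balanced_accuracy = meanAcc),
    center = sc$center, scale = sc$scale, yMean = mean(yNum),
    threshold = thr, yLevels = levels(y))
}

#' Variable importance in projection (VIP)
#'
#' Computes the VIP score per predictor from a fitted PLS-DA model:
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}}
#' with \eqn{SS_a = q_a^2 t_a't_a} the y-variance explained by component
#' a and the weight vectors unit-norm, so that the mean of the squared
#' VIPs equals 1. For a one-component model this reduces to
#' \eqn{\sqrt{p}\,|w_j|}.
#'
#' @param model a [PlsdaModel].
#' @return named numeric vector of VIP scores, one per predictor.
#' @export
plsdaVIP <- function(model) {
  W <- model@weights
  ss <- model@yLoadings^2 * colSums(model@scores^2)
  if (sum(ss) < 1e-300)
    stop("degenerate input: total explained sum of squares is zero")
  p <- nrow(W)
  vip <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  names(vip) <- rownames(W)
  vip
}

#' Select MCI-associated voxels by VIP and percent mean difference
#'
#' Applies the joint selection rule: a voxel passes when its VIP is at
#' least `vipMin` (default 2) and its absolute percent gray-matter
#' difference exceeds `pctMin` (default 2%). The percent difference is
#' `100 * (mean_control - mean_case) / mean_control`, so positive values
#' mean lower gray matter in cases; those voxels form the `selected`
#' set, while voxels passing the thresholds with higher gray matter in
#' cases are bucketed as direction `artifact`s and excluded from
#' integration. Voxels with a zero control mean are flagged and excluded
#' with a warning.
#'
#' @param vip per-voxel VIP scores ([plsdaVIP()]), aligned with the
#'   columns of `X`.
#' @param X subject x voxel matrix.
#' @param y diagnosis factor; the first level is the control class.
#' @param vipMin,pctMin selection thresholds.
#' @return a [VoxelSelection].
#' @export
selectVoxels <- function(vip, X, y, vipMin = 2.0, pctMin = 2.0) {
  if (length(vip) != ncol(X))
    stop("input error: vip must align with the columns of X")
  y <- droplevels(as.factor(y))
  ctrl <- colMeans(X[y == levels(y)[1], , drop = FALSE])
  case <- colMeans(X[y == levels(y)[2], , drop = FALSE])
  flagged <- which(ctrl == 0)
  if (length(flagged) > 0)
    warning(length(flagged), " voxel(s) with zero control mean excluded")
  pct <- 100 * (ctrl - case) / ctrl
  pct[flagged] <- NA
  pass <- !is.na(pct) & vip >= vipMin & abs(pct) > pctMin
  new("VoxelSelection", vip = unname(vip), pctDiff = unname(pct),
    selected = unname(which(pass & pct > 0)),
    artifact = unname(which(pass & pct < 0)),
    flagged = as.integer(unname(flagged)),
    params = list(vip_min = vipMin, pct_min = pctMin))
}
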