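# Parametric empirical-Bayes batch adjustment (location/scale model),
# tolerant of missing cells: all moments are estimated from observed
# values only, so the adjustment can run before imputation.

ebPriors <- function(gammaHat, deltaHatSq) {
  m <- mean(deltaHatSq, na.rm = TRUE)
  s2 <- var(deltaHatSq, na.rm = TRUE)
  list(gbar = mean(gammaHat, na.rm = TRUE),
    t2 = var(gammaHat, na.rm = TRUE),
    a = (2 * s2 + m^2) / s2,
    b = (m * s2 + m^3) / s2)
}

# iterative joint posterior solution for the batch location (gamma*) and
# scale (delta^2*) parameters of one batch, all features at once
ebSolve <- function(z, gammaHat, deltaHatSq, pri, conv = 1e-4,
    maxIter = 200) {
  n <- rowSums(!is.na(z))
  g <- gammaHat
  d <- deltaHatSq
  for (it in seq_len(maxIter)) {
    gNew <- (n * pri$t2 * gammaHat + d * pri$gbar) / (n * pri$t2 + d)
    ssq <- rowSums((z - gNew)^2, na.rm = TRUE)
    dNew <- (pri$b + 0.5 * ssq) / (n / 2 + pri$a - 1)
    change <- max(abs(gNew - g) / pmax(abs(g), 1e-8),
      abs(dNew - d) / pmax(abs(d), 1e-8), na.rm = TRUE)
    g <- gNew
    d <- dNew
    if (change < conv) break
  }
  list(gStar = g, dStar = d)
}

#' Empirical-Bayes batch-effect correction
#'
#' Removes additive and multiplicative batch effects from a log-scale
#' feature table using a parametric empirical-Bayes location/scale
#' model: per-feature batch means and variances are shrunk toward
#' pooled priors estimated across features, then removed, preserving
#' each feature's grand mean. Missing cells are excluded from all
#' estimation and returned unchanged (as `NA`). With a single batch the
#' input is returned unmodified.
#'
#' Features for which some batch has fewer than two observed values are
#' returned unadjusted (there is no within-batch variance to estimate
#' for them).
#'
#' @param mat feature x sample matrix on the log scale (may contain
#'   `NA`).
#' @param batch batch labels, one per column; every batch must contain
#'   at least 2 samples.
#' @return The adjusted matrix, same shape and `NA` pattern.
#' @export
combatCorrect <- function(mat, batch) {
  batch <- droplevels(as.factor(batch))
  if (length(batch) != ncol(mat))
    stop("batch must have one label per sample")
  if (nlevels(batch) == 1) return(mat)
  nb <- table(batch)
  if (any(nb < 2))
    stop("degenerate input: every batch needs at least 2 samples")

  levs <- levels(batch)
  batchCols <- lapply(levs, function(b) which(batch == b))
  obsCount <- vapply(batchCols, function(j)
    rowSums(!is.na(mat[, j, drop = FALSE])), numeric(nrow(mat)))
  usable <- apply(obsCount >= 2, 1, all)
  out <- mat
  if (!any(usable)) return(out)
  y <- mat[usable, , drop = FALSE]

  # weighted grand mean and pooled variance (batch-model residuals)
  batchMean <- vapply(batchCols, function(j)
    rowMeans(y[, j, drop = FALSE], na.rm = TRUE), numeric(nrow(y)))
  w <- as.numeric(nb) / sum(nb)
  grand <- drop(batchMean %*% w)
  resid <- y - batchMean[, as.integer(batch)]
  varPooled <- rowSums(resid^2, na.rm = TRUE) / rowSums(!is.na(y))
  varPooled <- pmax(varPooled, 1e-12)

  z <- (y - grand) / sqrt(varPooled)
  for (bi in seq_along(levs)) {
    j <- batchCols[[bi]]
    zb <- z[, j, drop = FALSE]
    gammaHat <- rowMeans(zb, na.rm = TRUE)
    deltaHatSq <- apply(zb, 1, var, na.rm = TRUE)
    pri <- ebPriors(gammaHat, deltaHatSq)
    sol <- ebSolve(zb, gammaHat, deltaHatSq, pri)
    z[, j] <- (zb - sol$gStar) / sqrt(sol$dStar)
  }
  out[usable, ] <- z * sqrt(varPooled) + grand
  out
}
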