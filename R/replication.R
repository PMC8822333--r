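#' Stratified train/validation split
#'
#' Randomly splits subjects into a training and a validation set,
#' stratified by diagnosis: each stratum contributes
#' `round-half-up(trainFrac * stratum size)` training subjects (a 67%
#' split of 60 cases and 85 controls gives 40/57 training and 20/28
#' validation subjects), the remainder going to validation.
#'
#' @param meta data.frame with `subject_id` and `diagnosis`.
#' @param trainFrac training fraction in (0, 1), default 0.67.
#' @param seed RNG seed.
#' @return list of class `SplitPlan`: `train`, `validation` (subject
#'   ids), `counts` (per-stratum data.frame), `seed`.
#' @export
stratifiedSplit <- function(meta, trainFrac = 0.67, seed = 1L) {
  if (!is.numeric(trainFrac) || trainFrac <= 0 || trainFrac >= 1)
    stop("configuration error: trainFrac must lie strictly in (0, 1)")
  strata <- as.factor(meta$diagnosis)
  if (any(table(strata) == 0) || nlevels(droplevels(strata)) < 2)
    stop("both strata must be non-empty")
  set.seed(seed)
  train <- character(0)
  counts <- NULL
  for (lev in levels(strata)) {
    ids <- meta$subject_id[strata == lev]
    nTrain <- roundHalfUp(trainFrac * length(ids))
    pick <- sample(ids, nTrain)
    train <- c(train, pick)
    counts <- rbind(counts, data.frame(stratum = lev,
      n_train = nTrain, n_validation = length(ids) - nTrain))
  }
  out <- list(train = train,
    validation = setdiff(meta$subject_id, train), counts = counts,
    train_frac = trainFrac, seed = seed)
  class(out) <- "SplitPlan"
  out
}

#' Ordinary least-squares fit with R-squared
#'
#' @param x,y numeric vectors (at least 3 points; `x` must vary).
#' @return list: slope, intercept, r, r_squared, n.
#' @export
fitR2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("degenerate input: need at least 3 points")
  if (sd(x) < 1e-12) stop("degenerate input: x is constant")
  fit <- lm(y ~ x)
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r = cor(x, y), r_squared = r2, n = length(x))
}

#' @importFrom stats residuals
NULL

#' Train/validation replication of the voxel-metabolite integration
#'
#' Re-runs the correlation network on the training subjects with a
#' fixed cutoff (the voxel set and the cutoff are reused from the
#' full-data analysis; they are not reselected), then recomputes the
#' Pearson correlation of every retained training edge on the
#' validation subjects. Metabolites failing the edge criteria in the
#' training set contribute no pairs. Per-metabolite averages of the
#' training and validation correlations and ordinary least-squares fits
#' (with R-squared) quantify replication.
#'
#' @param X subject x selected-voxel matrix (full data; rows named by
#'   subject id).
#' @param M subject x metabolite matrix aligned with `X`.
#' @param plan a [stratifiedSplit()] plan.
#' @param cutoff fixed correlation threshold from the full-data run.
#' @param alpha p-value threshold (default 0.05).
#' @return list of class `ReplicationReport`: `pairs` (voxel,
#'   metabolite, r_train, r_valid), `metabolite_averages`, `fit`
#'   (OLS of r_valid on r_train over all pairs), `n_train`, `n_valid`.
#' @export
replicateNetwork <- function(X, M, plan, cutoff, alpha = 0.05) {
  tr <- match(plan$train, rownames(X))
  va <- match(plan$validation, rownames(X))
  if (anyNA(tr) || anyNA(va))
    stop("input error: split subjects missing from X")
  if (length(va) < 4)
    stop("input error: validation set must have at least 4 subjects")
  assocTr <- associationMatrix(X[tr, , drop = FALSE],
    M[tr, , drop = FALSE])
  net <- tryCatch(buildNetwork(assocTr, cutoff, alpha),
    error = function(e) NULL)
  if (is.null(net))
    return(structure(list(pairs = data.frame(), metabolite_averages =
      data.frame(), fit = NULL, n_train = length(tr),
      n_valid = length(va)), class = "ReplicationReport"))
  e <- net@edges
  rvalid <- vapply(seq_len(nrow(e)), function(i)
    cor(X[va, e$voxel[i]], M[va, e$metabolite[i]]), numeric(1))
  pairs <- data.frame(voxel = e$voxel, metabolite = e$metabolite,
    r_train = e$r, r_valid = rvalid)
  avg <- do.call(rbind, lapply(split(pairs, pairs$metabolite),
    function(d) data.frame(metabolite = d$metabolite[1],
      mean_r_train = mean(d$r_train), mean_r_valid = mean(d$r_valid),
      n_voxels = nrow(d))))
  rownames(avg) <- NULL
  fit <- fitR2(pairs$r_train, pairs$r_valid)
  structure(list(pairs = pairs, metabolite_averages = avg, fit = fit,
    n_train = length(tr), n_valid = length(va)),
    class = "ReplicationReport")
}
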