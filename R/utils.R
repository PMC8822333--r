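#' @importFrom stats cor median sd var rnorm runif quantile pt phyper
#'   setNames aggregate approx complete.cases lm coef rbinom
#' @importFrom utils head read.delim write.table
NULL

# Deterministic per-stage seed derived from the master seed; FNV-1a over
# the stage name keeps stage streams independent and < 2^31.
deriveSeed <- function(seed, stage) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(stage)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483629 + 1)
}

# FNV-1a hash of a config's deparsed contents, as a hex string, for
# fixture manifests.
configHash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Jaccard index of two id sets
#'
#' @param a,b vectors interpreted as sets.
#' @return `|a intersect b| / |a union b|` (1 when both are empty).
#' @export
jaccardIndex <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index comparing two labelings of the same
#' items, used to score community recovery against planted structure.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in \[-1, 1\]; 1 for identical partitions.
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

# stratified k-fold assignment: returns integer fold per row, both
# classes present in every fold (requires >= k members per class).
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    if (length(idx) < k)
      stop("class '", lev, "' has fewer members than folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# round-half-up, the rule that reproduces a 67% split of 60/85 into
# 40/57 training subjects
roundHalfUp <- function(x) floor(x + 0.5)
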