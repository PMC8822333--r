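dbCompounds <- function(db) {
  unique(db[, c("compound", "mass")])
}

#' Annotate m/z features with candidate compounds via adduct rules
#'
#' A feature matches a compound under an adduct when the observed m/z
#' lies within `tolPpm` parts per million of the compound's
#' monoisotopic mass plus the adduct delta. All matches are returned
#' with their ppm errors (one feature can match several compounds and
#' adducts).
#'
#' @param mz named numeric vector of observed m/z values (names are
#'   feature ids; unnamed input is named F1, F2, ...).
#' @param db compound/pathway table (columns compound, mass, pathway_id,
#'   pathway_name), e.g. from [simulateStudy()].
#' @param adducts adduct rule table, default [adductRules()].
#' @param tolPpm mass tolerance in ppm (default 10).
#' @return data.frame: feature, mz, compound, adduct, theoretical_mz,
#'   ppm_error.
#' @export
annotateFeaturesMz <- function(mz, db, adducts = adductRules(),
    tolPpm = 10) {
  stopifnot(all(mz > 0))
  if (is.null(names(mz))) names(mz) <- paste0("F", seq_along(mz))
  cmp <- dbCompounds(db)
  out <- vector("list", nrow(adducts))
  for (a in seq_len(nrow(adducts))) {
    theo <- cmp$mass + adducts$delta[a]
    # window search: for each feature, compounds within tolerance
    ord <- order(theo)
    ts <- theo[ord]
    lo <- findInterval(mz * (1 - tolPpm * 1e-6), ts) + 1
    hi <- findInterval(mz * (1 + tolPpm * 1e-6), ts)
    hits <- which(hi >= lo)
    if (length(hits) == 0) next
    rows <- do.call(rbind, lapply(hits, function(f) {
      j <- ord[lo[f]:hi[f]]
      data.frame(feature = names(mz)[f], mz = unname(mz[f]),
        compound = cmp$compound[j], adduct = adducts$name[a],
        theoretical_mz = theo[j],
        ppm_error = unname(mz[f] - theo[j]) / theo[j] * 1e6)
    }))
    out[[a]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(feature = character(0), mz = numeric(0),
      compound = character(0), adduct = character(0),
      theoretical_mz = numeric(0), ppm_error = numeric(0)))
  res <- res[abs(res$ppm_error) <= tolPpm, ]
  rownames(res) <- NULL
  res
}

#' Fisher/hypergeometric pathway enrichment
#'
#' For each pathway, tests over-representation of the significant
#' compound set within the reference compound set by the right-tail
#' hypergeometric probability `P(X >= k)` with `X ~ Hypergeom(N, K, n)`
#' (N reference compounds, K of them in the pathway, n significant,
#' k the overlap). Features must be collapsed to unique compounds before
#' calling (the annotation step does this).
#'
#' @param sigCompounds character, significant compound ids (a subset of
#'   `refCompounds`).
#' @param refCompounds character, reference compound ids.
#' @param db compound/pathway table.
#' @return data.frame: pathway_id, pathway_name, k, K, n, N, fisher_p;
#'   pathways absent from the reference are skipped with a warning.
#' @export
fisherEnrichment <- function(sigCompounds, refCompounds, db) {
  sigCompounds <- unique(sigCompounds)
  refCompounds <- unique(refCompounds)
  if (!all(sigCompounds %in% refCompounds))
    stop("significant compounds must be a subset of the reference")
  N <- length(refCompounds)
  n <- length(sigCompounds)
  pws <- unique(db[, c("pathway_id", "pathway_name")])
  K <- k <- integer(nrow(pws))
  for (i in seq_len(nrow(pws))) {
    members <- db$compound[db$pathway_id == pws$pathway_id[i]]
    K[i] <- length(intersect(members, refCompounds))
    k[i] <- length(intersect(members, sigCompounds))
  }
  absent <- K == 0
  if (any(absent))
    warning(sum(absent), " pathway(s) absent from the reference skipped")
  pws <- pws[!absent, , drop = FALSE]
  K <- K[!absent]; k <- k[!absent]
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(pathway_id = pws$pathway_id,
    pathway_name = pws$pathway_name, k = k, K = K, n = n, N = N,
    fisher_p = p)
  rownames(out) <- NULL
  out[order(out$fisher_p, out$pathway_id), ]
}

#' Permutation-based empirical p-values for pathway enrichment
#'
#' Draws `nPerm` random feature lists of the observed significant size
#' from the reference features, annotates each to compounds, recomputes
#' the Fisher p per pathway, and reports the add-one empirical p-value
#' `(1 + #\{perm p <= observed p\}) / (1 + nPerm)`.
#'
#' @param observed data.frame from [fisherEnrichment()].
#' @param sigFeatureCount number of features in the observed significant
#'   list (permutations resample at this size).
#' @param refFeatures all reference feature ids (annotated or not;
#'   permutations draw from this full list, mirroring the use of the
#'   whole extracted feature list as the reference).
#' @param refAnnotation feature-to-compound annotation of the reference
#'   ([annotateFeaturesMz()] output).
#' @param db compound/pathway table.
#' @param nPerm permutations (default 100).
#' @param seed RNG seed.
#' @return `observed` with a `permutation_p` column appended.
#' @export
permutationAdjust <- function(observed, sigFeatureCount, refFeatures,
    refAnnotation, db, nPerm = 100, seed = 1L) {
  stopifnot(nPerm >= 1)
  set.seed(seed)
  refFeatures <- unique(refFeatures)
  refCompounds <- unique(refAnnotation$compound)
  size <- min(sigFeatureCount, length(refFeatures))
  count <- integer(nrow(observed))
  for (b in seq_len(nPerm)) {
    pick <- sample(refFeatures, size)
    cmp <- unique(refAnnotation$compound[refAnnotation$feature %in% pick])
    if (length(cmp) == 0) next  # no annotation, no pathway can score
    perm <- suppressWarnings(fisherEnrichment(cmp, refCompounds, db))
    pp <- perm$fisher_p[match(observed$pathway_id, perm$pathway_id)]
    count <- count + (!is.na(pp) & pp <= observed$fisher_p)
  }
  observed$permutation_p <- (1 + count) / (1 + nPerm)
  observed
}

#' Pathway enrichment of one voxel-metabolite community
#'
#' Runs the full enrichment of a community: the significant list is the
#' community's metabolite features annotated to compounds; the
#' reference is all clean features annotated the same way. Fisher and
#' permutation p-values are computed per pathway. Communities none of
#' whose features annotate to any compound are reported as unenriched
#' with status `"no pathway mapping"`.
#'
#' @param clusterFeatures named numeric of the community features' m/z
#'   (names are feature ids), or character feature ids resolved against
#'   `allMz`.
#' @param allMz named numeric of all clean features' m/z.
#' @param db compound/pathway table.
#' @param adducts,tolPpm,nPerm,seed see [annotateFeaturesMz()] and
#'   [permutationAdjust()].
#' @return an [EnrichmentResult].
#' @export
enrichCluster <- function(clusterFeatures, allMz, db,
    adducts = adductRules(), tolPpm = 10, nPerm = 100, seed = 1L) {
  if (is.character(clusterFeatures)) {
    if (!all(clusterFeatures %in% names(allMz)))
      stop("community features must be a subset of the clean features")
    clusterFeatures <- allMz[clusterFeatures]
  }
  refAnn <- annotateFeaturesMz(allMz, db, adducts, tolPpm)
  sigAnn <- refAnn[refAnn$feature %in% names(clusterFeatures), ]
  if (nrow(sigAnn) == 0)
    return(new("EnrichmentResult",
      table = data.frame(pathway_id = character(0),
        pathway_name = character(0), k = integer(0), K = integer(0),
        n = integer(0), N = integer(0), fisher_p = numeric(0),
        permutation_p = numeric(0)),
      status = "no pathway mapping", nSignificant = 0L,
      nReference = length(unique(refAnn$compound))))
  sig <- unique(sigAnn$compound)
  ref <- unique(refAnn$compound)
  obs <- suppressWarnings(fisherEnrichment(sig, ref, db))
  obs <- permutationAdjust(obs, length(clusterFeatures), names(allMz),
    refAnn, db, nPerm, seed)
  new("EnrichmentResult", table = obs, status = "ok",
    nSignificant = length(sig), nReference = length(ref))
}
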