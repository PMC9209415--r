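# Representational geometry: identity-level dissimilarity matrices
# (1 - Pearson r between population response vectors), Spearman
# correlation between geometries over the off-diagonal upper triangle,
# and label-shuffle permutation tests, statically and across sliding
# time bins.

#' Identity-mean response matrix
#'
#' Averages the response vectors of all stimuli of each identity.
#'
#' @param responses numeric matrix stimuli x units, or an
#'   \linkS4class{ActivationSet}.
#' @param identity identity per stimulus (ignored for an ActivationSet).
#' @return numeric matrix identities x units.
#' @export
identityMeans <- function(responses, identity = NULL) {
  if (is(responses, "ActivationSet")) {
    identity <- identities(responses)
    responses <- t(responses(responses))
  }
  responses <- as.matrix(responses)
  identity <- droplevels(factor(identity))
  if (length(identity) != nrow(responses))
    stop("one identity per stimulus (row) is required")
  if (any(table(identity) == 0)) stop("missing identity")
  rowsum(responses, identity) / as.vector(table(identity))
}

#' Build an identity dissimilarity matrix
#'
#' D[i, j] = 1 - Pearson correlation between the identity-mean response
#' vectors of identities i and j. Zero-variance rows yield NA entries,
#' which are flagged and excluded from downstream rank correlations.
#' Because Pearson correlation is invariant to positive affine transforms
#' of each vector, so is the dissimilarity matrix.
#'
#' @param means numeric matrix identities x units (see [identityMeans()]).
#' @param population population tag (default "population").
#' @param window window tag (default "").
#' @return A \linkS4class{DissimilarityMatrix}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
#' buildRDM(m)
#' @export
buildRDM <- function(means, population = "population", window = "") {
  means <- as.matrix(means)
  if (ncol(means) < 2)
    stop("at least 2 units are required")
  ids <- rownames(means) %||% paste0("id", seq_len(nrow(means)))
  zeroVar <- apply(means, 1L, sd) == 0
  D <- 1 - suppressWarnings(cor(t(means)))
  D[zeroVar, ] <- NA_real_
  D[, zeroVar] <- NA_real_
  diag(D) <- 0
  D <- pmin(pmax(D, 0), 2)
  dimnames(D) <- list(ids, ids)
  new("DissimilarityMatrix", D = D, identities = ids,
      population = population, window = window)
}

#' Spearman correlation between two dissimilarity matrices
#'
#' Rank correlation over the off-diagonal upper-triangle entries only;
#' identity sets and order must match. Pairs with NA (zero-variance) in
#' either matrix are excluded; Spearman ties are handled by average ranks.
#'
#' @param A,B \linkS4class{DissimilarityMatrix} objects on the same
#'   identities.
#' @return Spearman rho.
#' @export
rdmCorrelation <- function(A, B) {
  stopifnot(is(A, "DissimilarityMatrix"), is(B, "DissimilarityMatrix"))
  if (!identical(A@identities, B@identities))
    stop("identity sets (and order) must match")
  ut <- upper.tri(A@D)
  a <- A@D[ut]; b <- B@D[ut]
  ok <- complete.cases(a, b)
  if (sum(ok) < 3) stop("too few comparable identity pairs")
  cor(a[ok], b[ok], method = "spearman")
}

#' Label-shuffle permutation test of RDM correspondence
#'
#' Tests whether two populations share face-space geometry. The observed
#' statistic is the Spearman correlation between the two identity-level
#' RDMs. Under the null, the identity labels of the second population's
#' stimuli are shuffled before identity averaging, its RDM rebuilt, and
#' the correlation recomputed, \code{nPerm} times. Significance follows
#' the rule that the observed correlation exceed 95\% of the null
#' distribution (one-sided at alpha); the p-value uses the add-one
#' estimator p = (1 + #\{null >= observed\}) / (1 + nPerm), which can
#' never be exactly zero.
#'
#' @param refResponses stimuli x units matrix (reference population, e.g.
#'   network units), or an \linkS4class{ActivationSet}.
#' @param testResponses stimuli x units matrix (test population, e.g.
#'   neurons) over the same stimuli, or an \linkS4class{ActivationSet}.
#' @param identity identity per stimulus (taken from the ActivationSet
#'   when omitted).
#' @param nPerm number of permutation runs (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param subsetIds optional identity subset (e.g. from
#'   [topEncodedSubset()]) on which to compute the correspondence.
#' @return list: \code{rho}, \code{p}, \code{significant}, \code{null}
#'   (the permutation distribution), \code{nPerm}.
#' @export
rdmPermutationTest <- function(refResponses, testResponses, identity = NULL,
                               nPerm = 1000L, alpha = 0.05, seed = 1L,
                               subsetIds = NULL) {
  if (is(refResponses, "ActivationSet")) {
    identity <- identity %||% identities(refResponses)
    refResponses <- t(responses(refResponses))
  }
  if (is(testResponses, "ActivationSet"))
    testResponses <- t(responses(testResponses))
  refResponses <- as.matrix(refResponses)
  testResponses <- as.matrix(testResponses)
  if (!is.null(rownames(refResponses)) && !is.null(rownames(testResponses))) {
    if (!setequal(rownames(refResponses), rownames(testResponses)))
      stop("stimulus sets of the two populations do not match")
    testResponses <- testResponses[rownames(refResponses), , drop = FALSE]
  } else if (nrow(refResponses) != nrow(testResponses))
    stop("the two populations must cover the same stimuli")
  if (is.null(identity)) stop("identity labels are required")
  identity <- droplevels(factor(identity))
  if (nPerm < 100) warning("nPerm < 100: unstable null tail")

  keepIds <- if (is.null(subsetIds)) levels(identity)
             else as.character(subsetIds)
  rdmOf <- function(resp, id) {
    m <- identityMeans(resp, id)
    buildRDM(m[keepIds, , drop = FALSE])
  }
  refRDM <- rdmOf(refResponses, identity)
  obs <- rdmCorrelation(refRDM, rdmOf(testResponses, identity))
  # permutation loop on raw matrices (no container overhead); identical
  # arithmetic to identityMeans + buildRDM + rdmCorrelation
  ut <- upper.tri(refRDM@D)
  refVec <- refRDM@D[ut]
  rdmVec <- function(id) {
    m <- rowsum(testResponses, id) / as.vector(table(id))
    (1 - suppressWarnings(cor(t(m[keepIds, , drop = FALSE]))))[ut]
  }
  spear <- function(a, b) {
    ok <- complete.cases(a, b)
    cor(a[ok], b[ok], method = "spearman")
  }
  set.seed(childSeed(seed, "rdmperm"))
  null <- vapply(seq_len(nPerm), function(i)
    spear(refVec, rdmVec(identity[sample.int(length(identity))])), 0)
  p <- (1 + sum(null >= obs)) / (1 + nPerm)
  list(rho = obs, p = p,
       significant = obs > quantile(null, 1 - alpha, names = FALSE),
       null = null, nPerm = nPerm)
}

#' Multiple-comparison correction across layers or bins
#'
#' @param p numeric vector of permutation p-values in (0, 1].
#' @param method "bonferroni" (flag when p * m < q) or "fdr_bh"
#'   (Benjamini-Hochberg step-up).
#' @param q significance level (default 0.05).
#' @return list: \code{flag} logical vector, \code{pAdjusted}.
#' @examples
#' correctLayers(c(0.001, 0.04, 0.2), method = "bonferroni")$flag
#' @export
correctLayers <- function(p, method = c("bonferroni", "fdr_bh"), q = 0.05) {
  method <- match.arg(method)
  if (!length(p)) stop("at least one p-value is required")
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    stop("p-values must lie in (0, 1]")
  adj <- p.adjust(p, method = if (method == "bonferroni") "bonferroni"
                              else "BH")
  list(flag = !is.na(adj) & adj < q, pAdjusted = adj)
}

#' Temporal dynamics of RDM correspondence
#'
#' Runs the full pipeline (windowed rates, repeat averaging, identity
#' means, RDM, Spearman correlation, label-shuffle permutation) in every
#' sliding bin, then corrects across bins.
#'
#' @param st a \linkS4class{SpikeTrains}.
#' @param refResponses stimuli x units matrix or \linkS4class{ActivationSet}
#'   (reference geometry; its stimulus order must match the stimulus ids in
#'   \code{st}).
#' @param bins data.frame of bins from [slidingBins()] (e.g. [humanBins()]).
#' @param identity identity per stimulus (from the ActivationSet when
#'   omitted).
#' @param nPerm,alpha,seed as in [rdmPermutationTest()].
#' @param method correction across bins (default "fdr_bh").
#' @param pad passed to [windowRate()].
#' @return data.frame: \code{start}, \code{end}, \code{rho}, \code{p},
#'   \code{significant} (after correction). Bins in which no neuron fires
#'   anywhere have NA rho and are never significant.
#' @export
temporalCorrespondence <- function(st, refResponses, bins, identity = NULL,
                                   nPerm = 1000L, alpha = 0.05, seed = 1L,
                                   method = c("fdr_bh", "bonferroni"),
                                   pad = FALSE) {
  stopifnot(is(st, "SpikeTrains"))
  method <- match.arg(method)
  if (is(refResponses, "ActivationSet")) {
    identity <- identity %||% identities(refResponses)
    refResponses <- t(responses(refResponses))
  }
  refStim <- rownames(refResponses)
  tr <- st@trials
  rho <- p <- rep(NA_real_, nrow(bins))
  for (b in seq_len(nrow(bins))) {
    r <- windowRate(st, bins$start[b], bins$end[b], pad = pad)
    if (all(r == 0)) next                     # empty bin: undefined
    m <- averageRepeats(r, tr$stimulus_id)
    if (!is.null(refStim) && all(refStim %in% colnames(m)))
      m <- m[, refStim, drop = FALSE]         # align stimulus order
    else if (ncol(m) != nrow(refResponses))
      stop("stimulus sets of spikes and reference do not match")
    if (all(apply(m, 1L, sd) == 0)) next      # constant rates: no geometry
    res <- tryCatch(
      rdmPermutationTest(refResponses, t(m), identity = identity,
                         nPerm = nPerm, alpha = alpha,
                         seed = childSeed(seed, paste0("bin", b))),
      error = function(e) NULL)
    if (!is.null(res)) { rho[b] <- res$rho; p[b] <- res$p }
  }
  flag <- rep(FALSE, nrow(bins))
  ok <- !is.na(p)
  if (any(ok)) flag[ok] <- correctLayers(p[ok], method, q = alpha)$flag
  data.frame(start = bins$start, end = bins$end, rho = rho, p = p,
             significant = flag)
}

#' Most frequently encoded identities
#'
#' Ranks identities by the number of units/neurons that encode them
#' (from a classified \linkS4class{SelectivityProfile}) and returns the
#' top k. Ties are broken by identity label order (deterministic).
#'
#' @param profile a classified \linkS4class{SelectivityProfile}.
#' @param k how many identities (default 10).
#' @return character vector of identities, most-encoded first; fewer than
#'   k (with a warning) when fewer identities are ever encoded.
#' @export
topEncodedSubset <- function(profile, k = 10L) {
  stopifnot(is(profile, "SelectivityProfile"))
  counts <- table(unlist(profile@encoded))
  if (!length(counts)) {
    warning("no identity is encoded by any unit")
    return(character(0))
  }
  ord <- order(-as.vector(counts), names(counts))
  ranked <- names(counts)[ord]
  if (length(ranked) < k) {
    warning("only ", length(ranked), " identities ever encoded; ",
            "returning all")
    return(ranked)
  }
  ranked[seq_len(k)]
}
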