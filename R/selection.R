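# Identity-selectivity screening and SI/MI taxonomy.
#
# A unit is identity-selective when a one-way ANOVA of its responses across
# identity groups rejects equality (p < alpha, default 0.01). Independently,
# its encoded identities are those whose identity-mean response exceeds the
# mean of all identity means by k SD (default 2) of the identity-mean
# distribution. Selective units with exactly one encoded identity are SI,
# with two or more MI; selective units with an empty encoded set are
# "selective-other"; the rest are non-selective. The identical procedure
# runs on artificial unit activations and on windowed neuronal firing rates.

#' One-way ANOVA selectivity screen
#'
#' Computes, for every unit, the one-way ANOVA F-test of response across
#' identity groups, vectorized over units. Constant-response units are
#' defined non-selective (p = 1) rather than an error, since dead units are
#' common in rectified networks.
#'
#' @param acts an \linkS4class{ActivationSet}.
#' @param alpha screen level; a unit is selective when p < alpha
#'   (default 0.01).
#' @return A \linkS4class{SelectivityProfile} with \code{pAnova} and
#'   \code{selective} filled; encoded sets and classes are empty until
#'   [classifyUnits()].
#' @examples
#' g <- genActivations(syntheticSpec(unitsPerLayer = 40, nIdentities = 10,
#'                                   seed = 3))
#' prof <- anovaScreen(g$layers[[1]])
#' mean(prof@selective)
#' @export
anovaScreen <- function(acts, alpha = 0.01) {
  stopifnot(is(acts, "ActivationSet"), alpha > 0, alpha < 1)
  X <- responses(acts)
  g <- droplevels(identities(acts))
  if (nlevels(g) < 2) stop("at least 2 identities are required")
  ng <- table(g)
  if (any(ng < 2)) stop("every identity group needs at least 2 stimuli")
  N <- ncol(X); k <- nlevels(g)
  gm <- t(rowsum(t(X), g) / as.vector(ng))          # units x identities
  mu <- rowMeans(X)
  ssb <- as.vector((gm - mu)^2 %*% as.vector(ng))
  sst <- rowSums((X - mu)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  const <- (apply(X, 1L, max) - apply(X, 1L, min)) == 0
  p[const] <- 1
  p[!const & ssw == 0] <- 0                          # perfectly separated
  new("SelectivityProfile",
      unitId = rownames(X), pAnova = unname(p),
      selective = unname(p < alpha),
      encoded = rep(list(character(0)), nrow(X)),
      unitClass = rep(NA_character_, nrow(X)),
      alpha = alpha, kSd = NA_real_, layerId = layerId(acts))
}

#' Encoded identities of a single unit
#'
#' An identity is encoded when its identity-mean response exceeds the mean
#' of all identity-mean responses by \code{kSd} standard deviations of the
#' identity-mean distribution. Both the mean and the SD are computed over
#' the identity means (not over individual trials), which makes the
#' criterion independent of the number of images per identity. The
#' criterion is separable from the ANOVA screen: it does not depend on
#' \code{alpha}.
#'
#' @param response numeric vector of per-stimulus responses for one unit.
#' @param identity identity label per stimulus.
#' @param kSd SD multiplier (default 2).
#' @return character vector of encoded identities (possibly empty), sorted.
#' @examples
#' r <- c(rep(10, 3), rep(0, 27))
#' encodedIdentities(r, rep(letters[1:10], each = 3))
#' @export
encodedIdentities <- function(response, identity, kSd = 2) {
  identity <- droplevels(factor(identity))
  if (nlevels(identity) < 3)
    stop("at least 3 identities are required for the SD criterion")
  m <- tapply(response, identity, mean)
  thr <- mean(m) + kSd * sd(m)
  sort(names(m)[!is.na(m) & m > thr])
}

# vectorized encoded-identity computation over all units of a matrix
encodedIdentitiesMatrix <- function(X, identity, kSd = 2) {
  identity <- droplevels(factor(identity))
  if (nlevels(identity) < 3)
    stop("at least 3 identities are required for the SD criterion")
  ng <- table(identity)
  gm <- t(rowsum(t(X), identity) / as.vector(ng))    # units x identities
  mu <- rowMeans(gm)
  s <- apply(gm, 1L, sd)
  hits <- gm > mu + kSd * s
  lapply(seq_len(nrow(X)), function(u)
    sort(colnames(gm)[hits[u, ]]))
}

#' Classify units as SI / MI / selective-other / non-selective
#'
#' Fills the encoded-identity sets and class labels of a screen profile.
#' SI and MI labels are assigned only among screen-selective units; a
#' selective unit whose encoded set is empty is "selective-other"; all
#' remaining units are non-selective with an empty encoded set. The four
#' classes partition the units.
#'
#' @param profile a \linkS4class{SelectivityProfile} from [anovaScreen()].
#' @param acts the \linkS4class{ActivationSet} the profile was computed on.
#' @param kSd SD multiplier of the encoded-identity criterion (default 2).
#' @return The completed \linkS4class{SelectivityProfile}.
#' @export
classifyUnits <- function(profile, acts, kSd = 2) {
  stopifnot(is(profile, "SelectivityProfile"), is(acts, "ActivationSet"))
  X <- responses(acts)
  if (!identical(rownames(X), profile@unitId))
    stop("profile and activations refer to different units")
  enc <- encodedIdentitiesMatrix(X, identities(acts), kSd)
  nenc <- lengths(enc)
  cls <- ifelse(!profile@selective, "non-selective",
         ifelse(nenc == 1L, "SI",
         ifelse(nenc >= 2L, "MI", "selective-other")))
  enc[cls %in% c("non-selective")] <- list(character(0))
  profile@encoded <- enc
  profile@unitClass <- cls
  profile@kSd <- kSd
  validObject(profile)
  profile
}

#' Full selectivity profile in one call
#'
#' Convenience wrapper: [anovaScreen()] followed by [classifyUnits()].
#'
#' @inheritParams anovaScreen
#' @inheritParams classifyUnits
#' @return A completed \linkS4class{SelectivityProfile}.
#' @export
selectivityProfile <- function(acts, alpha = 0.01, kSd = 2) {
  classifyUnits(anovaScreen(acts, alpha), acts, kSd)
}

#' Per-layer selectivity summary
#'
#' @param profiles a \linkS4class{SelectivityProfile} or a list of them
#'   (one per layer).
#' @return data.frame with one row per layer: \code{layer}, \code{n_units},
#'   \code{pct_selective}, \code{pct_SI}, \code{pct_MI} (percentages in
#'   [0, 100]), and \code{mean_encoded_MI} / \code{max_encoded_MI} computed
#'   over MI units only (NA when a layer has no MI units).
#' @export
layerSummary <- function(profiles) {
  if (is(profiles, "SelectivityProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    stopifnot(is(p, "SelectivityProfile"))
    if (all(is.na(p@unitClass)))
      stop("classify units before summarizing (see classifyUnits)")
    n <- length(p@unitId)
    if (n < 1) stop("layer with zero units")
    nSel <- sum(p@selective)
    mi <- p@unitClass == "MI"
    nenc <- lengths(p@encoded)[mi]
    data.frame(layer = p@layerId, n_units = n,
               pct_selective = 100 * nSel / n,
               pct_SI = 100 * sum(p@unitClass == "SI") / n,
               pct_MI = 100 * sum(mi) / n,
               mean_encoded_MI = if (any(mi)) mean(nenc) else NA_real_,
               max_encoded_MI = if (any(mi)) max(nenc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two selectivity proportions
#'
#' Pearson chi-squared test (2 x 2, no continuity correction) of two
#' proportions, e.g. the fraction of SI units in a network layer versus SI
#' neurons in a recorded population, with Bonferroni correction for a
#' stated number of comparisons (p multiplied by \code{nComparisons},
#' capped at 1).
#'
#' @param hitsA,totalA successes and total of population A.
#' @param hitsB,totalB successes and total of population B.
#' @param nComparisons Bonferroni multiplier (default 1).
#' @return list with \code{chisq}, \code{p} (uncorrected) and
#'   \code{pCorrected}.
#' @examples
#' compareProportions(90, 100, 10, 100)$pCorrected
#' @export
compareProportions <- function(hitsA, totalA, hitsB, totalB,
                               nComparisons = 1L) {
  stopifnot(totalA > 0, totalB > 0, nComparisons >= 1)
  if (hitsA > totalA || hitsB > totalB)
    stop("hits cannot exceed totals")
  tab <- rbind(c(hitsA, totalA - hitsA), c(hitsB, totalB - hitsB))
  if (hitsA / totalA == hitsB / totalB) {
    chisq <- 0; p <- 1                      # identical proportions
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chisq <- unname(ct$statistic); p <- ct$p.value
  }
  list(chisq = chisq, p = p, pCorrected = min(1, p * nComparisons))
}
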