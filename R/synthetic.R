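# Synthetic data with planted ground truth. Every generator is a pure
# function of its arguments including the seed; a single global seed fans
# out to per-component child seeds so independent streams stay independent.

#' Derive a child seed from a global seed and a stream key
#'
#' Deterministic fan-out of one global seed into independent per-component
#' streams. The result is always in [0, 2^31 - 2] so it is a valid R integer
#' seed.
#'
#' @param seed integer global seed.
#' @param key character stream name.
#' @return integer child seed.
#' @examples
#' childSeed(1, "activations") != childSeed(1, "spikes")
#' @export
childSeed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * (seq_along(utf8ToInt(as.character(key))) %% 31L + 1L))
  as.integer((as.double(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

#' Specification of a synthetic activation experiment
#'
#' Describes the stimulus design (identities x images per identity), the unit
#' population per layer, and the planted selectivity structure. Defaults
#' mirror the 50-identity, 10-image design with a moderate selective
#' subpopulation.
#'
#' @param nLayers number of layers to generate.
#' @param unitsPerLayer units per layer.
#' @param nIdentities number of identities (default 50).
#' @param nPerIdentity images per identity (default 10).
#' @param fracSelective fraction of units with planted identity selectivity.
#' @param fracMulti fraction of selective units encoding >= 2 identities.
#' @param effectSize standardized mean shift (Cohen's d) of encoded-identity
#'   responses relative to the noise SD.
#' @param noiseSd response noise scale.
#' @param baseline mean baseline response; chosen large relative to
#'   \code{noiseSd} so the non-negativity rectification almost never binds.
#' @param seed integer seed.
#' @return A list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(nLayers = 1L, unitsPerLayer = 500L,
                          nIdentities = 50L, nPerIdentity = 10L,
                          fracSelective = 0.2, fracMulti = 0.3,
                          effectSize = 3, noiseSd = 1, baseline = 5,
                          seed = 1L) {
  spec <- list(nLayers = as.integer(nLayers),
               unitsPerLayer = as.integer(unitsPerLayer),
               nIdentities = as.integer(nIdentities),
               nPerIdentity = as.integer(nPerIdentity),
               fracSelective = fracSelective, fracMulti = fracMulti,
               effectSize = effectSize, noiseSd = noiseSd,
               baseline = baseline, seed = as.integer(seed))
  with(spec, {
    stopifnot(nLayers >= 1, unitsPerLayer >= 1, nIdentities >= 1,
              nPerIdentity >= 1, noiseSd >= 0, effectSize >= 0,
              baseline >= 0)
    if (fracSelective < 0 || fracSelective > 1 ||
        fracMulti < 0 || fracMulti > 1)
      stop("fractions must lie in [0, 1]")
  })
  class(spec) <- "syntheticSpec"
  spec
}

#' Generate activation matrices with planted identity selectivity
#'
#' Draws, for each layer, a units x stimuli response matrix in which a
#' controlled fraction of units carry planted identity selectivity: each
#' selective unit's encoded identities are shifted upward by
#' \code{effectSize * noiseSd} on top of i.i.d. Gaussian noise around a
#' common baseline. Responses are rectified at zero, matching the
#' post-ReLU convention of network activations. Single-identity (SI)
#' plants encode exactly one identity; multiple-identity (MI) plants
#' encode 2-4.
#'
#' @param spec a [syntheticSpec()].
#' @return A list with elements \code{layers} (list of
#'   \linkS4class{ActivationSet}, one per layer) and \code{truth}
#'   (data.frame: \code{layer}, \code{unit_id}, \code{class} in
#'   \{SI, MI, non\}, list column \code{encoded}).
#' @examples
#' g <- genActivations(syntheticSpec(unitsPerLayer = 50, nIdentities = 10,
#'                                   seed = 7))
#' g$layers[[1]]
#' table(g$truth$class)
#' @export
genActivations <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  nSel <- round(spec$fracSelective * spec$unitsPerLayer)
  if (spec$fracSelective > 0 && nSel < 1)
    stop("fracSelective * unitsPerLayer < 1: no selective unit can be planted")
  nStim <- spec$nIdentities * spec$nPerIdentity
  idLevels <- sprintf("id%02d", seq_len(spec$nIdentities))
  identity <- factor(rep(idLevels, each = spec$nPerIdentity),
                     levels = idLevels)
  layers <- vector("list", spec$nLayers)
  truth <- vector("list", spec$nLayers)
  for (l in seq_len(spec$nLayers)) {
    set.seed(childSeed(spec$seed, paste0("activations", l)))
    nMi <- round(spec$fracMulti * nSel)
    cls <- c(rep("MI", nMi), rep("SI", nSel - nMi),
             rep("non", spec$unitsPerLayer - nSel))
    cls <- sample(cls)                      # shuffle unit order
    resp <- matrix(spec$baseline + rnorm(spec$unitsPerLayer * nStim,
                                         sd = spec$noiseSd),
                   nrow = spec$unitsPerLayer, ncol = nStim)
    encoded <- vector("list", spec$unitsPerLayer)
    for (u in seq_len(spec$unitsPerLayer)) {
      k <- switch(cls[u], SI = 1L, MI = sample(2:4, 1L), 0L)
      if (k > 0) {
        ids <- sample(idLevels, k)
        encoded[[u]] <- sort(ids)
        shift <- spec$effectSize * spec$noiseSd
        resp[u, identity %in% ids] <- resp[u, identity %in% ids] + shift
      } else encoded[[u]] <- character(0)
    }
    resp <- pmax(resp, 0)                   # rectified responses
    rownames(resp) <- sprintf("L%d_u%03d", l, seq_len(spec$unitsPerLayer))
    layerName <- paste0("layer", l)
    layers[[l]] <- ActivationSet(resp, identity, layerId = layerName)
    tr <- data.frame(layer = layerName, unit_id = rownames(resp),
                     class = cls, stringsAsFactors = FALSE)
    tr$encoded <- encoded
    truth[[l]] <- tr
  }
  names(layers) <- paste0("layer", seq_len(spec$nLayers))
  list(layers = layers, truth = do.call(rbind, truth))
}

#' Generate pseudo-neuron spike trains coupled to a reference geometry
#'
#' Simulates Poisson-spiking neurons whose post-latency firing rate mixes,
#' with weight \code{coupling}, a projection of a reference unit population's
#' response geometry with (1 - coupling) independent noise. Each neuron is
#' yoked to one reference unit; its stimulus drive is the z-scored reference
#' response entering the rate linearly (floored at 0 Hz; the floor almost
#' never binds at the default gain), so at \code{coupling = 1} the
#' underlying rate is an increasing affine transform of the reference
#' response and the neuron's identity-mean rate vector rank-correlates
#' perfectly with the reference unit's identity means. Before the response
#' latency the rate is an identity-independent baseline.
#'
#' @param nNeurons number of neurons.
#' @param reference an \linkS4class{ActivationSet} supplying the shared
#'   geometry.
#' @param coupling mixing weight in [0, 1].
#' @param latencyMs response latency in ms (>= 0).
#' @param nRepeats presentations per stimulus.
#' @param tMinMs,tMaxMs trial coverage in ms relative to onset.
#' @param baselineRate pre-latency (and mean post-latency) rate in Hz.
#' @param gain rate modulation depth: rate = baselineRate * (1 + gain *
#'   drive), floored at 0 Hz.
#' @param seed integer seed.
#' @return A \linkS4class{SpikeTrains}; the underlying per-(neuron, stimulus)
#'   post-latency rates are attached as metadata in
#'   \code{attr(, "rates")} (neurons x stimuli, Hz), with
#'   \code{attr(, "latencyMs")}.
#' @export
genPseudoNeurons <- function(nNeurons, reference, coupling,
                             latencyMs = 250, nRepeats = 5L,
                             tMinMs = -500, tMaxMs = 1500,
                             baselineRate = 10, gain = 0.25, seed = 1L) {
  stopifnot(is(reference, "ActivationSet"),
            coupling >= 0, coupling <= 1, nNeurons >= 1)
  if (latencyMs < 0) stop("latency must be non-negative")
  if (tMaxMs <= latencyMs) stop("trial must extend beyond the latency")
  set.seed(childSeed(seed, "pseudoneurons"))
  ref <- responses(reference)               # units x stimuli
  nStim <- ncol(ref)
  identity <- identities(reference)
  refUnit <- sample(nrow(ref), nNeurons, replace = TRUE)
  zscore <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  drive <- matrix(0, nNeurons, nStim)
  for (j in seq_len(nNeurons)) {
    sig <- zscore(ref[refUnit[j], ])
    eps <- rnorm(nStim)
    drive[j, ] <- coupling * sig + (1 - coupling) * eps
  }
  rates <- pmax(baselineRate * (1 + gain * drive), 0)  # Hz, affine in drive
  rownames(rates) <- sprintf("n%03d", seq_len(nNeurons))
  colnames(rates) <- colnames(ref)

  trials <- data.frame(
    trial_id = seq_len(nStim * nRepeats),
    stimulus_id = rep(colnames(ref), times = nRepeats),
    identity = rep(as.character(identity), times = nRepeats),
    t_min_ms = tMinMs, t_max_ms = tMaxMs,
    stringsAsFactors = FALSE)
  stimIdx <- rep(seq_len(nStim), times = nRepeats)

  preDur <- (latencyMs - tMinMs) / 1000     # s, baseline epoch
  postDur <- (tMaxMs - latencyMs) / 1000    # s, driven epoch
  sp <- vector("list", nNeurons)
  for (j in seq_len(nNeurons)) {
    nPre <- rpois(nrow(trials), baselineRate * preDur)
    nPost <- rpois(nrow(trials), rates[j, stimIdx] * postDur)
    tPre <- runif(sum(nPre), tMinMs, latencyMs)
    tPost <- runif(sum(nPost), latencyMs, tMaxMs)
    sp[[j]] <- data.frame(
      neuron_id = rownames(rates)[j],
      trial_id = c(rep(trials$trial_id, nPre), rep(trials$trial_id, nPost)),
      t_ms = c(tPre, tPost), stringsAsFactors = FALSE)
  }
  st <- SpikeTrains(do.call(rbind, sp), trials,
                    neurons = data.frame(neuron_id = rownames(rates),
                                         region = "synthetic"))
  attr(st, "rates") <- rates
  attr(st, "latencyMs") <- latencyMs
  st
}

#' Generate toy identity-structured images
#'
#' All images share a common grating scaffold; each identity is defined by
#' a deterministic pair of Gaussian blobs at identity-specific positions,
#' so identity information is spatially localized (as facial features
#' are), not spread over every pixel. Images of the same identity differ
#' by small positional jitter and pixel noise, so within-identity pixel
#' distances are smaller than between-identity distances by construction.
#' Pixel values lie in [0, 1].
#'
#' @param nIdentities,nPerIdentity stimulus design.
#' @param sizePx image side length in pixels (>= 16).
#' @param jitterPx maximum positional jitter in pixels.
#' @param noiseSd pixel noise SD.
#' @param seed integer seed.
#' @return list with \code{images} (array sizePx x sizePx x nImages) and
#'   \code{labels} (data.frame: stimulus_id, identity_id, image_index).
#' @export
genToyFaces <- function(nIdentities, nPerIdentity, sizePx = 16L,
                        jitterPx = 1, noiseSd = 0.15, seed = 1L) {
  if (sizePx < 16) stop("sizePx must be >= 16")
  set.seed(childSeed(seed, "toyfaces"))
  n <- nIdentities * nPerIdentity
  imgs <- array(0, c(sizePx, sizePx, n))
  xy <- seq(0, 1, length.out = sizePx)
  labs <- data.frame(stimulus_id = sprintf("s%03d", seq_len(n)),
                     identity_id = rep(sprintf("id%02d", seq_len(nIdentities)),
                                       each = nPerIdentity),
                     image_index = rep(seq_len(nPerIdentity), nIdentities),
                     stringsAsFactors = FALSE)
  # shared scaffold; identity-specific deterministic blob positions
  gx <- outer(xy, rep(1, sizePx)) * cos(pi / 6) +
        outer(rep(1, sizePx), xy) * sin(pi / 6)
  scaffold <- sin(2 * pi * 3 * gx)
  cx1 <- 0.15 + 0.7 * ((seq_len(nIdentities) * 7) %% 11) / 10
  cy1 <- 0.15 + 0.7 * ((seq_len(nIdentities) * 3) %% 11) / 10
  cx2 <- 0.15 + 0.7 * ((seq_len(nIdentities) * 5 + 4) %% 11) / 10
  cy2 <- 0.15 + 0.7 * ((seq_len(nIdentities) * 9 + 2) %% 11) / 10
  gauss2 <- function(cx, cy, s2)
    exp(-((outer(xy, rep(1, sizePx)) - cx)^2 +
          (outer(rep(1, sizePx), xy) - cy)^2) / (2 * s2))
  k <- 0L
  for (i in seq_len(nIdentities)) {
    for (m in seq_len(nPerIdentity)) {
      k <- k + 1L
      dx <- runif(2, -jitterPx, jitterPx) / sizePx
      dy <- runif(2, -jitterPx, jitterPx) / sizePx
      img <- 0.45 + 0.12 * scaffold +
        0.4 * gauss2(cx1[i] + dx[1], cy1[i] + dy[1], 0.004) +
        0.4 * gauss2(cx2[i] + dx[2], cy2[i] + dy[2], 0.004) +
        rnorm(sizePx^2, sd = noiseSd)
      imgs[, , k] <- pmin(pmax(img, 0), 1)
    }
  }
  list(images = imgs, labels = labs)
}
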