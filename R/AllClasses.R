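#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pf sd cor quantile rnorm runif rpois predict prcomp
#'   p.adjust chisq.test setNames aggregate complete.cases wilcox.test
#' @importFrom utils head read.delim write.table
NULL

#' ActivationSet: unit responses to labelled stimuli
#'
#' An \code{ActivationSet} stores a units x stimuli response matrix together
#' with the identity label of every stimulus. It extends
#' \linkS4class{SummarizedExperiment}: rows are units, columns are stimuli,
#' the single assay is named \code{"response"}, and \code{colData} carries
#' \code{stimulus_id} and \code{identity}. The same container holds artificial
#' unit activations (arbitrary units) and neuronal firing rates (Hz), so the
#' selectivity screen, decoding and representational analyses run unchanged on
#' either system.
#'
#' @slot layerId single character label for the population (e.g. a network
#'   layer name or a brain region).
#'
#' @seealso [ActivationSet()], [anovaScreen()], [identityMeans()]
#' @exportClass ActivationSet
setClass("ActivationSet",
  contains = "SummarizedExperiment",
  representation(layerId = "character"))

setValidity("ActivationSet", function(object) {
  msg <- character()
  if (length(object@layerId) != 1L)
    msg <- c(msg, "'layerId' must be a single string")
  if (!"response" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'response' is required")
  else if (anyNA(SummarizedExperiment::assay(object, "response")))
    msg <- c(msg, "responses must not contain missing values")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("stimulus_id", "identity") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'stimulus_id' and 'identity'")
  if (length(msg)) msg else TRUE
})

#' Construct an ActivationSet
#'
#' @param response numeric matrix, units x stimuli. Row names are unit ids
#'   (generated if absent); column names are stimulus ids.
#' @param identity identity label per stimulus (coerced to factor); length
#'   must equal \code{ncol(response)}.
#' @param layerId single character label for the population.
#' @param stimulusId optional stimulus ids; defaults to column names or
#'   \code{"s1"..}.
#'
#' @return An \linkS4class{ActivationSet}.
#' @examples
#' r <- matrix(rnorm(40), 4, 10)
#' a <- ActivationSet(r, identity = rep(c("A", "B"), each = 5))
#' responses(a)[1:2, 1:3]
#' table(identities(a))
#' @export
ActivationSet <- function(response, identity, layerId = "layer1",
                          stimulusId = NULL) {
  response <- as.matrix(response)
  if (length(identity) != ncol(response))
    stop("'identity' must have one label per stimulus (column)")
  if (is.null(rownames(response)))
    rownames(response) <- paste0("u", seq_len(nrow(response)))
  if (is.null(stimulusId))
    stimulusId <- colnames(response)
  if (is.null(stimulusId))
    stimulusId <- paste0("s", seq_len(ncol(response)))
  colnames(response) <- stimulusId
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(response = response),
    colData = S4Vectors::DataFrame(
      stimulus_id = stimulusId,
      identity = factor(identity)))
  new("ActivationSet", se, layerId = as.character(layerId))
}

#' @describeIn ActivationSet-class the units x stimuli response matrix.
#' @param x,object an \code{ActivationSet}.
#' @export
responses <- function(x) SummarizedExperiment::assay(x, "response")

#' @describeIn ActivationSet-class factor of identity labels, one per
#'   stimulus.
#' @export
identities <- function(x) SummarizedExperiment::colData(x)$identity

#' @describeIn ActivationSet-class the population label.
#' @export
layerId <- function(x) x@layerId

setMethod("show", "ActivationSet", function(object) {
  cat("ActivationSet '", object@layerId, "': ",
      nrow(object), " units x ", ncol(object), " stimuli, ",
      nlevels(identities(object)), " identities\n", sep = "")
})

#' SelectivityProfile: per-unit identity-selectivity results
#'
#' Holds, for each unit of one population, the one-way ANOVA p-value of the
#' selectivity screen, the screen flag, the set of encoded identities under
#' the 2-SD criterion, and the resulting class: \code{"SI"} (single encoded
#' identity), \code{"MI"} (two or more), \code{"selective-other"} (screen
#' passed, empty encoded set) or \code{"non-selective"}.
#'
#' @slot unitId character, unit identifiers.
#' @slot pAnova numeric, screen p-values in [0,1].
#' @slot selective logical, \code{pAnova < alpha}.
#' @slot encoded list of character vectors, encoded identities per unit
#'   (empty for non-selective units).
#' @slot unitClass character, one of SI / MI / selective-other /
#'   non-selective, or NA before classification.
#' @slot alpha,kSd numeric scalars: screen level and SD multiplier used.
#' @slot layerId population label.
#' @seealso [anovaScreen()], [classifyUnits()], [layerSummary()]
#' @exportClass SelectivityProfile
setClass("SelectivityProfile",
  representation(unitId = "character", pAnova = "numeric",
                 selective = "logical", encoded = "list",
                 unitClass = "character", alpha = "numeric",
                 kSd = "numeric", layerId = "character"))

setValidity("SelectivityProfile", function(object) {
  n <- length(object@unitId)
  msg <- character()
  if (length(object@pAnova) != n || length(object@selective) != n ||
      length(object@encoded) != n || length(object@unitClass) != n)
    msg <- c(msg, "all per-unit slots must have equal length")
  if (any(object@pAnova < 0 | object@pAnova > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0,1]")
  ok <- is.na(object@unitClass) |
    object@unitClass %in% c("SI", "MI", "selective-other", "non-selective")
  if (!all(ok))
    msg <- c(msg, "invalid unit class label")
  cls <- object@unitClass
  nenc <- lengths(object@encoded)
  bad <- !is.na(cls) &
    ((cls == "SI" & nenc != 1L) | (cls == "MI" & nenc < 2L) |
     (cls %in% c("selective-other", "non-selective") & nenc != 0L))
  if (any(bad))
    msg <- c(msg, "encoded-set sizes inconsistent with unit classes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectivityProfile", function(object) {
  cat("SelectivityProfile '", object@layerId, "': ",
      length(object@unitId), " units (alpha=", object@alpha,
      ", kSd=", object@kSd, ")\n", sep = "")
  if (!all(is.na(object@unitClass)))
    print(table(factor(object@unitClass,
      levels = c("SI", "MI", "selective-other", "non-selective"))))
})

#' @describeIn SelectivityProfile-class coerce to a data.frame (the
#'   \code{encoded} column is a list column).
#' @param x a \code{SelectivityProfile}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "SelectivityProfile", function(x, ...) {
  d <- data.frame(unit_id = x@unitId, p_anova = x@pAnova,
                  selective = x@selective, unit_class = x@unitClass,
                  n_encoded = lengths(x@encoded),
                  stringsAsFactors = FALSE)
  d$encoded <- x@encoded
  d
})

#' @describeIn SelectivityProfile-class list of encoded-identity sets.
#' @param object a \code{SelectivityProfile}.
#' @export
encodedSets <- function(object) {
  stopifnot(is(object, "SelectivityProfile"))
  setNames(object@encoded, object@unitId)
}

#' @describeIn SelectivityProfile-class per-unit class labels.
#' @export
unitClasses <- function(object) {
  stopifnot(is(object, "SelectivityProfile"))
  setNames(object@unitClass, object@unitId)
}

#' SpikeTrains: onset-aligned spike times with trial metadata
#'
#' Container for single-unit (or multi-unit) spiking data. Spike times are in
#' milliseconds relative to stimulus onset (0 = onset). Trials with no spikes
#' are represented through the trial table, so windowed rates are defined for
#' every (neuron, trial) pair.
#'
#' @slot spikes data.frame with columns \code{neuron_id}, \code{trial_id},
#'   \code{t_ms} (one row per spike).
#' @slot trials data.frame with columns \code{trial_id}, \code{stimulus_id},
#'   \code{identity}, plus optional \code{t_min_ms}/\code{t_max_ms} recording
#'   coverage and logical \code{one_back}.
#' @slot neurons data.frame with columns \code{neuron_id} and optional
#'   \code{region}.
#' @seealso [SpikeTrains()], [windowRate()], [slidingBins()]
#' @exportClass SpikeTrains
setClass("SpikeTrains",
  representation(spikes = "data.frame", trials = "data.frame",
                 neurons = "data.frame"))

setValidity("SpikeTrains", function(object) {
  msg <- character()
  if (!all(c("neuron_id", "trial_id", "t_ms") %in% colnames(object@spikes)))
    msg <- c(msg, "spikes needs columns neuron_id, trial_id, t_ms")
  if (!all(c("trial_id", "stimulus_id", "identity") %in%
           colnames(object@trials)))
    msg <- c(msg, "trials needs columns trial_id, stimulus_id, identity")
  if (anyDuplicated(object@trials$trial_id))
    msg <- c(msg, "duplicate trial ids")
  if (!"neuron_id" %in% colnames(object@neurons))
    msg <- c(msg, "neurons needs column neuron_id")
  if (nrow(object@spikes) &&
      !all(object@spikes$trial_id %in% object@trials$trial_id))
    msg <- c(msg, "spikes reference unknown trials")
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrains object
#'
#' @param spikes data.frame of spikes: \code{neuron_id}, \code{trial_id},
#'   \code{t_ms} (ms relative to stimulus onset).
#' @param trials data.frame of trials: \code{trial_id}, \code{stimulus_id},
#'   \code{identity}; optionally \code{t_min_ms}, \code{t_max_ms},
#'   \code{one_back}.
#' @param neurons optional data.frame (\code{neuron_id}, \code{region});
#'   derived from \code{spikes} when absent.
#' @param dropOneBack drop trials flagged \code{one_back} before analysis
#'   (repeat probes of an immediately preceding stimulus), default TRUE.
#' @return A \linkS4class{SpikeTrains}.
#' @export
SpikeTrains <- function(spikes, trials, neurons = NULL, dropOneBack = TRUE) {
  spikes <- as.data.frame(spikes)
  trials <- as.data.frame(trials)
  if (dropOneBack && "one_back" %in% colnames(trials)) {
    keep <- !(trials$one_back %in% TRUE)   # NA-safe: keep unflagged trials
    trials <- trials[keep, , drop = FALSE]
    spikes <- spikes[spikes$trial_id %in% trials$trial_id, , drop = FALSE]
  }
  if (is.null(neurons))
    neurons <- data.frame(neuron_id = sort(unique(spikes$neuron_id)))
  new("SpikeTrains", spikes = spikes, trials = trials,
      neurons = as.data.frame(neurons))
}

setMethod("show", "SpikeTrains", function(object) {
  cat("SpikeTrains: ", nrow(object@neurons), " neurons, ",
      nrow(object@trials), " trials, ", nrow(object@spikes),
      " spikes\n", sep = "")
})

#' @describeIn SpikeTrains-class trial metadata table.
#' @param object a \code{SpikeTrains}.
#' @export
trialTable <- function(object) object@trials

#' @describeIn SpikeTrains-class neuron metadata table.
#' @export
neuronTable <- function(object) object@neurons

#' DissimilarityMatrix: identity-level representational geometry
#'
#' Symmetric identity x identity matrix of 1 - Pearson r between the
#' population response vectors of each identity pair. Entries lie in [0, 2];
#' the diagonal is 0. Pairs involving a zero-variance response vector are NA
#' and are excluded from downstream rank correlations.
#'
#' @slot D numeric matrix of dissimilarities.
#' @slot identities character, row/column identity labels.
#' @slot population label of the source population.
#' @slot window label of the response window used (may be "").
#' @seealso [buildRDM()], [rdmCorrelation()], [rdmPermutationTest()]
#' @exportClass DissimilarityMatrix
setClass("DissimilarityMatrix",
  representation(D = "matrix", identities = "character",
                 population = "character", window = "character"))

setValidity("DissimilarityMatrix", function(object) {
  D <- object@D
  msg <- character()
  if (nrow(D) != ncol(D) || nrow(D) != length(object@identities))
    msg <- c(msg, "D must be square with one row per identity")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8,
                        check.attributes = FALSE)))
    msg <- c(msg, "D must be symmetric")
  if (any(abs(diag(D)) > 1e-8, na.rm = TRUE))
    msg <- c(msg, "diagonal must be zero")
  if (any(D < -1e-8 | D > 2 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "entries must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DissimilarityMatrix", function(object) {
  cat("DissimilarityMatrix (", object@population, ", ",
      length(object@identities), " identities",
      if (nzchar(object@window)) paste0(", window ", object@window),
      ")\n", sep = "")
})

#' @describeIn DissimilarityMatrix-class the dissimilarity matrix itself.
#' @param object a \code{DissimilarityMatrix}.
#' @export
dissimilarities <- function(object) object@D

#' Embedding: low-dimensional stimulus coordinates
#'
#' @slot coords numeric matrix, stimuli x d (d = 2 or 3).
#' @slot method character tag: "pca", "tsne", "umap" or "precomputed".
#' @slot params list of method parameters.
#' @slot seed integer seed used (NA for deterministic methods).
#' @seealso [buildEmbedding()], [densityMap()], [tuningRegion()]
#' @exportClass Embedding
setClass("Embedding",
  representation(coords = "matrix", method = "character", params = "list",
                 seed = "numeric"))

setValidity("Embedding", function(object) {
  msg <- character()
  if (!ncol(object@coords) %in% c(2L, 3L))
    msg <- c(msg, "coords must have 2 or 3 columns")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Embedding", function(object) {
  cat("Embedding (", object@method, "): ", nrow(object@coords),
      " stimuli x ", ncol(object@coords), "d\n", sep = "")
})

#' @describeIn Embedding-class stimulus coordinates (stimuli x d).
#' @param object an \code{Embedding}.
#' @export
coordinates <- function(object) object@coords
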