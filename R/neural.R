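# Windowed, normalized, repeat-averaged firing rates from spike trains,
# with reliability and rate-based quality filters and sliding-window
# binning. Windows are half-open [start, end) in ms relative to stimulus
# onset (0 = onset), so boundary spikes are never double counted and
# counting is additive over disjoint windows.

#' Windowed firing rate per (neuron, trial)
#'
#' Rate = spike count in [start, end) divided by the window duration, in
#' Hz. Trials with no spikes in the window have rate 0.
#'
#' @param st a \linkS4class{SpikeTrains}.
#' @param start,end window bounds in ms relative to onset (end > start).
#' @param pad allow windows extending beyond a trial's recorded coverage
#'   (\code{t_min_ms}/\code{t_max_ms} in the trial table); default FALSE:
#'   such windows are an error.
#' @return numeric matrix neurons x trials (Hz), dimnames from neuron and
#'   trial ids.
#' @examples
#' st <- SpikeTrains(
#'   data.frame(neuron_id = "n1", trial_id = 1, t_ms = seq(50, 650, 100)),
#'   data.frame(trial_id = 1, stimulus_id = "s1", identity = "A"))
#' windowRate(st, 0, 700)   # 7 spikes / 0.7 s = 10 Hz
#' @export
windowRate <- function(st, start, end, pad = FALSE) {
  stopifnot(is(st, "SpikeTrains"))
  if (end <= start) stop("window end must exceed start")
  tr <- st@trials
  if (!pad && all(c("t_min_ms", "t_max_ms") %in% colnames(tr)) &&
      any(start < tr$t_min_ms | end > tr$t_max_ms))
    stop("window exceeds trial coverage; set pad = TRUE to allow")
  nid <- as.character(st@neurons$neuron_id)
  tid <- as.character(tr$trial_id)
  counts <- matrix(0, length(nid), length(tid),
                   dimnames = list(nid, tid))
  sp <- st@spikes
  keep <- sp$t_ms >= start & sp$t_ms < end
  if (any(keep)) {
    tab <- table(factor(as.character(sp$neuron_id[keep]), levels = nid),
                 factor(as.character(sp$trial_id[keep]), levels = tid))
    counts <- counts + unclass(tab)
  }
  counts / ((end - start) / 1000)
}

#' Normalize rates to control (gray-image) trials
#'
#' Divides each neuron's rates by the mean of its control-trial rates, so a
#' normalized value of 1 means "at control level". Multiplicative gain
#' differences between channels cancel out.
#'
#' @param rates numeric matrix neurons x trials (or stimuli).
#' @param controlRates numeric matrix neurons x control trials (same row
#'   order), or a vector of per-neuron control means.
#' @return normalized rate matrix.
#' @export
baselineNormalize <- function(rates, controlRates) {
  rates <- as.matrix(rates)
  ctrl <- if (is.matrix(controlRates)) rowMeans(controlRates)
          else as.numeric(controlRates)
  if (length(ctrl) != nrow(rates))
    stop("one control mean per neuron is required")
  if (!length(ctrl)) stop("at least one control trial is required")
  if (any(ctrl == 0))
    stop("control mean rate of zero: normalization undefined")
  rates / ctrl
}

#' Average rates over repeated presentations of each stimulus
#'
#' @param rates numeric matrix neurons x trials.
#' @param stimulusOf stimulus id per trial (column).
#' @return numeric matrix neurons x stimuli of mean rates over available
#'   repeats, with the per-stimulus repeat counts in
#'   \code{attr(, "nRepeats")}.
#' @export
averageRepeats <- function(rates, stimulusOf) {
  rates <- as.matrix(rates)
  stimulusOf <- factor(stimulusOf)
  if (length(stimulusOf) != ncol(rates))
    stop("one stimulus id per trial (column) is required")
  nRep <- table(stimulusOf)
  m <- t(rowsum(t(rates), stimulusOf) / as.vector(nRep))
  attr(m, "nRepeats") <- as.vector(nRep)
  m
}

#' Spike trains to an identity-labelled ActivationSet
#'
#' Convenience: windowed rates, averaged over repeats, packaged as an
#' \linkS4class{ActivationSet} so the selectivity screen, decoding and
#' representational analyses run unchanged on neurons.
#'
#' @param st a \linkS4class{SpikeTrains}.
#' @param start,end response window in ms (e.g. 250-1000 for human MTL,
#'   70-180 for monkey IT).
#' @param layerId population label (default "neurons").
#' @param pad passed to [windowRate()].
#' @return An \linkS4class{ActivationSet}, neurons x stimuli.
#' @export
rateActivationSet <- function(st, start, end, layerId = "neurons",
                              pad = FALSE) {
  r <- windowRate(st, start, end, pad = pad)
  tr <- st@trials
  m <- averageRepeats(r, tr$stimulus_id)
  idOf <- tr$identity[match(colnames(m), as.character(tr$stimulus_id))]
  ActivationSet(m, idOf, layerId = layerId)
}

#' Split-half internal consistency per channel
#'
#' Reliability of each channel's stimulus-evoked response: repeats of every
#' stimulus are randomly split in half, per-half stimulus means are
#' correlated across stimuli (Pearson), the correlation is averaged over
#' random splits and Spearman-Brown corrected (2r / (1 + r)). A channel is
#' kept when its corrected consistency exceeds the threshold (default 0.6).
#'
#' @param rates numeric matrix neurons x trials.
#' @param stimulusOf stimulus id per trial.
#' @param threshold keep threshold (default 0.6, strict >).
#' @param nSplits number of random splits averaged (default 50).
#' @param seed integer seed.
#' @return data.frame: \code{neuron_id} (rownames of \code{rates}),
#'   \code{consistency}, \code{keep}. Channels with fewer than 2 repeats of
#'   some stimulus are unevaluable (NA consistency, keep = NA).
#' @export
internalConsistency <- function(rates, stimulusOf, threshold = 0.6,
                                nSplits = 50L, seed = 1L) {
  rates <- as.matrix(rates)
  stimulusOf <- factor(stimulusOf)
  set.seed(childSeed(seed, "consistency"))
  byStim <- split(seq_along(stimulusOf), stimulusOf)
  evaluable <- all(lengths(byStim) >= 2L)
  cons <- rep(NA_real_, nrow(rates))
  if (evaluable) {
    rsum <- numeric(nrow(rates))
    halfMeans <- function(cols) {
      g <- droplevels(stimulusOf[cols])
      t(rowsum(t(rates[, cols, drop = FALSE]), g) / as.vector(table(g)))
    }
    for (s in seq_len(nSplits)) {
      h1 <- unlist(lapply(byStim, function(ix)
        sample(ix, floor(length(ix) / 2))))
      h2 <- setdiff(seq_along(stimulusOf), h1)
      m1 <- halfMeans(h1)
      m2 <- halfMeans(h2)[, colnames(m1), drop = FALSE]
      r <- vapply(seq_len(nrow(rates)), function(u) {
        if (sd(m1[u, ]) == 0 || sd(m2[u, ]) == 0) 0
        else cor(m1[u, ], m2[u, ])
      }, 0)
      rsum <- rsum + r
    }
    rbar <- rsum / nSplits
    cons <- 2 * rbar / (1 + rbar)            # Spearman-Brown, split half
  }
  data.frame(neuron_id = rownames(rates) %||% seq_len(nrow(rates)),
             consistency = cons,
             keep = if (evaluable) cons > threshold else NA,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum task-wide firing-rate filter
#'
#' Keeps neurons whose mean rate over the entire task exceeds the
#' threshold (strict >, so a rate exactly at the threshold is dropped).
#'
#' @param rates numeric matrix neurons x trials of task-wide rates, or a
#'   per-neuron vector of mean rates.
#' @param minRate threshold in Hz (default 0.15).
#' @return logical keep flag per neuron.
#' @export
rateFilter <- function(rates, minRate = 0.15) {
  m <- if (is.matrix(rates)) rowMeans(rates) else as.numeric(rates)
  m > minRate
}

#' Sliding analysis bins
#'
#' Bins of width \code{binSize} advancing by \code{stepSize}, the first
#' starting at \code{firstStart}; all in ms relative to stimulus onset,
#' half-open [start, end).
#'
#' @param binSize bin width in ms (> 0).
#' @param stepSize step between bin starts in ms (> 0).
#' @param firstStart start of the first bin in ms.
#' @param nBins number of bins (>= 1).
#' @return data.frame with columns \code{start}, \code{end}, one row per
#'   bin.
#' @examples
#' humanBins()[c(1, 19), ]    # first bin [-300, 200), last [600, 1100)
#' monkeyBins()[c(1, 26), ]   # first bin [-70, -30), last [180, 220)
#' @export
slidingBins <- function(binSize, stepSize, firstStart, nBins) {
  if (binSize <= 0 || stepSize <= 0) stop("bin and step must be positive")
  if (nBins < 1) stop("at least one bin is required")
  start <- firstStart + stepSize * (seq_len(nBins) - 1)
  data.frame(start = start, end = start + binSize)
}

#' @describeIn slidingBins human preset: 500 ms bins, 50 ms steps, first
#'   bin starting -300 ms, 19 bins (last bin [600, 1100)).
#' @export
humanBins <- function() slidingBins(500, 50, -300, 19)

#' @describeIn slidingBins monkey preset: 40 ms bins, 10 ms steps, first
#'   bin starting -70 ms, 26 bins (last bin [180, 220)).
#' @export
monkeyBins <- function() slidingBins(40, 10, -70, 26)

#' @describeIn slidingBins human static response window, 250-1000 ms.
#' @export
humanWindow <- function() c(start = 250, end = 1000)

#' @describeIn slidingBins longer human window variant, 250-1250 ms.
#' @export
humanWindowLong <- function() c(start = 250, end = 1250)

#' @describeIn slidingBins monkey static response window, 70-180 ms.
#' @export
monkeyWindow <- function() c(start = 70, end = 180)
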