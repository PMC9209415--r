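# Lesion and perturbation of the fixture network: random activation
# dropout ("RandDrop" binary masks after each conv layer), targeted dropout
# of SI/MI unit sets, and weight shuffles that preserve weight multisets at
# kernel or layer granularity. No retraining is ever involved.

#' Build a random drop mask for a fixture network
#'
#' Selects, uniformly at random and without regard to selectivity class, an
#' exact fraction of units (feature-map elements for conv layers) to
#' deactivate. The realized number of zeros per masked layer is
#' \code{round(fraction * nUnits)}, i.e. within one unit of the requested
#' fraction. With \code{level = "channel"} whole feature-map channels are
#' dropped instead of individual elements.
#'
#' @param net a \linkS4class{FixtureNetwork}.
#' @param fraction fraction of units to drop, in [0, 1].
#' @param scope \code{"all_layers"} to mask every conv layer, or the name of
#'   a single layer (conv or fc) to mask only that layer.
#' @param level \code{"element"} (default; each channel x position counts as
#'   one unit) or \code{"channel"}.
#' @param seed integer seed.
#' @return A named list of logical vectors (TRUE = dropped), one entry per
#'   masked layer, with attributes \code{fraction}, \code{scope},
#'   \code{seed}; class \code{"DropMask"}.
#' @examples
#' net <- genFixtureNetwork(seed = 1)
#' m <- makeDropMask(net, 0.3, seed = 2)
#' vapply(m, sum, 1L)   # exact counts per layer
#' @export
makeDropMask <- function(net, fraction, scope = "all_layers",
                         level = c("element", "channel"), seed = 1L) {
  stopifnot(is(net, "FixtureNetwork"), fraction >= 0, fraction <= 1)
  level <- match.arg(level)
  convs <- names(net@layers)[vapply(net@layers, function(l)
    l$type == "conv", TRUE)]
  target <- if (identical(scope, "all_layers")) convs else scope
  if (!all(target %in% names(net@layers)))
    stop("unknown layer in scope: ", paste(setdiff(target, names(net@layers)),
                                           collapse = ", "))
  shapes <- layerShapes(net)
  set.seed(childSeed(seed, "dropmask"))
  mask <- lapply(target, function(nm) {
    sh <- shapes[[nm]]
    nu <- prod(sh)
    m <- rep(FALSE, nu)
    if (level == "element" || length(sh) == 1L) {
      m[sample.int(nu, round(fraction * nu))] <- TRUE
    } else {
      chDrop <- sample.int(sh[3], round(fraction * sh[3]))
      mArr <- array(FALSE, sh)
      mArr[, , chDrop] <- TRUE
      m <- as.vector(mArr)
    }
    m
  })
  names(mask) <- target
  structure(mask, fraction = fraction, scope = scope, level = level,
            seed = seed, class = "DropMask")
}

# per-layer activation shapes: c(h, w, channels) for conv/pool, units for fc
layerShapes <- function(net) {
  h <- net@inputShape[1]; w <- net@inputShape[2]
  ch <- net@inputShape[3]
  out <- vector("list", length(net@layers))
  for (i in seq_along(net@layers)) {
    l <- net@layers[[i]]
    if (l$type == "conv") {
      ch <- dim(l$weights)[4]
      out[[i]] <- c(h, w, ch)
    } else if (l$type == "pool") {
      h <- h %/% 2L; w <- w %/% 2L
      out[[i]] <- c(h, w, ch)
    } else {
      h <- 1L; w <- 1L; ch <- nrow(l$W)
      out[[i]] <- ch
    }
  }
  setNames(out, names(net@layers))
}

#' Install a drop mask on a network
#'
#' Returns a copy of the network whose forward pass zeroes the masked
#' activation elements after rectification. Unmasked elements are
#' untouched at the masked layer itself; downstream layers change only via
#' propagation.
#'
#' @param net a \linkS4class{FixtureNetwork}.
#' @param mask a \code{DropMask} from [makeDropMask()].
#' @return The masked \linkS4class{FixtureNetwork}.
#' @export
applyDrop <- function(net, mask) {
  stopifnot(is(net, "FixtureNetwork"), inherits(mask, "DropMask"))
  shapes <- layerShapes(net)
  for (nm in names(mask)) {
    if (!nm %in% names(net@layers)) stop("mask names unknown layer: ", nm)
    if (length(mask[[nm]]) != prod(shapes[[nm]]))
      stop("mask shape mismatch at ", nm)
    net@masks[[nm]] <- mask[[nm]]
  }
  net
}

#' Permanently silence a named unit set
#'
#' Zeroes the listed units of one layer in every forward pass, e.g. all SI
#' units, all MI units, or their union, taken from a
#' \linkS4class{SelectivityProfile} computed on that layer's activations.
#'
#' @param net a \linkS4class{FixtureNetwork}.
#' @param layer layer name.
#' @param units integer indices of units within the layer (flattened
#'   activation index, matching rows of [networkActivations()] output).
#' @return The lesioned \linkS4class{FixtureNetwork}. An empty unit set
#'   leaves behavior identical (with a warning).
#' @export
dropUnitSet <- function(net, layer, units) {
  stopifnot(is(net, "FixtureNetwork"))
  if (!layer %in% names(net@layers)) stop("unknown layer: ", layer)
  units <- as.integer(units)
  if (!length(units)) {
    warning("empty unit set: network unchanged")
    return(net)
  }
  nu <- prod(layerShapes(net)[[layer]])
  if (any(units < 1 | units > nu)) stop("unit indices out of range")
  net@dropUnits[[layer]] <- sort(unique(c(net@dropUnits[[layer]], units)))
  net
}

#' Units of a profile class, as indices into a layer's activation rows
#'
#' @param profile a \linkS4class{SelectivityProfile} computed on the layer's
#'   \linkS4class{ActivationSet}.
#' @param classes which classes to select, a subset of
#'   c("SI", "MI", "selective-other", "non-selective").
#' @return integer indices.
#' @export
unitsOfClass <- function(profile, classes) {
  stopifnot(is(profile, "SelectivityProfile"))
  which(profile@unitClass %in% classes)
}

#' Kernel-wise weight shuffle
#'
#' Randomly permutes the 9 weight values within each selected 3x3 kernel
#' (one kernel per input-channel x output-channel pair). The multiset of the
#' 9 weights of every kernel is preserved exactly; biases are untouched.
#'
#' @param net a \linkS4class{FixtureNetwork}.
#' @param fraction fraction of kernels shuffled in each conv layer (1 =
#'   every kernel).
#' @param seed integer seed.
#' @return The perturbed \linkS4class{FixtureNetwork}.
#' @export
kernelShuffle <- function(net, fraction = 1, seed = 1L) {
  stopifnot(is(net, "FixtureNetwork"), fraction >= 0, fraction <= 1)
  set.seed(childSeed(seed, "kernelshuffle"))
  for (i in seq_along(net@layers)) {
    l <- net@layers[[i]]
    if (l$type != "conv") next
    d <- dim(l$weights)
    if (d[1] != 3 || d[2] != 3) stop("kernel-wise shuffle requires 3x3 kernels")
    wm <- matrix(l$weights, 9, d[3] * d[4])   # one column per kernel
    pick <- sample.int(ncol(wm), round(fraction * ncol(wm)))
    for (k in pick) wm[, k] <- wm[sample.int(9), k]
    net@layers[[i]]$weights <- array(wm, d)
  }
  net
}

#' Layer-wise weight shuffle
#'
#' Pools the weights of all kernels of each selected conv layer, permutes
#' them, and reorganizes them into new kernels of the same shapes. The
#' layer-level weight multiset is preserved exactly; biases are untouched.
#'
#' @param net a \linkS4class{FixtureNetwork}.
#' @param fraction fraction of conv layers shuffled (1 = every conv layer).
#' @param seed integer seed.
#' @return The perturbed \linkS4class{FixtureNetwork}.
#' @export
layerShuffle <- function(net, fraction = 1, seed = 1L) {
  stopifnot(is(net, "FixtureNetwork"), fraction >= 0, fraction <= 1)
  set.seed(childSeed(seed, "layershuffle"))
  convIdx <- which(vapply(net@layers, function(l) l$type == "conv", TRUE))
  pick <- convIdx[sample.int(length(convIdx),
                             round(fraction * length(convIdx)))]
  for (i in pick) {
    d <- dim(net@layers[[i]]$weights)
    wv <- as.vector(net@layers[[i]]$weights)
    net@layers[[i]]$weights <- array(wv[sample.int(length(wv))], d)
  }
  net
}
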