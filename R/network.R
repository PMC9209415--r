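# A small deterministic convolutional network fixture. Structural grammar:
# 3x3 convolutions with 1-pixel stride and padding (spatial size preserved),
# ReLU after every conv and fully connected layer, 2x2 max pooling with
# stride 2 between blocks. Used as the substrate for lesion and
# weight-shuffle experiments; no training is involved anywhere.

#' FixtureNetwork: a deterministic layered convolutional network
#'
#' @slot layers list of layer descriptors. Conv layers carry \code{weights}
#'   (3 x 3 x inChannels x outChannels array) and \code{bias}; fc layers
#'   carry \code{W} (out x in) and \code{b}; pool layers have no parameters.
#' @slot inputShape integer c(height, width, channels).
#' @slot masks per-layer logical drop masks (TRUE = force activation to 0),
#'   or NULL for no mask; applied after rectification.
#' @slot dropUnits per-layer integer indices of units forced to 0 on every
#'   forward pass (flattened activation index).
#' @slot seed seed the weights were drawn with.
#' @seealso [genFixtureNetwork()], [networkActivations()], [makeDropMask()]
#' @exportClass FixtureNetwork
setClass("FixtureNetwork",
  representation(layers = "list", inputShape = "integer", masks = "list",
                 dropUnits = "list", seed = "numeric"))

setMethod("show", "FixtureNetwork", function(object) {
  desc <- vapply(object@layers, function(l) switch(l$type,
    conv = paste0("conv", dim(l$weights)[4]),
    pool = "pool",
    fc = paste0("fc", nrow(l$W))), "")
  cat("FixtureNetwork [", paste(object@inputShape, collapse = "x"), "] -> ",
      paste(desc, collapse = " -> "), "\n", sep = "")
})

#' Generate a deterministic convolutional network fixture
#'
#' Builds a small convolutional network in the 3x3 / stride-1 / pad-1 grammar
#' with interleaved 2x2 max pooling and trailing fully connected layers,
#' fully determined by the seed. With the default "structured" weight
#' style, every conv kernel is a separable product of a 1-d smoothing tap
#' and/or a 1-d derivative tap with random polarity (oriented,
#' edge-detector-like filters): the spatial arrangement of the 9 kernel
#' weights then carries meaning, so kernel- and layer-wise weight shuffles
#' destroy real structure as they would in a trained network. The
#' "gaussian" style draws i.i.d. He-scaled weights instead (kernels are
#' then statistically exchangeable under shuffling).
#'
#' @param arch list of layer specs, each one of
#'   \code{list(type = "conv", out = <channels>, kernel = 3)},
#'   \code{list(type = "pool")} or \code{list(type = "fc", out = <units>)}.
#'   A conv kernel other than 3 is rejected (the fixture mirrors the 3x3
#'   grammar).
#' @param inputShape integer c(height, width, channels) of input images.
#' @param seed integer seed for the weight draws.
#' @param weightStyle "structured" (default) or "gaussian", see above.
#' @return A \linkS4class{FixtureNetwork}.
#' @examples
#' net <- genFixtureNetwork(seed = 1)
#' net
#' @export
genFixtureNetwork <- function(arch = list(list(type = "conv", out = 8),
                                          list(type = "pool"),
                                          list(type = "conv", out = 16),
                                          list(type = "pool"),
                                          list(type = "fc", out = 32)),
                              inputShape = c(16L, 16L, 1L), seed = 1L,
                              weightStyle = c("structured", "gaussian")) {
  weightStyle <- match.arg(weightStyle)
  set.seed(childSeed(seed, "fixturenet"))
  h <- inputShape[1]; w <- inputShape[2]; ch <- inputShape[3]
  smoothTap <- c(1, 2, 1) / sqrt(6)
  derivTap <- c(-1, 0, 1) / sqrt(2)
  layers <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    a <- arch[[i]]
    if (a$type == "conv") {
      if (!is.null(a$kernel) && a$kernel != 3)
        stop("only 3x3 convolution kernels are supported by the fixture")
      gain <- 3 * sqrt(2 / (9 * ch))
      if (weightStyle == "gaussian") {
        weights <- array(rnorm(9 * ch * a$out, sd = sqrt(2 / (9 * ch))),
                         c(3, 3, ch, a$out))
      } else {
        weights <- array(0, c(3, 3, ch, a$out))
        for (ic in seq_len(ch)) for (oc in seq_len(a$out)) {
          u <- if (runif(1) < 0.5) smoothTap else derivTap
          v <- if (runif(1) < 0.5) smoothTap else derivTap
          weights[, , ic, oc] <- outer(u, v) * sample(c(-1, 1), 1) * gain
        }
      }
      layers[[i]] <- list(type = "conv", weights = weights,
                          bias = rnorm(a$out, sd = 0.5),
                          name = paste0("conv", i))
      ch <- a$out
    } else if (a$type == "pool") {
      if (h %% 2L || w %% 2L) stop("pooling requires even spatial size")
      h <- h %/% 2L; w <- w %/% 2L
      layers[[i]] <- list(type = "pool", name = paste0("pool", i))
    } else if (a$type == "fc") {
      nin <- h * w * ch
      layers[[i]] <- list(type = "fc",
                          W = matrix(rnorm(a$out * nin, sd = sqrt(2 / nin)),
                                     a$out, nin),
                          b = rnorm(a$out, sd = 0.5),
                          name = paste0("fc", i))
      h <- 1L; w <- 1L; ch <- a$out
    } else stop("unknown layer type: ", a$type)
  }
  names(layers) <- vapply(layers, `[[`, "", "name")
  new("FixtureNetwork", layers = layers,
      inputShape = as.integer(inputShape),
      masks = setNames(vector("list", length(layers)), names(layers)),
      dropUnits = setNames(vector("list", length(layers)), names(layers)),
      seed = as.numeric(seed))
}

#' @describeIn genFixtureNetwork layer names of a fixture network.
#' @param net a \linkS4class{FixtureNetwork}.
#' @export
layerNames <- function(net) names(net@layers)

# 3x3 stride-1 pad-1 convolution via a patch matrix and one matrix product.
# x: array (h, w, inC, n); returns (h, w, outC, n) pre-activation.
conv3x3 <- function(x, weights, bias) {
  d <- dim(x); h <- d[1]; w <- d[2]; inC <- d[3]; n <- d[4]
  outC <- dim(weights)[4]
  xp <- array(0, c(h + 2, w + 2, inC, n))
  xp[2:(h + 1), 2:(w + 1), , ] <- x
  P <- matrix(0, 9 * inC, h * w * n)
  for (ic in seq_len(inC))
    for (dx in 0:2)
      for (dy in 0:2) {
        r <- dy + 1L + 3L * dx + 9L * (ic - 1L)
        P[r, ] <- xp[(1 + dy):(h + dy), (1 + dx):(w + dx), ic, ]
      }
  out <- crossprod(matrix(weights, 9 * inC, outC), P) + bias
  aperm(array(out, c(outC, h, w, n)), c(2, 3, 1, 4))
}

maxpool2 <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  io <- seq(1, h, by = 2); jo <- seq(1, w, by = 2)
  pmax(x[io, jo, , , drop = FALSE], x[io + 1, jo, , , drop = FALSE],
       x[io, jo + 1, , , drop = FALSE], x[io + 1, jo + 1, , , drop = FALSE])
}

#' Forward-pass activations of a fixture network
#'
#' Runs a batch of images through the network and returns the post-ReLU
#' activations of every layer, flattened to units x images. Any drop masks
#' or targeted unit drops installed on the network (see [applyDrop()],
#' [dropUnitSet()]) are applied after rectification of the corresponding
#' layer, so masked elements are exactly zero and everything downstream
#' changes only via propagation.
#'
#' @param net a \linkS4class{FixtureNetwork}.
#' @param images array h x w x n (single channel) or h x w x c x n.
#' @return named list of numeric matrices, one per layer (units x images).
#' @examples
#' net <- genFixtureNetwork(seed = 1)
#' toy <- genToyFaces(2, 3, seed = 1)
#' acts <- networkActivations(net, toy$images)
#' vapply(acts, nrow, 1L)
#' @export
networkActivations <- function(net, images) {
  stopifnot(is(net, "FixtureNetwork"))
  d <- dim(images)
  if (length(d) == 3L) images <- array(images, c(d[1], d[2], 1L, d[3]))
  d <- dim(images)
  if (!all(d[1:3] == net@inputShape))
    stop("image shape does not match the network input shape")
  n <- d[4]
  x <- images
  out <- vector("list", length(net@layers))
  for (i in seq_along(net@layers)) {
    l <- net@layers[[i]]
    if (l$type == "conv") {
      x <- pmax(conv3x3(x, l$weights, l$bias), 0)
    } else if (l$type == "pool") {
      x <- maxpool2(x)
    } else {                                 # fc
      xm <- matrix(x, prod(dim(x)[-length(dim(x))]), n)
      x <- pmax(l$W %*% xm + l$b, 0)
    }
    # flatten per-image activation, apply drops bit-exactly
    xm <- matrix(x, ncol = n)
    keep <- rep(TRUE, nrow(xm))
    m <- net@masks[[i]]
    if (!is.null(m)) {
      if (length(m) != nrow(xm)) stop("mask shape mismatch at ", l$name)
      keep[as.logical(m)] <- FALSE
    }
    du <- net@dropUnits[[i]]
    if (length(du)) {
      if (any(du < 1 | du > nrow(xm)))
        stop("unit indices out of range at ", l$name)
      keep[du] <- FALSE
    }
    if (!all(keep)) {
      xm <- xm * keep
      x <- if (l$type == "fc") xm else array(xm, dim(x))
    }
    out[[i]] <- xm
  }
  names(out) <- names(net@layers)
  out
}

#' Activations of one layer as an ActivationSet
#'
#' @param net a \linkS4class{FixtureNetwork}.
#' @param images image batch as in [networkActivations()].
#' @param identity identity label per image.
#' @param layer layer name (see [layerNames()]); default last layer.
#' @return An \linkS4class{ActivationSet} (units x stimuli).
#' @export
layerActivationSet <- function(net, images, identity,
                               layer = tail(layerNames(net), 1)) {
  acts <- networkActivations(net, images)
  if (!layer %in% names(acts)) stop("unknown layer: ", layer)
  m <- acts[[layer]]
  rownames(m) <- sprintf("%s_u%04d", layer, seq_len(nrow(m)))
  ActivationSet(m, identity, layerId = layer)
}

#' @importFrom utils tail
NULL
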