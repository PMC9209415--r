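# Cross-validated multiclass identity decoding with an RBF-kernel SVM.
# Stimuli are partitioned into stratified folds (every identity present in
# every training fold); features are standardized per unit on the training
# folds only and the fitted scaling is applied to the held-out fold, so no
# information leaks across the split.

#' Stratified cross-validation folds
#'
#' @param labels class label per sample.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed; the same seed always yields identical folds.
#' @return integer fold assignment per sample, each class spread across
#'   folds as evenly as possible.
#' @export
stratifiedFolds <- function(labels, nFolds = 5L, seed = 1L) {
  labels <- factor(labels)
  if (any(table(labels) < nFolds))
    stop("every class needs at least as many samples as folds")
  set.seed(childSeed(seed, "folds"))
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  folds
}

#' Cross-validated identity decoding
#'
#' Five-fold (by default) cross-validated multiclass classification of
#' stimulus identity from unit responses, using an RBF-kernel SVM. Reported
#' accuracy is the fraction of correctly classified held-out stimuli per
#' fold. Chance level is 1/nClasses.
#'
#' @param features numeric matrix, stimuli x units.
#' @param labels identity label per stimulus.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed (fold partition).
#' @param cost,gamma SVM hyperparameters; defaults are the library
#'   conventions (cost 1; gamma follows the "scale" heuristic
#'   1 / (nUnits * var(trainingFeatures)), recomputed per training fold).
#' @param scaleFeatures standardize each unit on the training folds and
#'   apply to test (default TRUE).
#' @return list of class \code{"decodeResult"}: \code{foldAccuracy},
#'   \code{mean}, \code{sd}, \code{nFolds}, \code{chance}.
#' @examples
#' oneHot <- diag(5)[rep(1:5, each = 6), ]
#' crossvalDecode(oneHot, rep(letters[1:5], each = 6))$mean
#' @export
crossvalDecode <- function(features, labels, nFolds = 5L, seed = 1L,
                           cost = 1, gamma = NULL, scaleFeatures = TRUE) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nrow(features) != length(labels))
    stop("one label per stimulus (row) is required")
  folds <- stratifiedFolds(labels, nFolds, seed)
  acc <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    xtr <- features[tr, , drop = FALSE]
    xte <- features[!tr, , drop = FALSE]
    if (scaleFeatures) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2L, sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
    }
    gma <- gamma %||% {                     # "scale" heuristic per fold
      v <- mean(xtr^2) - mean(xtr)^2
      if (v <= 0) 1 / ncol(xtr) else 1 / (ncol(xtr) * v)
    }
    fit <- e1071::svm(xtr, labels[tr], kernel = "radial",
                      cost = cost, gamma = gma, scale = FALSE)
    pred <- predict(fit, xte)
    acc[f] <- mean(pred == labels[!tr])
  }
  structure(list(foldAccuracy = acc, mean = mean(acc), sd = sd(acc),
                 nFolds = nFolds, chance = 1 / nlevels(labels)),
            class = "decodeResult")
}

#' @export
print.decodeResult <- function(x, ...) {
  cat(sprintf("decodeResult: accuracy %.3f +- %.3f (%d folds, chance %.3f)\n",
              x$mean, x$sd, x$nFolds, x$chance))
  invisible(x)
}

#' Decode identity from unit groups of a selectivity profile
#'
#' Runs [crossvalDecode()] on subsets of units defined by their
#' selectivity class: all units, screen-selective, non-selective, SI, MI,
#' or SI and MI combined. With \code{equalize = TRUE} every requested group
#' is subsampled without replacement to the smallest non-empty group size
#' (repeated \code{nDraws} times, accuracies averaged), removing unit-count
#' confounds when comparing groups. Groups with zero units are skipped with
#' a warning.
#'
#' @param acts an \linkS4class{ActivationSet}.
#' @param profile the matching \linkS4class{SelectivityProfile}.
#' @param groups character subset of c("all", "selective", "non_selective",
#'   "SI", "MI", "SI_MI").
#' @param equalize equalize unit counts across groups (default FALSE).
#' @param nDraws subsample repetitions when equalizing (default 10).
#' @param nFolds,seed,... passed to [crossvalDecode()].
#' @return data.frame with one row per decoded group: \code{group},
#'   \code{n_units}, \code{accuracy}, \code{sd} (across folds, averaged
#'   over draws when equalizing).
#' @export
decodeByGroup <- function(acts, profile,
                          groups = c("all", "selective", "non_selective",
                                     "SI", "MI", "SI_MI"),
                          equalize = FALSE, nDraws = 10L, nFolds = 5L,
                          seed = 1L, ...) {
  stopifnot(is(acts, "ActivationSet"), is(profile, "SelectivityProfile"))
  known <- c("all", "selective", "non_selective", "SI", "MI", "SI_MI")
  if (!all(groups %in% known))
    stop("unknown group label: ", paste(setdiff(groups, known),
                                        collapse = ", "))
  X <- responses(acts)
  idx <- list(
    all = seq_len(nrow(X)),
    selective = which(profile@selective),
    non_selective = which(!profile@selective),
    SI = unitsOfClass(profile, "SI"),
    MI = unitsOfClass(profile, "MI"),
    SI_MI = unitsOfClass(profile, c("SI", "MI")))[groups]
  sizes <- lengths(idx)
  empty <- sizes == 0L
  if (any(empty)) {
    warning("skipping empty group(s): ",
            paste(names(idx)[empty], collapse = ", "))
    idx <- idx[!empty]
  }
  if (!length(idx)) return(data.frame())
  minSize <- min(lengths(idx))
  labels <- identities(acts)
  rows <- lapply(names(idx), function(g) {
    u <- idx[[g]]
    if (equalize && length(u) > minSize) {
      set.seed(childSeed(seed, paste0("equalize", g)))
      draws <- replicate(nDraws, sample(u, minSize), simplify = FALSE)
    } else draws <- list(u)
    res <- lapply(draws, function(d)
      crossvalDecode(t(X[d, , drop = FALSE]), labels,
                     nFolds = nFolds, seed = seed, ...))
    data.frame(group = g,
               n_units = if (equalize) minSize else length(u),
               accuracy = mean(vapply(res, `[[`, 0, "mean")),
               sd = mean(vapply(res, `[[`, 0, "sd")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
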