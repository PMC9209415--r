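# Plain-text serialization. Activation sets are written as a single TSV
# with commented metadata lines (layer, identities); spike trains as three
# CSVs (spikes, trials, neurons) sharing a file prefix. Images go to PNG
# when the png package is available.

#' Write / read an ActivationSet as TSV
#'
#' Schema: comment lines \code{# layer:} and \code{# identity:} (one label
#' per stimulus, tab-separated), then a tab-separated matrix with a
#' \code{unit_id} column and one column per stimulus.
#'
#' @param acts an \linkS4class{ActivationSet}.
#' @param path file path.
#' @return \code{writeActivations}: the path, invisibly;
#'   \code{readActivations}: the \linkS4class{ActivationSet}.
#' @export
writeActivations <- function(acts, path) {
  stopifnot(is(acts, "ActivationSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# layer: ", layerId(acts)),
               paste0("# identity: ",
                      paste(as.character(identities(acts)),
                            collapse = "\t"))), con)
  df <- data.frame(unit_id = rownames(responses(acts)),
                   responses(acts), check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname writeActivations
#' @export
readActivations <- function(path) {
  hdr <- readLines(path, n = 2L)
  layer <- sub("^# layer: ", "", hdr[1])
  identity <- strsplit(sub("^# identity: ", "", hdr[2]), "\t")[[1]]
  df <- read.delim(path, skip = 2L, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$unit_id
  ActivationSet(m, identity, layerId = layer)
}

#' Write / read a SpikeTrains object as CSVs
#'
#' Writes \code{<prefix>_spikes.csv}, \code{<prefix>_trials.csv} and
#' \code{<prefix>_neurons.csv}.
#'
#' @param st a \linkS4class{SpikeTrains}.
#' @param prefix path prefix.
#' @return \code{writeSpikeTrains}: the prefix, invisibly;
#'   \code{readSpikeTrains}: the \linkS4class{SpikeTrains}.
#' @export
writeSpikeTrains <- function(st, prefix) {
  stopifnot(is(st, "SpikeTrains"))
  utils::write.csv(st@spikes, paste0(prefix, "_spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(st@trials, paste0(prefix, "_trials.csv"),
                   row.names = FALSE)
  utils::write.csv(st@neurons, paste0(prefix, "_neurons.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeSpikeTrains
#' @export
readSpikeTrains <- function(prefix) {
  SpikeTrains(utils::read.csv(paste0(prefix, "_spikes.csv")),
              utils::read.csv(paste0(prefix, "_trials.csv")),
              utils::read.csv(paste0(prefix, "_neurons.csv")),
              dropOneBack = FALSE)
}

#' Write a grayscale image (or image stack) to PNG
#'
#' Requires the png package.
#'
#' @param img matrix in [0, 1], or h x w x n array (one file per image,
#'   suffixed \code{_001} etc.).
#' @param path output path (".png").
#' @return written path(s), invisibly.
#' @export
writeImagePNG <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  if (is.matrix(img)) {
    png::writePNG(img, path)
    return(invisible(path))
  }
  stopifnot(length(dim(img)) == 3L)
  base <- sub("\\.png$", "", path)
  paths <- sprintf("%s_%03d.png", base, seq_len(dim(img)[3]))
  for (k in seq_len(dim(img)[3])) png::writePNG(img[, , k], paths[k])
  invisible(paths)
}
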