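#' @include AllClasses.R
NULL

#' Write a channel stack as multipage TIFF with a JSON sidecar
#'
#' One 32-bit page per channel; each channel is scaled to [0, 1] by its
#' recorded maximum, which is stored (with the channel order) in a
#' \code{<path>.json} sidecar so \code{\link{readStack}} restores the
#' original intensity scale. Integer-valued rasters round-trip exactly;
#' arbitrary floats round-trip to 32-bit quantization (relative error
#' around 2e-10).
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ChannelStack"))
  ch <- stack@channels
  scales <- vapply(ch, function(m) max(m, 1e-12), numeric(1))
  pages <- lapply(seq_along(ch), function(i) ch[[i]] / scales[i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = names(ch), scales = as.numeric(scales)),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multichannel TIFF into a ChannelStack
#'
#' Pages are named from the sidecar written by \code{\link{writeStack}}
#' when present, else from \code{channelMap}. Integer inputs are promoted
#' to floating intensities without rescaling.
#'
#' @param path TIFF path.
#' @param channelMap Character vector of channel names, one per page
#'   (ignored when a sidecar provides them).
#' @return A \linkS4class{ChannelStack}.
#' @export
readStack <- function(path, channelMap = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nms <- meta$channels
    scales <- meta$scales
  } else {
    nms <- channelMap
    scales <- rep(1, length(pages))
  }
  if (is.null(nms) || length(nms) != length(pages))
    stop(sprintf(
      "channel map must name all %d page(s); got: %s", length(pages),
      if (is.null(nms)) "none" else paste(nms, collapse = ", ")))
  ch <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) > 2) m <- m[, , 1]
    m * scales[i]
  })
  names(ch) <- nms
  shapes <- lapply(ch, dim)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop("TIFF pages have mismatched shapes")
  channelStack(ch)
}

#' Write an integer label mask as 16-bit TIFF
#'
#' @param labels Integer matrix with values in [0, 65535].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLabelMask <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label mask written by \code{\link{writeLabelMask}}
#'
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) > 2) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file path.
#' @return Named list suitable for \code{\link{runPipeline}}.
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

# Canonical YAML serialization + md5 of a config, for provenance.
configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}
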