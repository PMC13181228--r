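#' @include utils.R
NULL

#' Segmentation parameters
#'
#' @param smoothingSigma Gaussian pre-smoothing sigma, pixels.
#' @param minNucleusArea Minimum nucleus object area, pixels^2.
#' @param minSeedSeparation Minimum separation between watershed seeds,
#'   pixels; nearby distance-transform maxima are merged.
#' @param membraneBandWidth Plasma-membrane band width, pixels (>= 1).
#' @param excludeBorderCells Drop cells touching the image edge? Partial
#'   cells bias per-cell means, so the default is TRUE.
#' @return A validated list of parameters.
#' @export
segmentationParams <- function(smoothingSigma = 1, minNucleusArea = 40,
                               minSeedSeparation = 7, membraneBandWidth = 3,
                               excludeBorderCells = TRUE) {
  stopifnot(smoothingSigma > 0, minNucleusArea > 0, minSeedSeparation > 0,
            membraneBandWidth >= 1)
  list(smoothingSigma = smoothingSigma, minNucleusArea = minNucleusArea,
       minSeedSeparation = minSeedSeparation,
       membraneBandWidth = membraneBandWidth,
       excludeBorderCells = isTRUE(excludeBorderCells))
}

#' Segment nuclei from the DAPI channel
#'
#' Smooth, global Otsu threshold, fill holes, split touching nuclei by a
#' distance-transform watershed (maxima closer than
#' \code{minSeedSeparation} merge into one seed), then drop objects below
#' \code{minNucleusArea}. The threshold is relative, so segmentation is
#' invariant to a global multiplicative gain.
#'
#' @param dapi Single-channel numeric matrix.
#' @param params \code{\link{segmentationParams}}.
#' @return Integer label raster with labels 1..K (0 = background). An
#'   all-zero field yields zero labels.
#' @examples
#' spec <- fieldSpec(nCells = 3L, imageHeight = 192L, imageWidth = 192L)
#' sc <- renderScene(sampleCellLayout(spec), spec, noise = FALSE)
#' nl <- segmentNuclei(getChannel(sc, "dapi"), segmentationParams())
#' max(nl)
#' @export
segmentNuclei <- function(dapi, params = segmentationParams()) {
  if (!is.matrix(dapi) || !length(dapi)) stop("dapi must be a non-empty matrix")
  if (any(!is.finite(dapi))) stop("dapi raster contains non-finite values")
  sm <- EBImage::gblur(dapi, sigma = params$smoothingSigma)
  th <- otsuThreshold(as.vector(sm))
  if (is.na(th)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  mask <- sm > th
  mask <- EBImage::fillHull(mask)
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  d <- EBImage::distmap(mask)
  labels <- EBImage::watershed(d, tolerance = 1,
                               ext = ceiling(params$minSeedSeparation))
  labels <- matrix(as.integer(labels), nrow(dapi), ncol(dapi))
  # area filter + sequential relabel
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= params$minNucleusArea)
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Segment cells by seeded watershed on the membrane channel
#'
#' Propagates one basin per nucleus seed through the smoothed membrane
#' channel (membrane intensity acts as the ridge landscape), restricted to
#' the cell foreground (filled membrane threshold union the nuclei). Cell
#' count equals nucleus count by construction.
#'
#' @param membrane Membrane-marker channel, numeric matrix.
#' @param nucleusLabels Integer nucleus label raster (seeds).
#' @param params \code{\link{segmentationParams}}.
#' @return Integer cell label raster; label k is the cell of nucleus k.
#' @examples
#' spec <- fieldSpec(nCells = 3L, imageHeight = 192L, imageWidth = 192L)
#' sc <- renderScene(sampleCellLayout(spec), spec, noise = FALSE)
#' nl <- segmentNuclei(getChannel(sc, "dapi"), segmentationParams())
#' cl <- segmentCells(getChannel(sc, "membrane"), nl, segmentationParams())
#' identical(sort(unique(cl[cl > 0])), sort(unique(nl[nl > 0])))
#' @export
segmentCells <- function(membrane, nucleusLabels,
                         params = segmentationParams()) {
  if (!any(nucleusLabels > 0))
    stop("no nuclei provided: run segmentNuclei first")
  if (!identical(dim(membrane), dim(nucleusLabels)))
    stop("membrane and nucleusLabels must share shape")
  sm <- EBImage::gblur(membrane, sigma = params$smoothingSigma)
  th <- otsuThreshold(as.vector(sm))
  fg <- if (is.na(th)) membrane > -Inf else sm > th
  fg <- EBImage::fillHull(fg) | nucleusLabels > 0
  cells <- EBImage::propagate(sm, seeds = nucleusLabels, mask = fg)
  cells <- matrix(as.integer(cells), nrow(membrane), ncol(membrane))
  clipped <- sum(nucleusLabels > 0 & cells != nucleusLabels)
  if (clipped > 0)
    warning(sprintf(
      "%d nucleus pixel(s) fall outside their cell basin and will be clipped",
      clipped))
  cells
}

#' Derive the three-compartment partition of each cell
#'
#' The plasma-membrane band is defined geometrically: pixels of each cell
#' within \code{membraneBandWidth} of that cell's boundary. Nucleus pixels
#' always win ties over the band (subtracted last), cytoplasm is the rest,
#' so the three compartments are pairwise disjoint and tile the cell
#' support exactly. Border-touching cells are dropped from all rasters when
#' \code{excludeBorderCells} is set.
#'
#' @param cellLabels,nucleusLabels Matched integer label rasters.
#' @param params \code{\link{segmentationParams}}.
#' @return A \linkS4class{CompartmentMasks}.
#' @examples
#' spec <- fieldSpec(nCells = 3L, imageHeight = 192L, imageWidth = 192L)
#' sc <- renderScene(sampleCellLayout(spec), spec, noise = FALSE)
#' cm <- deriveCompartments(cellLabels(sceneTruth(sc)),
#'                          nucleusLabels(sceneTruth(sc)))
#' cm
#' @export
deriveCompartments <- function(cellLabels, nucleusLabels,
                               params = segmentationParams()) {
  if (!identical(dim(cellLabels), dim(nucleusLabels)))
    stop("label rasters must share shape")
  cl <- matrix(as.integer(cellLabels), nrow(cellLabels), ncol(cellLabels))
  nl <- matrix(as.integer(nucleusLabels), nrow(cellLabels), ncol(cellLabels))
  cset <- sort(unique(cl[cl > 0])); nset <- sort(unique(nl[nl > 0]))
  if (!identical(cset, nset))
    stop(sprintf("cell and nucleus label sets differ (cells: %s; nuclei: %s)",
                 paste(cset, collapse = ","), paste(nset, collapse = ",")))
  clippedPx <- sum(nl > 0 & cl != nl)
  if (clippedPx > 0) {
    warning(sprintf("clipping %d nucleus pixel(s) to their cells", clippedPx))
    nl[nl > 0 & cl != nl] <- 0L
    # a nucleus fully clipped away would break the bijection
    nset2 <- sort(unique(nl[nl > 0]))
    gone <- setdiff(cset, nset2)
    if (length(gone)) {
      cl[cl %in% gone] <- 0L
      cset <- setdiff(cset, gone)
    }
  }
  if (params$excludeBorderCells) {
    H <- nrow(cl); W <- ncol(cl)
    border <- unique(c(cl[1, ], cl[H, ], cl[, 1], cl[, W]))
    border <- border[border > 0]
    if (length(border)) {
      cl[cl %in% border] <- 0L
      nl[nl %in% border] <- 0L
      cset <- setdiff(cset, border)
    }
  }
  H <- nrow(cl); W <- ncol(cl)
  pm <- matrix(FALSE, H, W)
  for (id in cset) {
    bb <- maskBBox(cl == id, pad = 1L)
    m <- cl[bb$rows, bb$cols] == id
    d <- EBImage::distmap(m)
    loc <- m & d <= params$membraneBandWidth & nl[bb$rows, bb$cols] != id
    pm[bb$rows, bb$cols] <- pm[bb$rows, bb$cols] | loc
  }
  cyto <- cl > 0 & nl == 0 & !pm
  new("CompartmentMasks", cellLabels = cl, nucleusLabels = nl,
      pmMask = pm, cytoplasmMask = cyto)
}

#' Full segmentation of one field
#'
#' Convenience wrapper: nuclei from DAPI, cells by seeded watershed on the
#' membrane channel, then the three-compartment partition.
#'
#' @param stack A \linkS4class{ChannelStack} (or \linkS4class{SyntheticScene})
#'   with \code{dapi} and \code{membrane} channels.
#' @param params \code{\link{segmentationParams}}.
#' @return A \linkS4class{CompartmentMasks}.
#' @export
segmentField <- function(stack, params = segmentationParams()) {
  nl <- segmentNuclei(getChannel(stack, "dapi"), params)
  if (!any(nl > 0))
    stop("no nuclei found in the DAPI channel")
  cl <- suppressWarnings(
    segmentCells(getChannel(stack, "membrane"), nl, params))
  suppressWarnings(deriveCompartments(cl, nl, params))
}
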