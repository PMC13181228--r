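#' @include AllGenerics.R
NULL

.SUBCOMPARTMENT_KINDS <- c("DFC", "NS", "heterochromatin")
.CONDITIONS <- c("plusUV", "minusUV", "untreated")
.LANE_ROLES <- c("ladder", "no_click", "untreated", "vehicle", "minusUV", "plusUV")

# ---------------------------------------------------------------------------
# FieldSpec
# ---------------------------------------------------------------------------

#' Synthetic microscopy field specification
#'
#' Parameter object describing one synthetic multichannel field: image size,
#' number of non-overlapping cells, cell/nucleus geometry, subnuclear
#' compartments with configurable probe-enrichment folds, per-compartment
#' base intensities, background and the Poisson+Gaussian camera noise model.
#'
#' @slot imageHeight,imageWidth Image size in pixels.
#' @slot nCells Number of cells to place (non-overlapping).
#' @slot cellRadiusRange,nucleusRadiusRange Min/max semi-axis in pixels.
#' @slot membraneBandWidth Width of the plasma-membrane band, pixels.
#' @slot minSpacing Extra margin between cell bounding circles, pixels.
#' @slot subcompartments data.frame with columns \code{kind},
#'   \code{fociPerNucleus}, \code{focusRadiusMin}, \code{focusRadiusMax}.
#' @slot rimWidth Width of the heterochromatin nuclear-rim band, pixels.
#' @slot baseLevels Named intensities (AU): \code{pm}, \code{cytoplasm},
#'   \code{nucleoplasm}.
#' @slot enrichmentFolds Named dimensionless folds per subcompartment kind.
#' @slot stainLevels Named marker-channel intensities (AU).
#' @slot backgroundLevel Additive background, AU.
#' @slot poissonScale Photons per AU for shot noise; \code{Inf} disables.
#' @slot gaussianSd Additive read-noise SD, AU.
#' @slot seed Integer seed; all generation is deterministic given the spec.
#' @seealso \code{\link{fieldSpec}}, \code{\link{sampleCellLayout}},
#'   \code{\link{renderScene}}
#' @export
setClass("FieldSpec", representation(
  imageHeight = "integer", imageWidth = "integer", nCells = "integer",
  cellRadiusRange = "numeric", nucleusRadiusRange = "numeric",
  membraneBandWidth = "numeric", minSpacing = "numeric",
  subcompartments = "data.frame", rimWidth = "numeric",
  baseLevels = "numeric", enrichmentFolds = "numeric",
  stainLevels = "numeric", backgroundLevel = "numeric",
  poissonScale = "numeric", gaussianSd = "numeric", seed = "integer"))

setValidity("FieldSpec", function(object) {
  msg <- character()
  if (object@imageHeight < 16L || object@imageWidth < 16L)
    msg <- c(msg, "image must be at least 16x16 pixels")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (diff(object@cellRadiusRange) < 0 || object@cellRadiusRange[1] <= 0)
    msg <- c(msg, "cellRadiusRange must be positive and ordered")
  if (diff(object@nucleusRadiusRange) < 0 || object@nucleusRadiusRange[1] <= 0)
    msg <- c(msg, "nucleusRadiusRange must be positive and ordered")
  if (object@nucleusRadiusRange[2] >= object@cellRadiusRange[1])
    msg <- c(msg, "nucleus radii must be smaller than cell radii")
  if (object@membraneBandWidth < 1)
    msg <- c(msg, "membraneBandWidth must be >= 1")
  if (any(object@enrichmentFolds < 0))
    msg <- c(msg, "enrichment folds must be >= 0")
  if (!all(c("pm", "cytoplasm", "nucleoplasm") %in% names(object@baseLevels)))
    msg <- c(msg, "baseLevels must name pm, cytoplasm, nucleoplasm")
  if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
  if (object@poissonScale <= 0 || object@gaussianSd < 0)
    msg <- c(msg, "noise parameters must be non-negative (poissonScale > 0)")
  if (nrow(object@subcompartments) &&
      !all(object@subcompartments$kind %in% .SUBCOMPARTMENT_KINDS))
    msg <- c(msg, sprintf("subcompartment kinds must be in {%s}",
                          paste(.SUBCOMPARTMENT_KINDS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a FieldSpec
#'
#' Defaults describe the study conditions the package's validation suite
#' assumes: fields of well-separated elliptical cells whose probe intensity
#' is highest in the nucleoplasm, lower in the cytoplasm and lowest in the
#' plasma-membrane band, with disk-like nucleolar (DFC) foci enriched by a
#' configurable fold, and shot+read noise at roughly 20:1 SNR at the
#' nucleoplasm level.
#'
#' @param imageHeight,imageWidth Image size, pixels.
#' @param nCells Number of cells.
#' @param cellRadiusRange,nucleusRadiusRange Semi-axis ranges, pixels.
#' @param membraneBandWidth Plasma-membrane band width, pixels (>= 1).
#' @param minSpacing Extra spacing enforced between cell bounding circles.
#' @param subcompartments data.frame(kind, fociPerNucleus, focusRadiusMin,
#'   focusRadiusMax); at most one kind is rendered into the marker channel.
#' @param rimWidth Heterochromatin rim width, pixels.
#' @param baseLevels Named AU levels for pm/cytoplasm/nucleoplasm.
#' @param enrichmentFolds Named folds, e.g. \code{c(DFC = 1.4)}.
#' @param stainLevels Named AU levels for the stain channels.
#' @param backgroundLevel Additive background AU (default 0).
#' @param poissonScale Photons per AU (shot noise); \code{Inf} disables.
#' @param gaussianSd Read-noise SD, AU.
#' @param seed Integer seed.
#' @return A validated \linkS4class{FieldSpec}.
#' @examples
#' spec <- fieldSpec(nCells = 4L, seed = 7L)
#' spec
#' @export
fieldSpec <- function(imageHeight = 512L, imageWidth = 512L, nCells = 9L,
                      cellRadiusRange = c(20, 30),
                      nucleusRadiusRange = c(9, 14),
                      membraneBandWidth = 3, minSpacing = 4,
                      subcompartments = data.frame(
                        kind = "DFC", fociPerNucleus = 4L,
                        focusRadiusMin = 2.5, focusRadiusMax = 4),
                      rimWidth = 2.5,
                      baseLevels = c(pm = 40, cytoplasm = 60, nucleoplasm = 100),
                      enrichmentFolds = c(DFC = 1.4),
                      stainLevels = c(dapi = 500, membrane = 150,
                                      cellInterior = 15, marker = 200,
                                      markerNucleoplasm = 50),
                      backgroundLevel = 0,
                      poissonScale = 4, gaussianSd = 2, seed = 1L) {
  new("FieldSpec",
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      nCells = as.integer(nCells), cellRadiusRange = as.numeric(cellRadiusRange),
      nucleusRadiusRange = as.numeric(nucleusRadiusRange),
      membraneBandWidth = as.numeric(membraneBandWidth),
      minSpacing = as.numeric(minSpacing),
      subcompartments = subcompartments, rimWidth = as.numeric(rimWidth),
      baseLevels = baseLevels, enrichmentFolds = enrichmentFolds,
      stainLevels = stainLevels, backgroundLevel = as.numeric(backgroundLevel),
      poissonScale = as.numeric(poissonScale), gaussianSd = as.numeric(gaussianSd),
      seed = as.integer(seed))
}

setMethod("show", "FieldSpec", function(object) {
  cat(sprintf("FieldSpec: %dx%d px, %d cells, folds [%s], seed %d\n",
              object@imageHeight, object@imageWidth, object@nCells,
              paste(sprintf("%s=%.3g", names(object@enrichmentFolds),
                            object@enrichmentFolds), collapse = ", "),
              object@seed))
})

# ---------------------------------------------------------------------------
# ChannelStack
# ---------------------------------------------------------------------------

#' Named co-registered fluorescence channels
#'
#' A set of equally shaped 2-D intensity rasters, one per fluorescence
#' channel (e.g. DAPI, membrane marker, subcompartment marker, probe).
#'
#' @slot channels Named list of numeric matrices, all the same shape,
#'   finite and non-negative.
#' @seealso \code{\link{channelStack}}, \code{\link{readStack}}
#' @export
setClass("ChannelStack", representation(channels = "list"))

setValidity("ChannelStack", function(object) {
  ch <- object@channels
  if (!length(ch)) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  dims <- lapply(ch, dim)
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("each channel must be a 2-D matrix")
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all channels must share the same shape")
  bad <- vapply(ch, function(m) any(!is.finite(m)) || any(m < 0), logical(1))
  if (any(bad))
    return(sprintf("channel(s) %s contain non-finite or negative intensities",
                   paste(names(ch)[bad], collapse = ", ")))
  TRUE
})

#' Construct a ChannelStack
#' @param ... Named numeric matrices, or a single named list of them.
#' @return A validated \linkS4class{ChannelStack}.
#' @examples
#' cs <- channelStack(dapi = matrix(0, 8, 8), probe = matrix(1, 8, 8))
#' channelNames(cs)
#' @export
channelStack <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !is.matrix(ch[[1]]))
    ch <- ch[[1]]
  new("ChannelStack", channels = ch)
}

#' @rdname channelNames
setMethod("channelNames", "ChannelStack", function(x) names(x@channels))

#' @rdname getChannel
setMethod("getChannel", "ChannelStack", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("channel '%s' not found; available: %s", name,
                 paste(names(x@channels), collapse = ", ")))
  x@channels[[name]]
})

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ChannelStack: %d channel(s) [%s], %dx%d px\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "), d[1], d[2]))
})

# ---------------------------------------------------------------------------
# GroundTruth / SyntheticScene
# ---------------------------------------------------------------------------

#' Generator-side ground truth for a synthetic scene
#'
#' @slot cellLabels,nucleusLabels Integer label rasters; nucleus k belongs
#'   to cell k and lies inside it.
#' @slot pmMask Logical plasma-membrane band mask.
#' @slot subcompartmentMasks Named list (by kind) of logical masks, each a
#'   subset of the nucleus support.
#' @slot trueFolds Named configured enrichment folds.
#' @slot trueCompartmentMeans Named noise-free mean intensities per
#'   compartment (AU), background included.
#' @export
setClass("GroundTruth", representation(
  cellLabels = "matrix", nucleusLabels = "matrix", pmMask = "matrix",
  subcompartmentMasks = "list", trueFolds = "numeric",
  trueCompartmentMeans = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@cellLabels), dim(object@nucleusLabels)))
    msg <- c(msg, "label rasters must share shape")
  if (any(object@nucleusLabels > 0 & object@cellLabels != object@nucleusLabels))
    msg <- c(msg, "each nucleus pixel must lie in its own cell")
  cl <- sort(unique(object@cellLabels[object@cellLabels > 0]))
  nl <- sort(unique(object@nucleusLabels[object@nucleusLabels > 0]))
  if (!identical(cl, nl))
    msg <- c(msg, "cell and nucleus label sets must be identical")
  for (kind in names(object@subcompartmentMasks)) {
    m <- object@subcompartmentMasks[[kind]]
    if (any(m & object@nucleusLabels == 0))
      msg <- c(msg, sprintf("%s mask leaks outside nuclei", kind))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname cellLabels
setMethod("cellLabels", "GroundTruth", function(x) x@cellLabels)
#' @rdname nucleusLabels
setMethod("nucleusLabels", "GroundTruth", function(x) x@nucleusLabels)
#' @rdname pmMask
setMethod("pmMask", "GroundTruth", function(x) x@pmMask)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cell(s), subcompartments [%s]\n",
              length(unique(object@cellLabels[object@cellLabels > 0])),
              paste(names(object@subcompartmentMasks), collapse = ", ")))
})

#' One synthetic multichannel field with attached ground truth
#'
#' @slot channels \linkS4class{ChannelStack} with channels \code{dapi},
#'   \code{membrane}, \code{marker}, \code{probe}.
#' @slot truth \linkS4class{GroundTruth}.
#' @slot timeMin Labeling time, minutes (NA when not a time-course scene).
#' @slot condition \code{"plusUV"}, \code{"minusUV"} or \code{"untreated"}.
#' @export
setClass("SyntheticScene", representation(
  channels = "ChannelStack", truth = "GroundTruth",
  timeMin = "numeric", condition = "character"))

setValidity("SyntheticScene", function(object) {
  if (!object@condition %in% .CONDITIONS)
    return(sprintf("condition must be one of %s",
                   paste(.CONDITIONS, collapse = ", ")))
  if (!identical(dim(object@channels@channels[[1]]),
                 dim(object@truth@cellLabels)))
    return("channel and truth rasters must share shape")
  TRUE
})

#' @rdname channelNames
setMethod("channelNames", "SyntheticScene",
          function(x) channelNames(x@channels))
#' @rdname getChannel
setMethod("getChannel", "SyntheticScene",
          function(x, name) getChannel(x@channels, name))
#' @rdname sceneTruth
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)
#' @rdname sceneCondition
setMethod("sceneCondition", "SyntheticScene", function(x) x@condition)

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %s, t=%s min, ", object@condition,
              format(object@timeMin)))
  show(object@channels)
})

# ---------------------------------------------------------------------------
# CompartmentMasks
# ---------------------------------------------------------------------------

#' Three-compartment partition of segmented cells
#'
#' For every retained cell the plasma-membrane band, cytoplasm and nucleus
#' are pairwise disjoint and tile the cell support exactly; validity
#' enforces this pixelwise, together with the cell/nucleus label bijection.
#'
#' @slot cellLabels,nucleusLabels Integer label rasters (matched label sets).
#' @slot pmMask,cytoplasmMask Logical masks.
#' @seealso \code{\link{deriveCompartments}}
#' @export
setClass("CompartmentMasks", representation(
  cellLabels = "matrix", nucleusLabels = "matrix",
  pmMask = "matrix", cytoplasmMask = "matrix"))

setValidity("CompartmentMasks", function(object) {
  cl <- object@cellLabels; nl <- object@nucleusLabels
  pm <- object@pmMask; cy <- object@cytoplasmMask
  if (!identical(dim(cl), dim(nl)) || !identical(dim(cl), dim(pm)) ||
      !identical(dim(cl), dim(cy)))
    return("all rasters must share shape")
  if (!identical(sort(unique(cl[cl > 0])), sort(unique(nl[nl > 0]))))
    return("cell and nucleus label sets must be identical")
  if (any(nl > 0 & cl != nl))
    return("each nucleus must lie inside its own cell")
  if (any((pm | cy) & cl == 0))
    return("pm/cytoplasm masks must lie inside cells")
  if (any(pm & cy) || any(pm & nl > 0) || any(cy & nl > 0))
    return("compartments must be pairwise disjoint")
  if (any(cl > 0 & !(pm | cy | nl > 0)))
    return("compartments must tile each cell exactly")
  TRUE
})

#' @rdname cellLabels
setMethod("cellLabels", "CompartmentMasks", function(x) x@cellLabels)
#' @rdname nucleusLabels
setMethod("nucleusLabels", "CompartmentMasks", function(x) x@nucleusLabels)
#' @rdname pmMask
setMethod("pmMask", "CompartmentMasks", function(x) x@pmMask)
#' @rdname cytoplasmMask
setMethod("cytoplasmMask", "CompartmentMasks", function(x) x@cytoplasmMask)

setMethod("show", "CompartmentMasks", function(object) {
  cat(sprintf("CompartmentMasks: %d cell(s), %dx%d px\n",
              length(unique(object@cellLabels[object@cellLabels > 0])),
              nrow(object@cellLabels), ncol(object@cellLabels)))
})

# ---------------------------------------------------------------------------
# SubcompartmentMasks
# ---------------------------------------------------------------------------

#' Per-nucleus subnuclear compartment / remainder partition
#'
#' For every analyzed nucleus the marker-defined compartment (e.g. DFC foci)
#' and the remaining nucleoplasm are disjoint and together tile the nucleus
#' support exactly. Nuclei with degenerate marker signal or too-small
#' compartments are excluded and recorded.
#'
#' @slot kind \code{"DFC"}, \code{"NS"} or \code{"heterochromatin"}.
#' @slot compartmentLabels,remainderLabels Integer rasters labeled by
#'   nucleus id.
#' @slot nucleusLabels The nucleus label raster the partition refers to.
#' @slot excluded Integer ids of nuclei excluded from analysis.
#' @seealso \code{\link{segmentSubcompartment}}, \code{\link{computeEnrichment}}
#' @export
setClass("SubcompartmentMasks", representation(
  kind = "character", compartmentLabels = "matrix",
  remainderLabels = "matrix", nucleusLabels = "matrix",
  excluded = "integer"))

setValidity("SubcompartmentMasks", function(object) {
  if (!object@kind %in% .SUBCOMPARTMENT_KINDS)
    return("unknown subcompartment kind")
  cm <- object@compartmentLabels; rm_ <- object@remainderLabels
  nl <- object@nucleusLabels
  if (!identical(dim(cm), dim(rm_)) || !identical(dim(cm), dim(nl)))
    return("rasters must share shape")
  if (any(cm > 0 & rm_ > 0))
    return("compartment and remainder must be disjoint")
  ids <- setdiff(sort(unique(cm[cm > 0])), object@excluded)
  for (k in ids) {
    nuc <- nl == k
    if (any((cm == k | rm_ == k) != nuc))
      return(sprintf("nucleus %d: compartment+remainder must tile the nucleus", k))
  }
  TRUE
})

setMethod("show", "SubcompartmentMasks", function(object) {
  ids <- unique(object@compartmentLabels[object@compartmentLabels > 0])
  cat(sprintf("SubcompartmentMasks (%s): %d analyzed, %d excluded nuclei\n",
              object@kind, length(ids), length(object@excluded)))
})

# ---------------------------------------------------------------------------
# BackgroundModel / UTestResult / GelSpec
# ---------------------------------------------------------------------------

#' Scalar background model estimated from untreated fields
#'
#' @slot background Non-negative scalar background (AU) for the probe channel.
#' @slot sourceFields Ids of the untreated fields the estimate pooled.
#' @seealso \code{\link{estimateBackground}}, \code{\link{subtractBackground}}
#' @export
setClass("BackgroundModel", representation(
  background = "numeric", sourceFields = "character"))

setValidity("BackgroundModel", function(object) {
  if (length(object@background) != 1L || object@background < 0)
    return("background must be a single non-negative scalar")
  TRUE
})

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel: %.4g AU from %d untreated field(s)\n",
              object@background, length(object@sourceFields)))
})

#' Mann-Whitney U test result
#'
#' @slot U The U statistic for the first sample (0 <= U <= n1*n2).
#' @slot pValue P-value under the selected alternative.
#' @slot method \code{"exact"} (null enumeration) or \code{"normal_approx"}
#'   (tie-corrected, continuity-corrected).
#' @slot alternative \code{"two_sided"}, \code{"greater"} or \code{"less"}.
#' @slot n1,n2 Sample sizes.
#' @seealso \code{\link{mannWhitneyU}}
#' @export
setClass("UTestResult", representation(
  U = "numeric", pValue = "numeric", method = "character",
  alternative = "character", n1 = "integer", n2 = "integer"))

setValidity("UTestResult", function(object) {
  msg <- character()
  if (object@U < 0 || object@U > object@n1 * object@n2)
    msg <- c(msg, "U must lie in [0, n1*n2]")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (!object@method %in% c("exact", "normal_approx"))
    msg <- c(msg, "method must be exact or normal_approx")
  if (length(msg)) msg else TRUE
})

setMethod("show", "UTestResult", function(object) {
  cat(sprintf("Mann-Whitney U test (%s, %s): U = %g, p = %.4g (n1=%d, n2=%d)\n",
              object@method, object@alternative, object@U, object@pValue,
              object@n1, object@n2))
})

#' Synthetic SDS-PAGE gel specification
#'
#' Describes a multi-lane fluorescence gel: lane roles (ladder and negative
#' controls are quantified but excluded from ratio truth), per-lane true
#' integrated signals above baseline, band layout along the migration axis,
#' baseline level and additive noise.
#'
#' @slot laneRoles Character vector of roles, one per lane, from
#'   \{ladder, no_click, untreated, vehicle, minusUV, plusUV\}.
#' @slot trueSignals Non-negative true integrated signal per lane (AU).
#' @slot laneWidth,laneGap Lane geometry, pixels.
#' @slot profileLength Migration-axis length, pixels.
#' @slot bandLayout data.frame(position, width, mass): band centers as a
#'   fraction of the migration axis, Gaussian widths in pixels, relative mass.
#' @slot baselineLevel Additive baseline, AU.
#' @slot noiseSd Additive Gaussian noise SD, AU.
#' @slot seed Integer seed.
#' @seealso \code{\link{gelSpec}}, \code{\link{generateGel}}
#' @export
setClass("GelSpec", representation(
  laneRoles = "character", trueSignals = "numeric",
  laneWidth = "integer", laneGap = "integer", profileLength = "integer",
  bandLayout = "data.frame", baselineLevel = "numeric",
  noiseSd = "numeric", seed = "integer"))

setValidity("GelSpec", function(object) {
  msg <- character()
  if (length(object@laneRoles) < 1L) msg <- c(msg, "at least one lane required")
  if (!all(object@laneRoles %in% .LANE_ROLES))
    msg <- c(msg, sprintf("lane roles must be in {%s}",
                          paste(.LANE_ROLES, collapse = ", ")))
  if (length(object@trueSignals) != length(object@laneRoles))
    msg <- c(msg, "one true signal per lane required")
  if (any(object@trueSignals < 0)) msg <- c(msg, "true signals must be >= 0")
  if (object@laneWidth < 3L) msg <- c(msg, "laneWidth must be >= 3 px")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(object@bandLayout$position <= 0.05) ||
      any(object@bandLayout$position >= 0.95))
    msg <- c(msg, "band positions must avoid the 5% baseline windows")
  if (length(msg)) msg else TRUE
})

#' Construct a GelSpec
#'
#' @param laneRoles Roles per lane; default mirrors an 8-lane layout with
#'   ladder, negative controls and paired -UV/+UV sample lanes.
#' @param trueSignals True integrated signal per lane (AU above baseline).
#' @param laneWidth,laneGap,profileLength Gel geometry, pixels.
#' @param bandLayout Band centers (fraction of migration axis), Gaussian
#'   widths (px) and relative masses.
#' @param baselineLevel,noiseSd Baseline and additive noise, AU.
#' @param seed Integer seed.
#' @return A validated \linkS4class{GelSpec}.
#' @examples
#' gs <- gelSpec(seed = 3L)
#' gel <- generateGel(gs)
#' dim(gel$raster)
#' @export
gelSpec <- function(laneRoles = c("ladder", "no_click", "untreated", "vehicle",
                                  "minusUV", "plusUV", "minusUV", "plusUV"),
                    trueSignals = c(3000, 40, 40, 40, 4900, 10000, 4900, 10000),
                    laneWidth = 14L, laneGap = 6L, profileLength = 200L,
                    bandLayout = data.frame(position = c(0.25, 0.45, 0.7),
                                            width = c(3, 4, 5),
                                            mass = c(0.3, 0.45, 0.25)),
                    baselineLevel = 50, noiseSd = 0, seed = 1L) {
  new("GelSpec", laneRoles = laneRoles, trueSignals = as.numeric(trueSignals),
      laneWidth = as.integer(laneWidth), laneGap = as.integer(laneGap),
      profileLength = as.integer(profileLength), bandLayout = bandLayout,
      baselineLevel = as.numeric(baselineLevel), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

setMethod("show", "GelSpec", function(object) {
  cat(sprintf("GelSpec: %d lane(s) [%s], %d px profile\n",
              length(object@laneRoles),
              paste(object@laneRoles, collapse = ", "), object@profileLength))
})

# ---------------------------------------------------------------------------
# ResultBundle
# ---------------------------------------------------------------------------

#' End-to-end pipeline result bundle
#'
#' Everything \code{\link{runPipeline}} produces: per-cell intensity records,
#' condition summaries, per-nucleus enrichment records and summaries, gel
#' lane quantification with the -UV/+UV incorporation result, the derived
#' compartment masks of the first analyzed field, and a provenance block
#' (config hash, package version, seed) from which every table is
#' regenerable.
#'
#' @slot records,summaries,enrichment,enrichmentSummary data.frames.
#' @slot gel List with lane table and incorporation result (or empty).
#' @slot masks \linkS4class{CompartmentMasks} of the first treated field.
#' @slot provenance List: configHash, packageVersion, seed.
#' @export
setClass("ResultBundle", representation(
  records = "data.frame", summaries = "data.frame",
  enrichment = "data.frame", enrichmentSummary = "data.frame",
  gel = "list", masks = "CompartmentMasks", provenance = "list"))

setMethod("show", "ResultBundle", function(object) {
  cat(sprintf(paste0("ResultBundle: %d intensity record(s), %d summary row(s), ",
                     "%d enrichment record(s)\n  seed %s, config %s\n"),
              nrow(object@records), nrow(object@summaries),
              nrow(object@enrichment),
              format(object@provenance$seed),
              substr(format(object@provenance$configHash), 1, 8)))
})
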