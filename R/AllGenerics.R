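#' @import methods
NULL

#' Channel names of a stack or scene
#'
#' @param x A \linkS4class{ChannelStack} or \linkS4class{SyntheticScene}.
#' @return Character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel raster
#'
#' @param x A \linkS4class{ChannelStack} or \linkS4class{SyntheticScene}.
#' @param name Channel name, e.g. \code{"dapi"}, \code{"membrane"},
#'   \code{"marker"}, \code{"probe"}.
#' @return Numeric matrix of intensities (arbitrary units).
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' Cell label raster
#' @param x A \linkS4class{CompartmentMasks} or \linkS4class{GroundTruth}.
#' @return Integer matrix; 0 is background, label k is cell k.
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' Nucleus label raster
#' @param x A \linkS4class{CompartmentMasks} or \linkS4class{GroundTruth}.
#' @return Integer matrix; label k is the nucleus of cell k.
#' @export
setGeneric("nucleusLabels", function(x) standardGeneric("nucleusLabels"))

#' Plasma-membrane band mask
#' @param x A \linkS4class{CompartmentMasks} or \linkS4class{GroundTruth}.
#' @return Logical matrix.
#' @export
setGeneric("pmMask", function(x) standardGeneric("pmMask"))

#' Cytoplasm mask
#' @param x A \linkS4class{CompartmentMasks}.
#' @return Logical matrix.
#' @export
setGeneric("cytoplasmMask", function(x) standardGeneric("cytoplasmMask"))

#' Generator ground truth attached to a scene
#' @param x A \linkS4class{SyntheticScene}.
#' @return A \linkS4class{GroundTruth}.
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' Experimental condition of a scene
#' @param x A \linkS4class{SyntheticScene}.
#' @return One of \code{"plusUV"}, \code{"minusUV"}, \code{"untreated"}.
#' @export
setGeneric("sceneCondition", function(x) standardGeneric("sceneCondition"))
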