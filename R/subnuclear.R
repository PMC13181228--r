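#' @include quantification.R mannwhitney.R
NULL

#' Subcompartment segmentation parameters
#'
#' @param minCompartmentArea Minimum total compartment area per nucleus,
#'   pixels^2; nuclei below it are excluded (and counted).
#' @param minFocusArea Minimum area of an individual marker object,
#'   pixels^2; smaller objects are removed as noise.
#' @return Validated parameter list.
#' @export
subcompartmentParams <- function(minCompartmentArea = 6, minFocusArea = 3) {
  stopifnot(minCompartmentArea > 0, minFocusArea > 0)
  list(minCompartmentArea = minCompartmentArea, minFocusArea = minFocusArea)
}

#' Segment a subnuclear compartment per nucleus
#'
#' For every nucleus, an Otsu threshold restricted to that nucleus's marker
#' pixels defines the compartment; objects below \code{minFocusArea} are
#' removed; the remainder is the nucleus minus the compartment. Nuclei with
#' degenerate marker signal (uniform) or compartment area below
#' \code{minCompartmentArea}, or with an empty remainder, are excluded and
#' recorded in the result.
#'
#' @param marker Marker-channel raster (numeric matrix).
#' @param nucleusLabels Integer nucleus label raster.
#' @param kind \code{"DFC"}, \code{"NS"} or \code{"heterochromatin"}.
#' @param params \code{\link{subcompartmentParams}}.
#' @return A \linkS4class{SubcompartmentMasks}.
#' @examples
#' spec <- fieldSpec(nCells = 3L, imageHeight = 192L, imageWidth = 192L)
#' sc <- renderScene(sampleCellLayout(spec), spec)
#' sm <- segmentSubcompartment(getChannel(sc, "marker"),
#'                             nucleusLabels(sceneTruth(sc)), "DFC")
#' sm
#' @export
segmentSubcompartment <- function(marker, nucleusLabels,
                                  kind = c("DFC", "NS", "heterochromatin"),
                                  params = subcompartmentParams()) {
  kind <- match.arg(kind)
  if (is.null(marker)) stop("marker channel missing")
  if (!identical(dim(marker), dim(nucleusLabels)))
    stop("marker and nucleusLabels must share shape")
  ids <- sort(unique(nucleusLabels[nucleusLabels > 0]))
  if (!length(ids)) stop("nucleus labels are empty")
  H <- nrow(marker); W <- ncol(marker)
  compL <- matrix(0L, H, W)
  remL <- matrix(0L, H, W)
  excluded <- integer(0)
  for (k in ids) {
    bb <- maskBBox(nucleusLabels == k, pad = 1L)
    nm <- nucleusLabels[bb$rows, bb$cols] == k
    mv <- marker[bb$rows, bb$cols]
    th <- otsuThreshold(mv[nm])
    if (is.na(th)) { excluded <- c(excluded, k); next }
    comp <- nm & mv > th
    # remove sub-threshold-size objects (noise speckles)
    if (any(comp)) {
      lab <- EBImage::bwlabel(comp)
      areas <- tabulate(lab[lab > 0])
      drop <- which(areas < params$minFocusArea)
      if (length(drop)) comp[lab %in% drop] <- FALSE
    }
    if (sum(comp) < params$minCompartmentArea || !any(nm & !comp)) {
      excluded <- c(excluded, k); next
    }
    sub <- compL[bb$rows, bb$cols]; sub[comp] <- k
    compL[bb$rows, bb$cols] <- sub
    sub <- remL[bb$rows, bb$cols]; sub[nm & !comp] <- k
    remL[bb$rows, bb$cols] <- sub
  }
  new("SubcompartmentMasks", kind = kind, compartmentLabels = compL,
      remainderLabels = remL, nucleusLabels = nucleusLabels,
      excluded = excluded)
}

#' Per-nucleus subcompartment enrichment folds
#'
#' fold = mean(probe | compartment) / mean(probe | remainder), computed per
#' nucleus on background-corrected intensities. Multiplying the probe by a
#' positive gain leaves folds unchanged; an additive offset does too,
#' provided the background model absorbs it. Nuclei whose corrected
#' remainder mean is non-positive are dropped with a diagnostic.
#'
#' @param probe Probe raster.
#' @param masks A \linkS4class{SubcompartmentMasks}.
#' @param background Scalar background or \linkS4class{BackgroundModel}.
#' @param probeId,uvCondition Metadata attached to each record.
#' @return data.frame: nucleus_id, kind, enrichment_fold, compartment_area,
#'   remainder_area, probe_id, uv_condition.
#' @export
computeEnrichment <- function(probe, masks, background = 0,
                              probeId = NA_character_,
                              uvCondition = NA_character_) {
  stopifnot(is(masks, "SubcompartmentMasks"))
  if (!identical(dim(probe), dim(masks@compartmentLabels)))
    stop("probe raster shape must match masks")
  bg <- if (is(background, "BackgroundModel")) background@background
        else as.numeric(background)
  cm <- .labelMeans(probe, masks@compartmentLabels) - bg
  rm_ <- .labelMeans(probe, masks@remainderLabels) - bg
  ids <- intersect(names(cm), names(rm_))
  keep <- ids[rm_[ids] > 0]
  droppedN <- setdiff(ids, keep)
  if (length(droppedN))
    message(sprintf(
      "dropping %d nucleus/nuclei with non-positive corrected remainder mean",
      length(droppedN)))
  if (!length(keep))
    return(data.frame(nucleus_id = integer(0), kind = character(0),
                      enrichment_fold = numeric(0),
                      compartment_area = numeric(0),
                      remainder_area = numeric(0),
                      probe_id = character(0), uv_condition = character(0),
                      stringsAsFactors = FALSE))
  ca <- tabulate(masks@compartmentLabels[masks@compartmentLabels > 0])
  ra <- tabulate(masks@remainderLabels[masks@remainderLabels > 0])
  data.frame(nucleus_id = as.integer(keep), kind = masks@kind,
             enrichment_fold = as.numeric(cm[keep] / rm_[keep]),
             compartment_area = ca[as.integer(keep)],
             remainder_area = ra[as.integer(keep)],
             probe_id = probeId, uv_condition = uvCondition,
             stringsAsFactors = FALSE)
}

#' Summarize enrichment folds across nuclei
#'
#' Mean fold and its standard error (SD / sqrt(n)) per kind, probe and UV
#' condition; n is the number of analyzed nuclei.
#'
#' @param records data.frame from \code{\link{computeEnrichment}}.
#' @return data.frame: kind, probe_id, uv_condition, n_nuclei, mean_fold,
#'   sd_fold, se_fold.
#' @examples
#' df <- data.frame(kind = "DFC", probe_id = "p2", uv_condition = "plusUV",
#'                  enrichment_fold = c(1.2, 1.4))
#' summarizeEnrichment(df)  # mean 1.3, se 0.1
#' @export
summarizeEnrichment <- function(records) {
  if (!nrow(records)) stop("at least one enrichment record required")
  for (col in c("kind", "probe_id", "uv_condition"))
    if (!col %in% names(records)) records[[col]] <- NA_character_
  key <- interaction(lapply(records[c("kind", "probe_id", "uv_condition")],
                            function(x) factor(x, exclude = NULL)),
                     drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    v <- g$enrichment_fold
    s <- if (length(v) > 1) stats::sd(v) else 0
    data.frame(kind = g$kind[1], probe_id = g$probe_id[1],
               uv_condition = g$uv_condition[1], n_nuclei = length(v),
               mean_fold = mean(v), sd_fold = s, se_fold = s / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate an enrichment sample of n nuclei at a configured fold
#'
#' Renders as many independent synthetic fields as needed (with the spec's
#' noise model), segments the configured subcompartment from the marker
#' channel within the ground-truth nuclei and returns the first
#' \code{nNuclei} per-nucleus enrichment folds. Used by the recovery
#' studies validating the enrichment estimator.
#'
#' @param fold True enrichment fold.
#' @param nNuclei Number of nuclei to collect.
#' @param seed Integer seed.
#' @param kind Subcompartment kind.
#' @param nCellsPerField Cells per rendered field.
#' @param spec Optional base \linkS4class{FieldSpec} to override defaults.
#' @return Numeric vector of \code{nNuclei} estimated folds.
#' @export
simulateEnrichmentSample <- function(fold, nNuclei, seed = 1L, kind = "DFC",
                                     nCellsPerField = 17L, spec = NULL) {
  if (is.null(spec))
    spec <- fieldSpec(imageHeight = 320L, imageWidth = 320L,
                      nCells = as.integer(nCellsPerField),
                      cellRadiusRange = c(16, 22),
                      nucleusRadiusRange = c(9, 13),
                      subcompartments = data.frame(
                        kind = kind, fociPerNucleus = 4L,
                        focusRadiusMin = 2.5, focusRadiusMax = 4))
  spec@enrichmentFolds <- stats::setNames(fold, kind)
  folds <- numeric(0)
  i <- 0L
  while (length(folds) < nNuclei && i < 100L) {
    i <- i + 1L
    speci <- spec
    speci@seed <- stageSeed(seed, paste0("enrichfield", i))
    scene <- renderScene(sampleCellLayout(speci), speci,
                         channels = c("marker", "probe"))
    sm <- segmentSubcompartment(getChannel(scene, "marker"),
                                nucleusLabels(sceneTruth(scene)), kind)
    rec <- suppressMessages(
      computeEnrichment(getChannel(scene, "probe"), sm))
    folds <- c(folds, rec$enrichment_fold)
  }
  if (length(folds) < nNuclei)
    stop("could not collect the requested number of nuclei")
  folds[seq_len(nNuclei)]
}

#' Enrichment-fold recovery study
#'
#' For each true fold, simulates \code{nNuclei} per-nucleus estimates at the
#' default noise model and reports the mean estimate and its bias.
#'
#' @param folds True folds to sweep.
#' @param nNuclei Nuclei per condition.
#' @param seed Integer seed.
#' @param kind Subcompartment kind.
#' @return data.frame: true_fold, mean_estimate, se, bias.
#' @export
enrichmentRecoveryStudy <- function(folds = c(1.0, 1.2, 1.35, 1.4, 2.0),
                                    nNuclei = 50L, seed = 1L, kind = "DFC") {
  out <- lapply(seq_along(folds), function(i) {
    f <- simulateEnrichmentSample(folds[i], nNuclei,
                                  seed = stageSeed(seed, paste0("fold", i)),
                                  kind = kind)
    data.frame(true_fold = folds[i], mean_estimate = mean(f),
               se = stats::sd(f) / sqrt(length(f)),
               bias = mean(f) - folds[i])
  })
  do.call(rbind, out)
}

#' Null rejection rate of the enrichment Mann-Whitney comparison
#'
#' Repeatedly simulates two matched fold-1.0 enrichment samples and counts
#' how often the two-sided Mann-Whitney comparison rejects at level
#' \code{alpha}; a calibrated pipeline stays near \code{alpha}.
#'
#' @param nReplicates Number of replicate comparisons.
#' @param nNuclei Nuclei per group.
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return Observed rejection rate.
#' @export
enrichmentNullRejection <- function(nReplicates = 500L, nNuclei = 50L,
                                    seed = 1L, alpha = 0.05) {
  rej <- vapply(seq_len(nReplicates), function(r) {
    f <- simulateEnrichmentSample(
      1.0, 2L * nNuclei, seed = stageSeed(seed, paste0("nullrep", r)))
    ut <- mannWhitneyU(f[seq_len(nNuclei)], f[nNuclei + seq_len(nNuclei)],
                       "two_sided")
    ut@pValue < alpha
  }, logical(1))
  mean(rej)
}
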