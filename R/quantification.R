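#' @include segmentation.R
NULL

.labelMeans <- function(raster, labels) {
  sel <- labels > 0
  if (!any(sel)) return(numeric(0))
  sums <- tapply(raster[sel], labels[sel], sum)
  ns <- tapply(raster[sel], labels[sel], length)
  structure(as.numeric(sums / ns), names = names(sums))
}

#' Measure per-cell, per-compartment probe intensities
#'
#' One record per retained cell for each of pm, cytoplasm, nucleus and the
#' whole cell: arithmetic mean intensity over the mask pixels, the
#' integrated intensity and the area. Empty compartments are skipped with a
#' warning rather than silently zeroed.
#'
#' @param probe Probe-channel raster (numeric matrix).
#' @param masks A \linkS4class{CompartmentMasks} matching the raster shape.
#' @param fieldId,probeId,timeMin,uvCondition,cellLine Metadata attached to
#'   every record.
#' @return data.frame with columns field_id, cell_id, compartment,
#'   mean_intensity, integrated_intensity, area, probe_id, time_min,
#'   uv_condition, cell_line.
#' @examples
#' spec <- fieldSpec(nCells = 2L, imageHeight = 128L, imageWidth = 128L)
#' sc <- renderScene(sampleCellLayout(spec), spec, noise = FALSE)
#' cm <- deriveCompartments(cellLabels(sceneTruth(sc)),
#'                          nucleusLabels(sceneTruth(sc)))
#' head(measureCompartments(getChannel(sc, "probe"), cm))
#' @export
measureCompartments <- function(probe, masks, fieldId = "field1",
                                probeId = NA_character_, timeMin = NA_real_,
                                uvCondition = NA_character_,
                                cellLine = NA_character_) {
  stopifnot(is(masks, "CompartmentMasks"))
  if (!identical(dim(probe), dim(masks@cellLabels)))
    stop("probe raster shape must match masks")
  cl <- masks@cellLabels; nl <- masks@nucleusLabels
  pmL <- ifelse(masks@pmMask, cl, 0L)
  cyL <- ifelse(masks@cytoplasmMask, cl, 0L)
  comp <- list(pm = pmL, cytoplasm = cyL, nucleus = nl, whole_cell = cl)
  recs <- list()
  ids <- sort(unique(cl[cl > 0]))
  for (nm in names(comp)) {
    mu <- .labelMeans(probe, comp[[nm]])
    area <- tapply(rep(1L, sum(comp[[nm]] > 0)),
                   comp[[nm]][comp[[nm]] > 0], sum)
    missing <- setdiff(as.character(ids), names(mu))
    if (length(missing))
      warning(sprintf("cell(s) %s: empty %s compartment, record skipped",
                      paste(missing, collapse = ","), nm))
    if (!length(mu)) next
    recs[[nm]] <- data.frame(
      field_id = fieldId, cell_id = as.integer(names(mu)), compartment = nm,
      mean_intensity = as.numeric(mu),
      integrated_intensity = as.numeric(mu) * as.numeric(area[names(mu)]),
      area = as.numeric(area[names(mu)]),
      probe_id = probeId, time_min = timeMin, uv_condition = uvCondition,
      cell_line = cellLine, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[order(out$cell_id, match(out$compartment, names(comp))), , drop = FALSE]
}

#' Estimate the probe background from untreated fields
#'
#' The background is the pooled mean probe intensity over all cell pixels
#' of the untreated fields (the labeling protocol gives minimal
#' cell-specific signal without probe treatment, so whatever remains is
#' background).
#'
#' @param probes List of probe rasters from untreated fields.
#' @param cellMasks List of matching cell label rasters (or
#'   \linkS4class{CompartmentMasks}).
#' @param fieldIds Optional field ids recorded as the estimate's source.
#' @return A \linkS4class{BackgroundModel}. With no untreated fields the
#'   background is 0 and a warning is issued.
#' @export
estimateBackground <- function(probes, cellMasks, fieldIds = NULL) {
  if (!length(probes)) {
    warning("no untreated fields: background set to 0")
    return(new("BackgroundModel", background = 0, sourceFields = character()))
  }
  if (is.null(fieldIds)) fieldIds <- paste0("field", seq_along(probes))
  total <- 0; npix <- 0
  for (i in seq_along(probes)) {
    cm <- cellMasks[[i]]
    lab <- if (is(cm, "CompartmentMasks")) cm@cellLabels else cm
    sel <- lab > 0
    total <- total + sum(probes[[i]][sel])
    npix <- npix + sum(sel)
  }
  if (npix == 0) {
    warning("untreated fields contain no cell pixels: background set to 0")
    return(new("BackgroundModel", background = 0,
               sourceFields = as.character(fieldIds)))
  }
  new("BackgroundModel", background = total / npix,
      sourceFields = as.character(fieldIds))
}

#' Subtract the scalar background from intensity records
#'
#' Corrected means may be negative; no clipping is applied so group means
#' stay unbiased.
#'
#' @param records data.frame from \code{\link{measureCompartments}}.
#' @param model A \linkS4class{BackgroundModel} (or a scalar).
#' @return The records with corrected \code{mean_intensity} and
#'   \code{integrated_intensity}.
#' @export
subtractBackground <- function(records, model) {
  bg <- if (is(model, "BackgroundModel")) model@background else as.numeric(model)
  records$mean_intensity <- records$mean_intensity - bg
  records$integrated_intensity <- records$integrated_intensity -
    bg * records$area
  records
}

#' Summarize intensity records by condition
#'
#' Per group: number of cells, mean, sample standard deviation (n-1
#' denominator) and standard error. Size-1 groups report SD 0 and are
#' flagged.
#'
#' @param records data.frame of intensity records.
#' @param groupBy Columns to group by.
#' @param value Column to summarize (default \code{mean_intensity}).
#' @return data.frame with the grouping columns plus n_cells, mean, sd, se,
#'   singleton.
#' @examples
#' df <- data.frame(probe_id = "p2", compartment = "nucleus",
#'                  mean_intensity = c(2, 4, 6))
#' summarizeConditions(df, groupBy = c("probe_id", "compartment"))
#' @export
summarizeConditions <- function(records,
                                groupBy = c("probe_id", "cell_line",
                                            "time_min", "uv_condition",
                                            "compartment"),
                                value = "mean_intensity") {
  groupBy <- intersect(groupBy, names(records))
  if (!length(groupBy)) stop("no grouping columns present in records")
  if (!nrow(records)) stop("records must be nonempty")
  keyCols <- lapply(records[groupBy], function(x) factor(x, exclude = NULL))
  key <- interaction(keyCols, drop = TRUE, lex.order = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    v <- g[[value]]
    n <- length(v)
    s <- if (n > 1) stats::sd(v) else 0
    cbind(g[1, groupBy, drop = FALSE],
          data.frame(n_cells = n, mean = mean(v), sd = s, se = s / sqrt(n),
                     singleton = n == 1L))
  }))
  rownames(out) <- NULL
  out
}

#' One-sided (or two-sided) two-sample Student's t-test
#'
#' Classic pooled-variance Student's t between two groups of per-cell
#' means. Zero pooled variance is flagged degenerate with p forced to 0 or
#' 1 by the sign of the mean difference.
#'
#' @param groupA,groupB Numeric vectors (n >= 2 each).
#' @param alternative \code{"greater"} (A > B), \code{"less"} or
#'   \code{"two.sided"}.
#' @return List: statistic, df, pValue, degenerate.
#' @examples
#' compareGroupsTTest(c(11, 12, 13), c(1, 2, 3), "greater")$pValue
#' @export
compareGroupsTTest <- function(groupA, groupB,
                               alternative = c("greater", "less",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need at least 2 observations")
  sp2 <- ((length(groupA) - 1) * stats::var(groupA) +
          (length(groupB) - 1) * stats::var(groupB)) /
         (length(groupA) + length(groupB) - 2)
  if (sp2 == 0) {
    d <- mean(groupA) - mean(groupB)
    p <- switch(alternative,
                greater = if (d > 0) 0 else 1,
                less = if (d < 0) 0 else 1,
                two.sided = if (d != 0) 0 else 1)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                df = length(groupA) + length(groupB) - 2,
                pValue = p, degenerate = TRUE))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = TRUE,
                      alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value, degenerate = FALSE)
}

#' Piecewise-linear interpolation of a time course
#'
#' Exact linear interpolation through the group means, mirroring the
#' linear-interpolation overlays of uptake time courses. No extrapolation
#' beyond the observed times (queries outside return NA). Duplicate time
#' points are averaged first (with a message).
#'
#' @param times Observed times (minutes).
#' @param means Group means at those times.
#' @return List: \code{fun} (vectorized interpolant), \code{times},
#'   \code{means} (the knots after duplicate averaging).
#' @examples
#' curve <- interpolateTimecourse(c(0, 10), c(0, 10))
#' curve$fun(5)
#' @export
interpolateTimecourse <- function(times, means) {
  if (length(times) != length(means)) stop("times and means must align")
  if (anyDuplicated(times)) {
    message("duplicate time points averaged before interpolation")
    means <- as.numeric(tapply(means, times, mean))
    times <- sort(unique(times))
  } else {
    o <- order(times)
    times <- times[o]; means <- means[o]
  }
  if (length(times) < 2) stop("need at least 2 time points")
  f <- stats::approxfun(times, means, method = "linear", rule = 1)
  list(fun = f, times = times, means = means)
}

#' Uptake-rate recovery study
#'
#' Simulates a linear-uptake time course (fields without subnuclear foci,
#' mirroring the uptake experiments where no compartment marker is
#' imaged), runs the full segmentation + quantification pipeline on every
#' field, and recovers the uptake rate as the fitted slope of the
#' per-time-point mean nuclear intensity divided by the nucleoplasm base
#' level.
#'
#' @param times Labeling times, minutes.
#' @param rate True uptake rate per minute.
#' @param nFieldsPerTime Independent fields per time point.
#' @param seed Integer seed.
#' @return List: rateHat, trueRate, relError, groupMeans (data.frame of
#'   per-time mean nuclear intensity and cell count).
#' @export
uptakeRecoveryStudy <- function(times = c(10, 30, 60, 120, 360),
                                rate = 0.01, nFieldsPerTime = 3L,
                                seed = 1L) {
  noFoci <- data.frame(kind = character(), fociPerNucleus = integer(),
                       focusRadiusMin = numeric(), focusRadiusMax = numeric())
  spec <- fieldSpec(imageHeight = 320L, imageWidth = 320L, nCells = 17L,
                    cellRadiusRange = c(16, 22),
                    nucleusRadiusRange = c(9, 13),
                    subcompartments = noFoci, enrichmentFolds = numeric(0))
  gm <- do.call(rbind, lapply(seq_along(times), function(i) {
    nucMeans <- unlist(lapply(seq_len(nFieldsPerTime), function(j) {
      sp <- spec
      sp@seed <- stageSeed(seed, paste0("uptake", i, ".", j))
      sc <- renderScene(sampleCellLayout(sp), sp, timeMin = times[i],
                        uptakeScale = rate * times[i])
      cm <- segmentField(sc@channels)
      rec <- measureCompartments(getChannel(sc, "probe"), cm)
      rec$mean_intensity[rec$compartment == "nucleus"]
    }))
    data.frame(time_min = times[i], mean = mean(nucMeans),
               n_cells = length(nucMeans))
  }))
  fit <- stats::lm(mean ~ time_min, data = gm)
  rateHat <- unname(stats::coef(fit)[2]) / spec@baseLevels[["nucleoplasm"]]
  list(rateHat = rateHat, trueRate = rate,
       relError = abs(rateHat - rate) / rate, groupMeans = gm)
}

#' Measure every compartment of a synthetic scene against its truth masks
#'
#' Convenience used by recovery studies: quantifies the probe channel of a
#' scene over the generator's own compartment masks.
#'
#' @param scene A \linkS4class{SyntheticScene}.
#' @param ... Metadata passed to \code{\link{measureCompartments}}.
#' @return data.frame of intensity records.
#' @export
measureSceneTruth <- function(scene, ...) {
  truth <- sceneTruth(scene)
  cm <- suppressWarnings(deriveCompartments(
    cellLabels(truth), nucleusLabels(truth),
    segmentationParams(excludeBorderCells = FALSE)))
  measureCompartments(getChannel(scene, "probe"), cm,
                      timeMin = scene@timeMin,
                      uvCondition = sceneCondition(scene), ...)
}
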