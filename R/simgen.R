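#' @include utils.R
NULL

# --- geometry helpers -------------------------------------------------------

# Is the ellipse (cy1,cx1,a1,b1) fully inside the ellipse (cy2,cx2,a2,b2)?
# a = column semi-axis, b = row semi-axis; checked on an angular grid.
.ellipseInEllipse <- function(cy1, cx1, a1, b1, cy2, cx2, a2, b2,
                              margin = 0.98, ntheta = 64L) {
  th <- seq(0, 2 * pi, length.out = ntheta)
  x <- cx1 + a1 * cos(th)
  y <- cy1 + b1 * sin(th)
  all(((x - cx2) / a2)^2 + ((y - cy2) / b2)^2 <= margin)
}

.diskInEllipse <- function(cy, cx, r, ecy, ecx, a, b,
                           margin = 0.98, ntheta = 32L) {
  .ellipseInEllipse(cy, cx, r, r, ecy, ecx, a, b, margin, ntheta)
}

#' Sample a non-overlapping cell layout
#'
#' Rejection-samples \code{nCells} elliptical cells with mild random
#' eccentricity into the field so that bounding circles do not overlap
#' (pairwise center distance exceeds the sum of bounding radii plus
#' \code{minSpacing}), places one nucleus fully inside each cell, and places
#' disk-like subcompartment foci fully inside each nucleus. Deterministic
#' for a fixed spec seed.
#'
#' @param spec A \linkS4class{FieldSpec}.
#' @return A list with data.frames \code{cells} (id, cy, cx, a, b),
#'   \code{nuclei} (same columns) and \code{foci} (id, cy, cx, r, kind),
#'   plus \code{height}/\code{width}. Coordinates are 1-based pixel centers;
#'   \code{a} is the column (x) semi-axis, \code{b} the row (y) semi-axis.
#' @examples
#' geom <- sampleCellLayout(fieldSpec(nCells = 3L, seed = 2L))
#' nrow(geom$cells)
#' @export
sampleCellLayout <- function(spec) {
  stopifnot(is(spec, "FieldSpec"))
  validObject(spec)
  H <- spec@imageHeight; W <- spec@imageWidth
  empty <- list(
    cells = data.frame(id = integer(), cy = numeric(), cx = numeric(),
                       a = numeric(), b = numeric()),
    nuclei = data.frame(id = integer(), cy = numeric(), cx = numeric(),
                        a = numeric(), b = numeric()),
    foci = data.frame(id = integer(), cy = numeric(), cx = numeric(),
                      r = numeric(), kind = character()),
    height = H, width = W)
  if (spec@nCells == 0L) return(empty)

  withSeed(stageSeed(spec@seed, "layout"), {
    n <- spec@nCells
    rr <- spec@cellRadiusRange
    budget <- 4000L * n
    cy <- cx <- a <- b <- rb <- numeric(0)
    attempts <- 0L
    while (length(cy) < n && attempts < budget) {
      attempts <- attempts + 1L
      ai <- runif(1, rr[1], rr[2]); bi <- runif(1, rr[1], rr[2])
      ri <- max(ai, bi)
      if (2 * (ri + 2) >= min(H, W)) next
      yi <- runif(1, ri + 2, H - ri - 1)
      xi <- runif(1, ri + 2, W - ri - 1)
      if (length(cy) == 0 ||
          all(sqrt((cy - yi)^2 + (cx - xi)^2) > rb + ri + spec@minSpacing)) {
        cy <- c(cy, yi); cx <- c(cx, xi); a <- c(a, ai); b <- c(b, bi)
        rb <- c(rb, ri)
      }
    }
    if (length(cy) < n)
      stop(sprintf(
        "cell placement failed: placed %d of %d cells within the sampling budget; reduce nCells or cell radii",
        length(cy), n))
    cells <- data.frame(id = seq_len(n), cy = cy, cx = cx, a = a, b = b)

    nr <- spec@nucleusRadiusRange
    nuclei <- cells
    for (i in seq_len(n)) {
      na <- runif(1, nr[1], nr[2]); nb <- runif(1, nr[1], nr[2])
      ncy <- cells$cy[i]; ncx <- cells$cx[i]
      for (try in seq_len(50L)) {
        dy <- runif(1, -(cells$b[i] - nb), cells$b[i] - nb) * 0.5
        dx <- runif(1, -(cells$a[i] - na), cells$a[i] - na) * 0.5
        if (.ellipseInEllipse(cells$cy[i] + dy, cells$cx[i] + dx, na, nb,
                              cells$cy[i], cells$cx[i],
                              cells$a[i], cells$b[i])) {
          ncy <- cells$cy[i] + dy; ncx <- cells$cx[i] + dx
          break
        }
      }
      nuclei$cy[i] <- ncy; nuclei$cx[i] <- ncx
      nuclei$a[i] <- na; nuclei$b[i] <- nb
    }

    foci <- empty$foci
    sc <- spec@subcompartments
    if (nrow(sc)) for (s in seq_len(nrow(sc))) {
      if (sc$kind[s] == "heterochromatin") next  # rendered as a rim band
      for (i in seq_len(n)) {
        placedF <- 0L
        for (f in seq_len(sc$fociPerNucleus[s])) {
          r <- runif(1, sc$focusRadiusMin[s], sc$focusRadiusMax[s])
          for (try in seq_len(200L)) {
            fy <- runif(1, nuclei$cy[i] - nuclei$b[i], nuclei$cy[i] + nuclei$b[i])
            fx <- runif(1, nuclei$cx[i] - nuclei$a[i], nuclei$cx[i] + nuclei$a[i])
            if (.diskInEllipse(fy, fx, r, nuclei$cy[i], nuclei$cx[i],
                               nuclei$a[i], nuclei$b[i])) {
              foci <- rbind(foci, data.frame(id = i, cy = fy, cx = fx, r = r,
                                             kind = sc$kind[s]))
              placedF <- placedF + 1L
              break
            }
          }
        }
        if (placedF == 0L)
          stop(sprintf("could not place any focus inside nucleus %d", i))
      }
    }
    list(cells = cells, nuclei = nuclei, foci = foci, height = H, width = W)
  })
}

# Fill an ellipse into an integer label raster (1-based pixel centers).
.fillEllipse <- function(labels, cy, cx, a, b, value) {
  H <- nrow(labels); W <- ncol(labels)
  rows <- max(1L, floor(cy - b)):min(H, ceiling(cy + b))
  cols <- max(1L, floor(cx - a)):min(W, ceiling(cx + a))
  inside <- outer(((rows - cy) / b)^2, ((cols - cx) / a)^2, "+") <= 1
  sub <- labels[rows, cols, drop = FALSE]
  sub[inside] <- value
  labels[rows, cols] <- sub
  labels
}

#' Rasterize a sampled layout into ground-truth masks
#'
#' @param geometry Output of \code{\link{sampleCellLayout}}.
#' @param spec The \linkS4class{FieldSpec} the geometry was sampled from.
#' @return A \linkS4class{GroundTruth}: cell and nucleus label rasters,
#'   plasma-membrane band mask (pixels within \code{membraneBandWidth} of
#'   the cell boundary, nucleus pixels excluded), one binary mask per
#'   configured subcompartment kind, and the configured folds.
#' @export
rasterizeGeometry <- function(geometry, spec) {
  H <- geometry$height; W <- geometry$width
  cellL <- matrix(0L, H, W)
  nucL <- matrix(0L, H, W)
  for (i in seq_len(nrow(geometry$cells))) {
    g <- geometry$cells[i, ]
    cellL <- .fillEllipse(cellL, g$cy, g$cx, g$a, g$b, g$id)
    gn <- geometry$nuclei[i, ]
    nucL <- .fillEllipse(nucL, gn$cy, gn$cx, gn$a, gn$b, gn$id)
  }
  nucL[cellL != nucL] <- 0L  # rasterization guard: nucleus stays in its cell

  pm <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(geometry$cells))) {
    id <- geometry$cells$id[i]
    bb <- maskBBox(cellL == id, pad = 1L)
    if (is.null(bb)) next
    m <- cellL[bb$rows, bb$cols] == id
    d <- EBImage::distmap(m)
    loc <- m & d <= spec@membraneBandWidth & nucL[bb$rows, bb$cols] != id
    pm[bb$rows, bb$cols] <- pm[bb$rows, bb$cols] | loc
  }

  scMasks <- list()
  kinds <- unique(spec@subcompartments$kind)
  for (kind in kinds) {
    m <- matrix(FALSE, H, W)
    if (kind == "heterochromatin") {
      for (i in seq_len(nrow(geometry$nuclei))) {
        id <- geometry$nuclei$id[i]
        bb <- maskBBox(nucL == id, pad = 1L)
        if (is.null(bb)) next
        nm <- nucL[bb$rows, bb$cols] == id
        d <- EBImage::distmap(nm)
        m[bb$rows, bb$cols] <- m[bb$rows, bb$cols] | (nm & d <= spec@rimWidth)
      }
    } else {
      fk <- geometry$foci[geometry$foci$kind == kind, , drop = FALSE]
      for (f in seq_len(nrow(fk))) {
        g <- fk[f, ]
        rows <- max(1L, floor(g$cy - g$r)):min(H, ceiling(g$cy + g$r))
        cols <- max(1L, floor(g$cx - g$r)):min(W, ceiling(g$cx + g$r))
        inside <- outer((rows - g$cy)^2, (cols - g$cx)^2, "+") <= g$r^2
        inside <- inside & nucL[rows, cols] == g$id
        m[rows, cols] <- m[rows, cols] | inside
      }
    }
    scMasks[[kind]] <- m
  }

  new("GroundTruth", cellLabels = cellL, nucleusLabels = nucL, pmMask = pm,
      subcompartmentMasks = scMasks, trueFolds = spec@enrichmentFolds,
      trueCompartmentMeans = spec@baseLevels)
}

#' Apply the camera noise model to a raster
#'
#' Poisson shot noise at \code{poissonScale} photons per intensity unit,
#' followed by additive Gaussian read noise, clipped at zero. Deterministic
#' for a fixed seed; \code{poissonScale = Inf} with \code{gaussianSd = 0}
#' returns the input unchanged.
#'
#' @param raster Non-negative numeric matrix (AU).
#' @param poissonScale Photons per AU; larger means less shot noise.
#' @param gaussianSd Read-noise standard deviation, AU.
#' @param seed Integer seed.
#' @return Noisy raster, same shape, clipped at 0.
#' @examples
#' x <- matrix(100, 10, 10)
#' identical(applyNoise(x, Inf, 0, 1L), x)
#' @export
applyNoise <- function(raster, poissonScale = 4, gaussianSd = 2, seed = 1L) {
  if (!is.numeric(poissonScale) || !is.numeric(gaussianSd) ||
      poissonScale <= 0 || gaussianSd < 0)
    stop("noise parameters must be non-negative (poissonScale > 0)")
  if (any(raster < 0)) stop("raster must be non-negative")
  d <- dim(raster)
  withSeed(seed, {
    out <- if (is.finite(poissonScale))
      stats::rpois(length(raster), as.vector(raster) * poissonScale) / poissonScale
    else as.vector(raster)
    if (gaussianSd > 0)
      out <- out + stats::rnorm(length(out), 0, gaussianSd)
    out <- pmax(out, 0)
    dim(out) <- d
    out
  })
}

#' Render a synthetic multichannel scene
#'
#' Renders DAPI (nonzero only in nuclei), membrane marker (peaking on the
#' plasma-membrane band), subcompartment marker and probe channels from a
#' sampled layout. Noise-free probe values are
#' \code{background + uptakeScale * level(compartment)}, with subcompartment
#' pixels at \code{background + uptakeScale * fold * nucleoplasm level};
#' untreated scenes carry the background only.
#'
#' @param geometry Output of \code{\link{sampleCellLayout}}.
#' @param spec The \linkS4class{FieldSpec}.
#' @param timeMin Labeling time in minutes (metadata only).
#' @param condition \code{"plusUV"}, \code{"minusUV"} or \code{"untreated"}.
#' @param uptakeScale Dimensionless multiplier on the compartment base
#'   levels (time-course scenes use \code{rate * t}).
#' @param noise Apply the spec's noise model? (default TRUE)
#' @param truth Optional pre-computed \linkS4class{GroundTruth}.
#' @param channels Which channels to render (default all four); recovery
#'   loops that only analyze marker and probe can skip the rest.
#' @return A \linkS4class{SyntheticScene}.
#' @examples
#' spec <- fieldSpec(nCells = 2L, imageHeight = 128L, imageWidth = 128L)
#' sc <- renderScene(sampleCellLayout(spec), spec, noise = FALSE)
#' channelNames(sc)
#' @export
renderScene <- function(geometry, spec, timeMin = NA_real_,
                        condition = c("plusUV", "minusUV", "untreated"),
                        uptakeScale = 1, noise = TRUE, truth = NULL,
                        channels = c("dapi", "membrane", "marker", "probe")) {
  condition <- match.arg(condition)
  channels <- match.arg(channels, several.ok = TRUE)
  if (is.null(truth)) truth <- rasterizeGeometry(geometry, spec)
  H <- nrow(truth@cellLabels); W <- ncol(truth@cellLabels)
  cellL <- truth@cellLabels; nucL <- truth@nucleusLabels
  lv <- spec@stainLevels; bg <- spec@backgroundLevel
  ch <- list()

  if ("dapi" %in% channels) {
    dapi <- matrix(0, H, W); dapi[nucL > 0] <- lv[["dapi"]]
    ch$dapi <- dapi
  }
  if ("membrane" %in% channels) {
    membrane <- matrix(0, H, W)
    membrane[cellL > 0] <- lv[["cellInterior"]]
    membrane[truth@pmMask] <- lv[["membrane"]]
    ch$membrane <- membrane
  }
  if ("marker" %in% channels) {
    marker <- matrix(0, H, W)
    if (length(truth@subcompartmentMasks)) {
      marker[nucL > 0] <- lv[["markerNucleoplasm"]]
      marker[truth@subcompartmentMasks[[1L]]] <- lv[["marker"]]
    }
    ch$marker <- marker
  }
  s <- if (condition == "untreated") 0 else uptakeScale
  if ("probe" %in% channels) {
    probe <- matrix(bg, H, W)
    if (s > 0) {
      base <- spec@baseLevels
      cyto <- cellL > 0 & nucL == 0 & !truth@pmMask
      probe[truth@pmMask] <- bg + s * base[["pm"]]
      probe[cyto] <- bg + s * base[["cytoplasm"]]
      probe[nucL > 0] <- bg + s * base[["nucleoplasm"]]
      for (kind in names(truth@subcompartmentMasks)) {
        fold <- spec@enrichmentFolds[kind]
        if (is.na(fold)) fold <- 1
        probe[truth@subcompartmentMasks[[kind]]] <-
          bg + s * fold * base[["nucleoplasm"]]
      }
    }
    ch$probe <- probe
  }
  truth@trueCompartmentMeans <- c(
    pm = bg + s * spec@baseLevels[["pm"]],
    cytoplasm = bg + s * spec@baseLevels[["cytoplasm"]],
    nucleoplasm = bg + s * spec@baseLevels[["nucleoplasm"]])

  if (noise) {
    tkey <- if (is.na(timeMin)) "na" else format(timeMin)
    for (nm in names(ch))
      ch[[nm]] <- applyNoise(ch[[nm]], spec@poissonScale, spec@gaussianSd,
                             stageSeed(spec@seed,
                                       paste("noise", nm, condition, tkey)))
  }
  new("SyntheticScene", channels = channelStack(ch), truth = truth,
      timeMin = as.numeric(timeMin), condition = condition)
}

#' Generate a labeling time course of independent synthetic fields
#'
#' Each time point is an independently sampled field whose probe levels
#' scale linearly with time: \code{level(t) = uptakeRate * t * baseLevel}
#' (monotone non-decreasing by construction). At \code{t = 0} the probe
#' channel carries background only.
#'
#' @param spec A \linkS4class{FieldSpec}; each time point derives its own
#'   sub-seed from \code{spec@seed}.
#' @param times Sorted, non-negative labeling times in minutes.
#' @param uptakeRate Uptake rate per minute (dimensionless multiplier on
#'   base levels per minute).
#' @param condition Condition label for all scenes.
#' @param noise Apply the noise model? (default TRUE)
#' @return List of \linkS4class{SyntheticScene}, one per time point.
#' @examples
#' tc <- generateTimeCourse(fieldSpec(nCells = 2L, imageHeight = 128L,
#'                                    imageWidth = 128L),
#'                          times = c(0, 30), uptakeRate = 1 / 60)
#' length(tc)
#' @export
generateTimeCourse <- function(spec, times, uptakeRate,
                               condition = "plusUV", noise = TRUE) {
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted increasing")
  lapply(seq_along(times), function(i) {
    speci <- spec
    speci@seed <- stageSeed(spec@seed, paste0("timepoint", i))
    geom <- sampleCellLayout(speci)
    renderScene(geom, speci, timeMin = times[i], condition = condition,
                uptakeScale = uptakeRate * times[i], noise = noise)
  })
}

#' Generate a synthetic multi-lane gel image
#'
#' Renders one Gaussian-band profile per lane along the migration axis,
#' scaled so the noise-free integrated signal above baseline equals each
#' lane's configured true signal, replicated across the lane width with a
#' slight lateral taper (so lane centers are detectable as column-sum
#' peaks). Ladder lanes get an evenly spaced band pattern and are excluded
#' from quantification truth downstream.
#'
#' @param gelspec A \linkS4class{GelSpec}.
#' @return List: \code{raster} (numeric matrix, rows = migration axis),
#'   \code{lanes} data.frame (lane, role, trueSignal, colStart, colEnd,
#'   center), and the input \code{spec}.
#' @examples
#' gel <- generateGel(gelSpec(noiseSd = 0, seed = 1L))
#' nrow(gel$lanes)
#' @export
generateGel <- function(gelspec) {
  stopifnot(is(gelspec, "GelSpec"))
  validObject(gelspec)
  L <- gelspec@profileLength
  nl <- length(gelspec@laneRoles)
  wd <- gelspec@laneWidth; gap <- gelspec@laneGap
  W <- gap + nl * (wd + gap)
  raster <- matrix(gelspec@baselineLevel, L, W)
  rows <- seq_len(L)
  # lateral taper across the lane width; peak at the lane center
  lat <- 0.7 + 0.3 * cos(seq(-pi / 3, pi / 3, length.out = wd))
  lanes <- data.frame(lane = seq_len(nl), role = gelspec@laneRoles,
                      trueSignal = gelspec@trueSignals,
                      colStart = NA_integer_, colEnd = NA_integer_,
                      center = NA_real_)
  for (i in seq_len(nl)) {
    c0 <- gap + (i - 1L) * (wd + gap) + 1L
    c1 <- c0 + wd - 1L
    lanes$colStart[i] <- c0; lanes$colEnd[i] <- c1
    lanes$center[i] <- (c0 + c1) / 2
    layout <- if (gelspec@laneRoles[i] == "ladder")
      data.frame(position = seq(0.15, 0.85, length.out = 6),
                 width = 2, mass = 1)
    else gelspec@bandLayout
    bump <- rep(0, L)
    for (j in seq_len(nrow(layout)))
      bump <- bump + layout$mass[j] *
        exp(-(rows - layout$position[j] * L)^2 / (2 * layout$width[j]^2))
    if (sum(bump) > 0 && gelspec@trueSignals[i] > 0)
      bump <- bump / (sum(bump) * mean(lat)) * gelspec@trueSignals[i]
    raster[, c0:c1] <- raster[, c0:c1] + outer(bump, lat)
  }
  if (gelspec@noiseSd > 0)
    raster <- withSeed(stageSeed(gelspec@seed, "gel"), {
      pmax(raster + stats::rnorm(length(raster), 0, gelspec@noiseSd), 0)
    })
  list(raster = raster, lanes = lanes, spec = gelspec)
}
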