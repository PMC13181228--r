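#' @include utils.R
NULL

#' Detect lane boundaries in a gel image
#'
#' Lanes are located as peaks of the column-sum profile; boundaries are the
#' midpoints between adjacent peaks. When fewer than \code{nExpected} peaks
#' are found the raster is partitioned into equal-width lanes and the
#' result is flagged as a fallback.
#'
#' @param gel 2-D numeric matrix (rows = migration axis).
#' @param nExpected Expected number of lanes (>= 1).
#' @return data.frame: lane, colStart, colEnd, center; attribute
#'   \code{fallback} is TRUE when equal-width partitioning was used.
#' @examples
#' gel <- generateGel(gelSpec(seed = 1L))
#' detectLanes(gel$raster, nrow(gel$lanes))
#' @export
detectLanes <- function(gel, nExpected) {
  if (!is.matrix(gel)) stop("gel must be a 2-D matrix")
  if (nExpected < 1) stop("nExpected must be >= 1")
  if (ncol(gel) < nExpected)
    stop(sprintf("gel raster (%d columns) narrower than %d lanes",
                 ncol(gel), nExpected))
  if (nExpected == 1) {
    out <- data.frame(lane = 1L, colStart = 1L, colEnd = ncol(gel),
                      center = (1 + ncol(gel)) / 2)
    attr(out, "fallback") <- FALSE
    return(out)
  }
  csRaw <- colSums(gel)
  # noise floor from the low-signal (gap) columns of the raw profile:
  # peaks must rise clearly above it, else detection is not trusted
  low <- csRaw[csRaw <= stats::quantile(csRaw, 0.3)]
  thr <- stats::median(low) + max(4 * stats::mad(low),
                                  1e-9 * max(diff(range(csRaw)), 1))
  # light running-mean smoothing so per-column noise does not fragment peaks
  cs <- csRaw
  k <- max(1, min(floor(ncol(gel) / (3 * nExpected)), 9))
  if (k > 1) {
    cs <- as.numeric(stats::filter(cs, rep(1 / k, k), sides = 2))
    cs[is.na(cs)] <- min(cs, na.rm = TRUE)
  }
  minDist <- max(2, floor(ncol(gel) / (2 * nExpected)))
  pk <- if (diff(range(cs)) > 0)
    pracma::findpeaks(cs, minpeakdistance = minDist, minpeakheight = thr)
  else NULL
  fallback <- is.null(pk) || nrow(pk) < nExpected
  if (!fallback) {
    if (nrow(pk) > nExpected)
      pk <- pk[order(pk[, 1], decreasing = TRUE)[seq_len(nExpected)], ,
               drop = FALSE]
    centers <- sort(pk[, 2])
    # equal-width windows centered on the peaks: keeps per-lane dilution
    # identical so downstream ratios are unaffected by window size
    half <- if (nExpected > 1) floor(stats::median(diff(centers)) / 2)
            else floor(ncol(gel) / 2)
    starts <- pmax(1, round(centers) - half)
    ends <- pmin(ncol(gel), round(centers) + half)
  } else {
    warning("fewer column-sum peaks than expected lanes: equal-width fallback")
    edges <- round(seq(0, ncol(gel), length.out = nExpected + 1))
    starts <- edges[-length(edges)] + 1
    ends <- edges[-1]
    centers <- (starts + ends) / 2
  }
  out <- data.frame(lane = seq_len(nExpected),
                    colStart = as.integer(starts), colEnd = as.integer(ends),
                    center = centers)
  attr(out, "fallback") <- fallback
  out
}

#' Extract a 1-D lane profile
#'
#' @param gel Gel raster.
#' @param colStart,colEnd Lane column bounds.
#' @return Numeric vector: mean intensity per migration row.
#' @export
extractLaneProfile <- function(gel, colStart, colEnd) {
  rowMeans(gel[, colStart:colEnd, drop = FALSE])
}

#' Integrate a lane profile above its baseline
#'
#' Baseline = median of the top and bottom 5\% migration windows; signal =
#' sum of the positive part of (profile - baseline). A flat profile
#' integrates to 0.
#'
#' @param profile Numeric lane profile.
#' @return Integrated background-subtracted signal (AU).
#' @examples
#' integrateLane(rep(5, 100))  # flat -> 0
#' @export
integrateLane <- function(profile) {
  if (!length(profile)) stop("profile must be nonempty")
  k <- max(1L, floor(0.05 * length(profile)))
  baseline <- stats::median(c(utils::head(profile, k),
                              utils::tail(profile, k)))
  sum(pmax(profile - baseline, 0))
}

#' Quantify all lanes of a gel
#'
#' @param gel Gel raster.
#' @param lanes Lane table (from \code{\link{detectLanes}} or generator
#'   truth) with colStart/colEnd, optionally role.
#' @return The lane table with an added \code{signal} column.
#' @export
quantifyLanes <- function(gel, lanes) {
  lanes$signal <- vapply(seq_len(nrow(lanes)), function(i)
    integrateLane(extractLaneProfile(gel, lanes$colStart[i],
                                     lanes$colEnd[i])), numeric(1))
  lanes
}

#' -UV/+UV incorporation ratio from paired replicates
#'
#' Each replicate pair contributes S(-UV)/S(+UV); the ratios are averaged
#' and reported with their SE, and as a percentage of covalently bound
#' probe (not capped; values above 100 by noise are flagged). Replicates
#' with non-positive +UV signal are dropped with a diagnostic. An optional
#' reference ratio set yields a one-sided pooled-variance Student's t
#' p-value for "this probe incorporates more than the reference".
#'
#' @param minusUV,plusUV Paired replicate signals (same length).
#' @param probeId,timeH Metadata.
#' @param reference Optional numeric vector of reference ratios.
#' @return List of class data: probe_id, time_h, n, ratios, mean_ratio,
#'   se_ratio, percent, flagged_over_100, p_value.
#' @examples
#' incorporationRatio(c(49, 50), c(100, 100))$percent
#' @export
incorporationRatio <- function(minusUV, plusUV, probeId = NA_character_,
                               timeH = NA_real_, reference = NULL) {
  if (length(minusUV) != length(plusUV))
    stop("minusUV and plusUV must be paired (equal length)")
  bad <- plusUV <= 0
  if (any(bad)) {
    message(sprintf("dropping %d replicate(s) with non-positive +UV signal",
                    sum(bad)))
    minusUV <- minusUV[!bad]; plusUV <- plusUV[!bad]
  }
  if (!length(plusUV)) stop("no usable replicate pairs")
  ratios <- minusUV / plusUV
  n <- length(ratios)
  s <- if (n > 1) stats::sd(ratios) else 0
  meanR <- mean(ratios)
  p <- if (!is.null(reference) && n >= 2 && length(reference) >= 2)
    compareGroupsTTest(ratios, reference, "greater")$pValue
  else NA_real_
  structure(list(probe_id = probeId, time_h = timeH, n = n, ratios = ratios,
                 mean_ratio = meanR, se_ratio = s / sqrt(n),
                 percent = 100 * meanR,
                 flagged_over_100 = meanR > 1, p_value = p),
            class = "IncorporationResult")
}

#' @export
print.IncorporationResult <- function(x, ...) {
  cat(sprintf(
    "Incorporation (probe %s, %s h): %.1f%% +/- %.1f (n = %d)%s\n",
    format(x$probe_id), format(x$time_h), x$percent, 100 * x$se_ratio, x$n,
    if (x$flagged_over_100) " [ratio > 1, flagged]" else ""))
  invisible(x)
}

#' Gel incorporation-ratio recovery study
#'
#' Simulates \code{nReplicates} independent gels with a configured
#' -UV/+UV signal ratio, runs lane detection and integration on each, and
#' recovers the incorporation percentage. Noise is additive Gaussian with
#' SD equal to \code{noiseFrac} of the peak per-pixel band amplitude of
#' the +UV lane.
#'
#' @param trueRatio Configured -UV/+UV ratio.
#' @param noiseFrac Noise SD as a fraction of the +UV peak band amplitude.
#' @param nReplicates Number of replicate gels.
#' @param seed Integer seed.
#' @param plusSignal True integrated +UV signal, AU.
#' @return List: percent (recovered), truePercent, incorporation result,
#'   perReplicate ratios.
#' @export
gelRecoveryStudy <- function(trueRatio = 0.49, noiseFrac = 0.02,
                             nReplicates = 4L, seed = 1L,
                             plusSignal = 10000) {
  roles <- c("ladder", "no_click", "untreated", "vehicle",
             "minusUV", "plusUV")
  signals <- c(3000, 40, 40, 40, trueRatio * plusSignal, plusSignal)
  ref <- generateGel(gelSpec(laneRoles = roles, trueSignals = signals,
                             noiseSd = 0, seed = 1L))
  peak <- max(ref$raster) - ref$spec@baselineLevel
  reps <- vapply(seq_len(nReplicates), function(r) {
    gs <- gelSpec(laneRoles = roles, trueSignals = signals,
                  noiseSd = noiseFrac * peak,
                  seed = stageSeed(seed, paste0("gelrep", r)))
    g <- generateGel(gs)
    lanes <- suppressWarnings(detectLanes(g$raster, length(roles)))
    lanes$role <- roles
    q <- quantifyLanes(g$raster, lanes)
    c(q$signal[q$role == "minusUV"], q$signal[q$role == "plusUV"])
  }, numeric(2))
  inc <- incorporationRatio(reps[1, ], reps[2, ])
  list(percent = inc$percent, truePercent = 100 * trueRatio,
       incorporation = inc, perReplicate = inc$ratios)
}

#' End-to-end gel analysis
#'
#' Detects lanes, integrates each, and computes the -UV/+UV incorporation
#' ratio from the minusUV/plusUV lane pairs (in order of appearance).
#' Ladder and negative-control lanes are quantified but excluded from the
#' ratio.
#'
#' @param gel Gel raster.
#' @param laneRoles Role per lane (same order as lanes appear).
#' @param probeId,timeH Metadata for the incorporation result.
#' @return List: lanes (quantified lane table), incorporation
#'   (\code{\link{incorporationRatio}} result or NULL when no pairs).
#' @export
analyzeGel <- function(gel, laneRoles, probeId = NA_character_,
                       timeH = NA_real_) {
  lanes <- detectLanes(gel, length(laneRoles))
  lanes$role <- laneRoles
  lanes <- quantifyLanes(gel, lanes)
  minus <- lanes$signal[lanes$role == "minusUV"]
  plus <- lanes$signal[lanes$role == "plusUV"]
  inc <- if (length(minus) && length(minus) == length(plus))
    incorporationRatio(minus, plus, probeId = probeId, timeH = timeH)
  else NULL
  list(lanes = lanes, incorporation = inc)
}
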