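#' @include io.R subnuclear.R geldens.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# CSV writer stamping the provenance (config hash + seed) as a comment line,
# so every table names the run it came from; read back with comment.char="#".
.writeTable <- function(df, path, prov) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config=%s seed=%d version=%s",
                     prov$configHash, prov$seed, prov$packageVersion), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Run the full simulate -> segment -> quantify -> enrich -> gel pipeline
#'
#' Executes the stages in order on synthetic fields generated from the
#' config, persisting all intermediates when \code{outdir} is given.
#' Deterministic given config + seed: one global seed is expanded into
#' per-stage substreams, and rerunning with the same config reproduces
#' byte-identical tables. Any stage error aborts with a stage-named
#' diagnostic; outputs written by earlier stages are retained.
#'
#' Config keys (all optional except none): \code{seed}; \code{field} (args
#' to \code{\link{fieldSpec}}); \code{nFields}, \code{nUntreated};
#' \code{probeId}, \code{cellLine}, \code{timeMin}, \code{condition};
#' \code{segmentation} (args to \code{\link{segmentationParams}});
#' \code{enrichment} (list with \code{kind}); \code{gel} (args to
#' \code{\link{gelSpec}}).
#'
#' @param config Named list or path to a YAML file.
#' @param outdir Optional output directory.
#' @return A \linkS4class{ResultBundle}.
#' @examples
#' \donttest{
#' cfg <- list(seed = 1L,
#'             field = list(nCells = 4L, imageHeight = 256L,
#'                          imageWidth = 256L),
#'             nFields = 1L, nUntreated = 1L,
#'             enrichment = list(kind = "DFC"))
#' rb <- runPipeline(cfg)
#' rb
#' }
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  seed <- as.integer(config$seed %||% 1L)
  prov <- list(configHash = configHash(config),
               packageVersion = as.character(utils::packageVersion("glycoclick")),
               seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  fieldArgs <- config$field %||% list()
  mkSpec <- function(s) do.call(fieldSpec, c(fieldArgs, list(seed = s)))
  nFields <- config$nFields %||% 2L
  nUntreated <- config$nUntreated %||% 1L
  segp <- do.call(segmentationParams, config$segmentation %||% list())
  meta <- list(probeId = config$probeId %||% "probe",
               cellLine = config$cellLine %||% "synthetic",
               timeMin = config$timeMin %||% NA_real_,
               condition = config$condition %||% "plusUV")

  scenes <- stage("simulate", {
    treated <- lapply(seq_len(nFields), function(i) {
      sp <- mkSpec(stageSeed(seed, paste0("field", i)))
      renderScene(sampleCellLayout(sp), sp, timeMin = meta$timeMin,
                  condition = meta$condition)
    })
    untreated <- lapply(seq_len(nUntreated), function(i) {
      sp <- mkSpec(stageSeed(seed, paste0("untreatedfield", i)))
      renderScene(sampleCellLayout(sp), sp, condition = "untreated")
    })
    list(treated = treated, untreated = untreated)
  })
  if (!is.null(outdir) && length(scenes$treated))
    writeStack(scenes$treated[[1]]@channels, file.path(outdir, "field1.tif"))

  masksList <- stage("segment", lapply(scenes$treated, segmentField, params = segp))
  masksUntreated <- stage("segment",
                          lapply(scenes$untreated, segmentField, params = segp))
  if (!is.null(outdir) && length(masksList)) {
    writeLabelMask(cellLabels(masksList[[1]]),
                   file.path(outdir, "field1_cells.tif"))
    writeLabelMask(nucleusLabels(masksList[[1]]),
                   file.path(outdir, "field1_nuclei.tif"))
  }

  quant <- stage("quantify", {
    bg <- estimateBackground(
      lapply(scenes$untreated, getChannel, "probe"), masksUntreated,
      fieldIds = paste0("untreated", seq_along(masksUntreated)))
    recs <- do.call(rbind, lapply(seq_along(masksList), function(i)
      measureCompartments(getChannel(scenes$treated[[i]], "probe"),
                          masksList[[i]], fieldId = paste0("field", i),
                          probeId = meta$probeId, timeMin = meta$timeMin,
                          uvCondition = meta$condition,
                          cellLine = meta$cellLine)))
    recs <- subtractBackground(recs, bg)
    list(background = bg, records = recs,
         summaries = summarizeConditions(recs))
  })
  if (!is.null(outdir)) {
    .writeTable(quant$records, file.path(outdir, "records.csv"), prov)
    .writeTable(quant$summaries, file.path(outdir, "summaries.csv"), prov)
  }

  enrichment <- data.frame()
  enrichmentSummary <- data.frame()
  tests <- list()
  if (!is.null(config$enrichment)) {
    enr <- stage("enrich", {
      kind <- config$enrichment$kind %||% "DFC"
      sc <- fieldArgs$subcompartments
      hasKind <- if (is.null(sc)) kind == "DFC" else kind %in% sc$kind
      if (!hasKind && kind != "heterochromatin")
        stop(sprintf(
          "enrichment kind '%s' requested but the marker channel renders no such compartment (configure field$subcompartments)",
          kind))
      parts <- lapply(seq_along(masksList), function(i) {
        sm <- segmentSubcompartment(getChannel(scenes$treated[[i]], "marker"),
                                    nucleusLabels(masksList[[i]]), kind)
        probe <- getChannel(scenes$treated[[i]], "probe")
        bg <- quant$background@background
        list(rec = suppressMessages(computeEnrichment(
               probe, sm, background = quant$background,
               probeId = meta$probeId, uvCondition = meta$condition)),
             compMeans = .labelMeans(probe, sm@compartmentLabels) - bg,
             remMeans = .labelMeans(probe, sm@remainderLabels) - bg)
      })
      list(records = do.call(rbind, lapply(parts, `[[`, "rec")),
           compMeans = unlist(lapply(parts, `[[`, "compMeans")),
           remMeans = unlist(lapply(parts, `[[`, "remMeans")))
    })
    enrichment <- enr$records
    if (nrow(enrichment)) {
      enrichmentSummary <- summarizeEnrichment(enrichment)
      # two comparisons, both emitted: compartment vs remainder per-nucleus
      # means, and the per-nucleus folds against unity
      if (length(enr$compMeans) >= 2) {
        ut <- mannWhitneyU(enr$compMeans, enr$remMeans, "two_sided")
        tests$compartment_vs_remainder <- list(U = ut@U, p = ut@pValue,
                                               method = ut@method)
      }
      folds <- enrichment$enrichment_fold
      if (length(folds) >= 2) {
        ut <- mannWhitneyU(folds, rep(1, length(folds)), "two_sided")
        tests$fold_vs_unity <- list(U = ut@U, p = ut@pValue,
                                    method = ut@method)
      }
    }
    if (!is.null(outdir)) {
      .writeTable(enrichment, file.path(outdir, "enrichment.csv"), prov)
      if (nrow(enrichmentSummary))
        .writeTable(enrichmentSummary,
                    file.path(outdir, "enrichment_summary.csv"), prov)
    }
  }

  gelRes <- list()
  if (!is.null(config$gel)) {
    gelRes <- stage("gel", {
      gspec <- do.call(gelSpec, c(config$gel,
                                  list(seed = stageSeed(seed, "gelspec"))))
      g <- generateGel(gspec)
      out <- analyzeGel(g$raster, gspec@laneRoles,
                        probeId = meta$probeId)
      out$truth <- g$lanes
      out
    })
    if (!is.null(outdir))
      .writeTable(gelRes$lanes, file.path(outdir, "gel_lanes.csv"), prov)
  }

  if (!is.null(outdir)) {
    report <- list(
      provenance = prov,
      background = quant$background@background,
      tests = tests,
      incorporation = if (!is.null(gelRes$incorporation))
        unclass(gelRes$incorporation) else NULL)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  }

  new("ResultBundle", records = quant$records, summaries = quant$summaries,
      enrichment = enrichment, enrichmentSummary = enrichmentSummary,
      gel = gelRes, masks = masksList[[1]],
      provenance = c(prov, list(tests = tests)))
}
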