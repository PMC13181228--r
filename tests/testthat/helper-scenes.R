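# Shared fixtures: small synthetic scenes, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixtureScene <- function(name, noise = FALSE, nCells = 5L, size = 256L,
                         seed = 101L, kind = "DFC", fold = 1.4,
                         background = 0, condition = "plusUV") {
  key <- paste(name, noise, nCells, size, seed, kind, fold, background,
               condition, sep = "|")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  sub <- if (kind == "heterochromatin")
    data.frame(kind = "heterochromatin", fociPerNucleus = 0L,
               focusRadiusMin = 1, focusRadiusMax = 1)
  else data.frame(kind = kind, fociPerNucleus = 4L,
                  focusRadiusMin = 2.5, focusRadiusMax = 4)
  spec <- fieldSpec(imageHeight = size, imageWidth = size, nCells = nCells,
                    subcompartments = sub,
                    enrichmentFolds = stats::setNames(fold, kind),
                    backgroundLevel = background, seed = seed)
  sc <- renderScene(sampleCellLayout(spec), spec, noise = noise,
                    condition = condition)
  .fixtures[[key]] <- list(spec = spec, scene = sc)
  .fixtures[[key]]
}

# Per-pixel brute-force mean over a labeled region (independent oracle).
bruteLabelMean <- function(raster, labels, id) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(raster))) for (j in seq_len(ncol(raster))) {
    if (labels[i, j] == id) { tot <- tot + raster[i, j]; n <- n + 1 }
  }
  tot / n
}

# Match each truth object to the segmented object with the largest overlap
# and return per-object IoU values.
matchedIoU <- function(segLabels, truthLabels) {
  ids <- sort(unique(truthLabels[truthLabels > 0]))
  vapply(ids, function(id) {
    tm <- truthLabels == id
    ov <- table(segLabels[tm])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) return(0)
    sid <- as.integer(names(which.max(ov)))
    sm <- segLabels == sid
    sum(sm & tm) / sum(sm | tm)
  }, numeric(1))
}

# Exhaustive-enumeration Mann-Whitney oracle (distinct values, no ties):
# every assignment of n1 of the pooled ranks to the first sample is equally
# likely under the null.
enumMWU <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  list(U = Uobs,
       pTwoSided = min(1, 2 * min(mean(Us <= Uobs), mean(Us >= Uobs))),
       pGreater = mean(Us >= Uobs),
       pLess = mean(Us <= Uobs))
}
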