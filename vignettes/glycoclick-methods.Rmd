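---
title: "Quantifying intracellular monosaccharide probe imaging with glycoclick"
author: "glycoclick maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular monosaccharide probe imaging with glycoclick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific background

Metabolic oligosaccharide engineering (MOE) feeds cells chemically modified
monosaccharides that enter glycosylation pathways. Bifunctional probes carry
both a diazirine (UV-crosslinkable) and an alkyne (clickable) group: after
labeling, cells are either irradiated at 300 nm and fixed (+UV) or fixed
without irradiation (−UV), then stained by copper-mediated click chemistry.
Because only covalently bound probe survives fixation without crosslinking,
the −UV/+UV signal ratio estimates the covalently incorporated fraction,
while confocal images of the clicked stain report where the probe sits in
the cell.

`glycoclick` implements the downstream quantification of such experiments:

1. **Segmentation** of each field into cells and, per cell, into plasma
   membrane (PM) band, cytoplasm and nucleus, from a DAPI channel and a
   membrane-marker channel (ZO1 or Na/K-pump antibody stain).
2. **Quantification** of per-cell, per-compartment probe intensity with
   untreated-control background correction, condition summaries, pooled
   Student's *t* comparisons and piecewise-linear uptake time courses.
3. **Subnuclear enrichment** scoring of nucleolar dense fibrillar component
   (DFC), nuclear speckle (NS) or heterochromatin masks against the
   remaining nucleoplasm, with Mann–Whitney U testing.
4. **Gel densitometry** of SDS-PAGE fluorescence lanes and the −UV/+UV
   incorporation ratio.
5. A **synthetic scene generator** with complete ground truth, used by the
   package's own validation studies.

Real acquisitions for this kind of experiment are rarely deposited, so the
package treats *parameter recovery on synthetic ground truth* as its
primary evidence of correctness: every stage is exercised on generated data
whose true folds, rates and ratios are known exactly.

## The synthetic scene model

A `FieldSpec` describes one field. Cells are axis-aligned ellipses with
mild random eccentricity, rejection-sampled so bounding circles never
overlap; each cell contains one ellipse nucleus placed fully inside it;
DFC/NS compartments are 2–6 disk foci per nucleus, heterochromatin is a
nuclear-rim band. Channels are rendered as flat compartment levels:

* `dapi` — nonzero only inside nuclei;
* `membrane` — peaks on the PM band (pixels within `membraneBandWidth` of
  the cell boundary), low inside the cell;
* `marker` — bright on the subcompartment, dimmer on the rest of the
  nucleus;
* `probe` — `background + s · level(compartment)`, where `s` is an uptake
  scale (`s = rate · t` in time courses, 0 for untreated scenes) and
  subcompartment pixels sit at `fold ×` the nucleoplasm level.

Default intensity levels are nucleoplasm 100 AU > cytoplasm 60 AU > PM
40 AU, matching the qualitative compartment ordering these probes show in
cells, with `background = 0` so that noise-free subcompartment pixels equal
`fold × nucleoplasm` exactly.

Noise follows the standard fluorescence-camera model: Poisson shot noise at
`poissonScale` photons/AU followed by additive Gaussian read noise, clipped
at zero. The defaults (`poissonScale = 4`, `gaussianSd = 2`) give SNR ≈ 20
at the nucleoplasm level. No acquisition-noise statistics are published for
this assay, so these are conventional choices, fixed once — not fitted.

What the generator deliberately does **not** emulate: real point-spread
functions, irregular cell shapes, photobleaching, chromatic shift, 3-D
structure, field-to-field illumination drift. Passing recovery tests
therefore demonstrate the *estimators* are unbiased and calibrated under
the stated noise model, not that segmentation would survive arbitrary real
tissue.

```{r example-scene}
library(glycoclick)
spec <- fieldSpec(nCells = 9L, enrichmentFolds = c(DFC = 1.4), seed = 1L)
scene <- renderScene(sampleCellLayout(spec), spec)
scene
```

## Segmentation

Nuclei: Gaussian smoothing (`smoothingSigma = 1` px), a global Otsu
threshold, hole filling, a distance-transform watershed that splits
touching nuclei (maxima closer than `minSeedSeparation = 7` px merge into
one seed), and an area filter (`minNucleusArea = 40` px²). The Otsu
threshold is computed on the data's own histogram, so all masks are
invariant to a global multiplicative gain.

Cells: seeded watershed on the smoothed membrane channel
(`EBImage::propagate`), one basin per nucleus, restricted to the filled
membrane-threshold foreground. Cell count equals nucleus count by
construction; a nucleus that leaks over its basin is clipped with a
warning.

Compartments: the PM band is defined *geometrically* — pixels of a cell
within `membraneBandWidth = 3` px (Euclidean distance) of that cell's
boundary — rather than by thresholding the marker, because marker staining
quality varies between antibodies and cell lines; the width is
configurable. Nucleus pixels always win ties over the band (the nucleus is
subtracted last), so nuclear measurements are never contaminated; the
cytoplasm is the remainder. The three compartments are pairwise disjoint
and tile each cell exactly — this partition is enforced by the
`CompartmentMasks` validity method on every construction. Cells touching
the image border are dropped by default because partial cells bias
per-cell means.

## Quantification

The primary statistic is the per-cell *mean* intensity over each
compartment mask (integrated intensity and area are also recorded). The
background model is a single scalar per channel: the pooled mean probe
intensity over all cell pixels of untreated fields. Corrected intensities
are not clipped at zero, so group means of untreated controls stay centered
at zero. Summaries report n, mean, sample SD (n−1) and SE per condition;
SD and SE are both always emitted because different figures of a study
conventionally use one or the other. Group comparisons use the classic
pooled-variance Student's *t* (one-sided where directionality is claimed);
uptake curves are exact linear interpolations through group means with no
extrapolation.

## Subnuclear enrichment

Per nucleus, an Otsu threshold restricted to that nucleus's marker pixels
defines the compartment mask; objects smaller than `minFocusArea = 3` px²
are removed and nuclei whose compartment area falls below
`minCompartmentArea = 6` px² (or whose marker is degenerate/uniform) are
excluded and counted. The enrichment fold is

> fold = mean(probe | compartment) / mean(probe | remainder)

computed per nucleus on background-corrected intensities and then averaged
across nuclei (the nucleus, not the pixel, is the unit of independence —
reported n counts nuclei). Correction precedes the ratio because ratios of
offset-contaminated intensities are biased toward 1; the corrected fold is
invariant both to multiplicative gain and to additive offsets absorbed by
the background model. Heterochromatin masks run through the same machinery
and serve as the biological null (fold 1).

### Mann–Whitney U

`mannWhitneyU()` reports U for the first sample. With no ties and
`n1·n2 ≤ 400` the p-value comes from the exact null distribution
(`stats::pwilcox` supplies the exact CDF; branch selection and two-sided
doubling are implemented here and verified against full enumeration for all
`n1, n2 ≤ 6`). Otherwise a normal approximation with tie-corrected variance
and a 0.5 continuity correction is used; its exact size at
`n1 = n2 = 50`, α = 0.05 is 0.0495 (computable deterministically from the
exact U distribution), i.e. slightly conservative.

## Gel densitometry

Lanes are detected as peaks of the (lightly smoothed) column-sum profile;
peaks must rise above a noise floor estimated from the low-signal gap
columns, and lanes get equal-width windows centered on their peaks so that
per-lane dilution cancels from any ratio. When fewer peaks than expected
lanes clear the floor — e.g. near-empty control lanes under noise — the
raster is partitioned into equal-width lanes and the result is flagged as a
fallback. Each lane profile (column means per migration row) is integrated
above a baseline estimated as the median of the top and bottom 5% migration
windows, keeping only the positive part. Ladder, no-click, untreated and
vehicle lanes are quantified but excluded from ratios; no-click and
untreated act as negative-signal QC.

Incorporation is computed per replicate pair — ratio first, then averaged —
rather than as a ratio of averages, because per-pair ratios are unbiased
under multiplicative gel-to-gel gain variation. The percentage
`100 · mean ratio` is not capped; values above 100 caused by noise are
flagged rather than truncated. No cross-lane total-protein normalization is
applied by default.

## Numerical choices and degenerate inputs

* Rasters are R-native matrices, 1-based, column-major; pixel centers are
  integer coordinates.
* `otsuThreshold()` uses 256 histogram bins over the data range; constant
  input returns `NA` (callers treat this as "no signal", e.g. a blank DAPI
  field yields zero nuclei, a uniform marker excludes the nucleus).
* Watershed ridge ties are resolved deterministically by `EBImage`.
* Zero pooled variance in the *t* comparison is flagged degenerate with p
  forced to 0/1 by the sign of the difference; a fully tied Mann–Whitney
  comparison returns p = 1.
* Poisson noise at `poissonScale = Inf` is the identity; clipping at zero
  after read noise slightly inflates near-zero backgrounds, which cancels
  in background-corrected group means because the correction is estimated
  from identically clipped untreated fields.
* One global seed is expanded into per-stage substreams by full-precision
  modular hashing, so any stage can be rerun independently yet
  reproducibly, and replicate studies get collision-free streams.

## Validation study sizes

The shipped studies (test suite and `scripts/acceptance.R`) use: enrichment
recovery across true folds {1.0, 1.2, 1.35, 1.4, 2.0} with 50 nuclei per
condition (bias stays below 0.005 at default SNR, well within the ±0.05
acceptance band); a 500-replicate matched null for the Mann–Whitney
comparison at fold 1.0; 2000-replicate type-I calibration of the
normal-approximation branch at n = 30 per group; noise-free 9-cell fields
for segmentation fidelity; 4-replicate gels at 2%-of-peak noise for the
incorporation ratio; and a 5-time-point linear uptake course with ≥50
cells per point. Fields for the replicate-heavy studies are 320×320 px
with 17 cells so a study completes in minutes on one core; these sizes are
the package's validation conditions, chosen once.

```{r studies}
enrichmentRecoveryStudy(seed = 1L)      # bias per true fold
gelRecoveryStudy(trueRatio = 0.49)      # recovered percent of 49
uptakeRecoveryStudy(seed = 1L)$relError # relative rate error
```

## End-to-end runs

`runPipeline()` executes simulate → segment → quantify → enrich → gel from
a single config (list or YAML), persists CSV/JSON/TIFF outputs stamped
with the config hash and seed, and is byte-reproducible given config +
seed. Both subnuclear comparisons whose pairing conventions differ between
studies — compartment vs remainder across nuclei, and per-nucleus folds vs
unity — are emitted so the report layer can choose.

## Known limitations

* 2-D only; no tracking across time points (time courses are independent
  fields, as in the experimental design this mirrors).
* The PM band is geometric; marker-intensity-defined membranes are out of
  scope.
* Enrichment folds assume the remainder mean is positive after correction;
  nuclei violating this are dropped with a diagnostic rather than imputed.
* Lane detection assumes vertically oriented, roughly evenly spaced lanes;
  band-level molecular-weight calling is out of scope.
* No colocalization coefficients; enrichment folds are the only
  subnuclear statistic.
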