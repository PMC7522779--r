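---
title: "Methods: single-cell cytosolic GFP quantification and phosphoproteomics bookkeeping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell cytosolic GFP quantification and phosphoproteomics bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexphos)
```

## Scope

`pexphos` re-implements, as tested and reusable components, the
computational procedures of a study design centred on phosphorylation of
the yeast peroxisomal docking protein Pex14p: (i) quantification of
cytosolic GFP fluorescence in single cells from paired bright-field and
GFP z-stacks, with Welch comparisons between strains; (ii) in-silico
multi-protease phosphoproteomics bookkeeping (digestion, phosphopeptide
masses, neutral-loss offsets, confidence-filtered phosphosite mapping);
and (iii) iBAQ-based normalization of affinity-purified complex
composition. Raw micrographs and spectra of such studies are typically
not deposited, so a first-class synthetic-data module generates
ground-truthed inputs with the same statistical structure, making every
downstream stage testable end to end.

## Imaging branch

### Model of the measurement

A strain's reporter signal is measured per cell. One bright-field slice
(chosen as the best-focused plane) is segmented; each cell's bounding
rectangle is mapped onto the maximum-intensity projection of the GFP
z-stack; and the cytosolic level is summarized per rectangle. Because
peroxisomal puncta are bright and spatially sparse, a *lower* quantile of
the rectangle's intensities reflects the diffuse cytosolic pool rather
than the organellar signal.

### Segmentation

The recipe is: binary threshold, remove objects smaller than 300 px,
morphological closing with a disk of radius 5 px, fill holes, label. The
operator order matters (closing first would rescue sub-threshold
fragments before the area filter) and is applied exactly as listed. Two
points are deliberately configurable because the original description
leaves them open:

* **Threshold method.** Default Otsu on the min-max-normalized histogram,
  which is parameter-free, standard for bimodal bright-field histograms,
  and makes the segmentation invariant under affine intensity changes. A
  fixed threshold is available (`segmentation_params(threshold =
  "fixed")`).
* **Polarity.** Cells are taken as the *dark* phase (dark boundary rings
  and slightly dim interiors on a bright background), with an inversion
  flag.

Rectangles are reported in 0-based, half-open coordinates; exported CSVs
state the convention in a header line.

### False-positive filters and quantification

A rectangle is discarded when either side is > 100 px or < 40 px, when
its GFP crop reaches the saturation value (255 on the 8-bit scale), when
the crop's intensity standard deviation is < 5, or when the rectangle
intersects a border band of 5% of the image size. All removal reasons are
recorded and filtering is idempotent.

For kept cells, the cytosolic surrogate is the 25th percentile of all
crop intensities (linear interpolation). "Lower quantile" is not defined
more precisely in the source description, so the probability is a
parameter (`quant_params(quantile_p = )`) with the lower quartile as
default. The background is the mean of the lowest 10% of the same crop's
intensities — both statistics are scoped to the single-cell crop, not the
whole image — and the reported value is quantile minus background, which
is invariant under a global additive offset and scales linearly with a
global gain.

**Centering.** Per-strain median centering is applied for reporting and
display (`centering = "subtract-median"`, default). The between-strain
Welch test, however, runs on *uncentered* background-corrected values:
centering every strain at its own median would remove exactly the
location difference under test. This resolves, as a package design
choice, an ambiguity in the source description (which mentions both
median centering and a strain comparison).

### Statistics

`welch_t_test()` is the unequal-variance two-sided t-test with
Welch–Satterthwaite degrees of freedom (delegating to `stats::t.test`),
with explicit conventions where `t.test` would fail: both samples
constant and equal gives p = 1; both constant and unequal gives p = 0.
`paired_t_test()` and `summarize_growth()` (sample SD, n − 1 denominator,
as used for error bars) support growth-endpoint comparisons such as OD600
at a fixed time point between strains.

## Synthetic microscopy generator

`generate_image_pair()` emulates the two channels:

* **Bright field**: bright background (default level 200) with each cell
  drawn as a dark boundary ring (drop 120, width 3 px) around an interior
  dimmed by 30. The slight interior dimming keeps the whole cell in the
  dark phase so that thresholding captures full disks rather than annuli;
  boundary-only images are what remain after typical contrast adjustment,
  and the dimming emulates the residual cell-body contrast of real bright
  field. One plane is in focus; the others are Gaussian-blurred copies
  (σ = 1.5 px per plane of defocus), exercising the focus-scoring slice
  selection.
* **GFP**: each cell carries a diffuse cytosolic disk (per-cell level
  drawn around the strain mean, default spread 10%) plus 3 punctate foci
  (Gaussian bumps, σ = 1.8 px, amplitude ≈ 120) each assigned to one z
  plane. The fluorescent footprint extends 2 px beyond the outer edge of
  the bright-field ring: the wall that produces the dark ring lies inside
  the fluorophore-filled volume, so the segmented rectangle is inscribed
  in the fluorescent disk. Without that geometry the rectangle's corner
  fraction exceeds the quantile probability and the lower-quartile
  statistic would systematically dip into background.
* Additive Gaussian noise (σ = 5) per pixel and plane, clipped to
  [0, 255]; 8-bit scale by default so the saturation-removal rule is
  exercised. Cells are placed by rejection sampling with a
  boundary-to-boundary gap larger than the closing-disk diameter, so
  closing cannot merge neighbours; all randomness is fixed by the
  config's seed.

What the generator does *not* emulate: optical point-spread functions,
shot-noise statistics, 3D cell shapes, touching or budding cells, uneven
illumination. Passing tests therefore demonstrate correctness of the
measurement pipeline under the stated model, not robustness to every
artifact of real micrographs (touching cells in particular would require
watershed splitting, which is out of scope).

### Problem sizes used in the checks

Parameter recovery runs 20 seeds of two strains with true cytosolic
levels 30 and 60 (a 2× effect), 60 cells per 1000×1000 field and 3 z
planes, requiring ≥ 50 kept cells per strain, the recovered
median-corrected ratio within 10% of 2, and Welch p < 0.01. Null
calibration runs 200 seeds of two identically configured strains
(level 40, 16 cells per 500×500 field) and checks the rejection rate at
α = 0.05 against [0.01, 0.12]. Segmentation recall uses fields of 20
non-overlapping cells with radii 15–25 px and requires ≥ 90% of
ground-truth centers matched within 3 px. These sizes give stable
statistics from i.i.d. per-cell measurements while each field still
segments in well under a second.

## Phosphoproteomics branch

### Digestion

`digest()` enumerates peptides with 0–4 missed cleavages (every run of
consecutive fully cleaved fragments) and filters by minimum length 6 and
maximum unmodified monoisotopic mass 6,000 Da — the search configuration
appropriate for deep phosphosite coverage of one target protein. Cleavage
dialects are explicit because conventions differ between tools:

* trypsin cleaves after K/R but, by default, not before proline
  (classical rule; the cut-anywhere variant is a flag);
* Lys-C cleaves after K (including K-P);
* Asp-N cleaves before D by default (before D/E as a flag).

The mass ceiling applies to the unmodified peptide (configurable input,
the phosphorylated mass is ~80 Da per site higher); applying it before
modification is the conservative reading.

### Masses and ions

Monoisotopic masses throughout (water 18.010565, proton 1.007276,
phospho +79.96633, H3PO4 97.9769), appropriate for high-resolution
instruments. `peptide_mz()` reports theoretical monoisotopic m/z;
published spectra sometimes label the isotope actually selected for
fragmentation (one 13C above monoisotopic is +0.5 m/z at z = 2), which is
why reported precursor labels can sit half an m/z unit above the
theoretical value computed here. `msa_neutral_loss_offsets()` gives the
per-charge m/z offsets of phosphoric-acid loss (97.9769/z; 98, 49, 32.7
at one decimal, as entered in multistage-activation instrument methods),
and `fragment_ions()` emits b/y series with −H3PO4 variants only for
site-containing fragments.

### Site-table assembly

`filter_and_assemble_sites()` reports a residue as a confident
phosphosite when at least one supporting peptide observation has
PEP < 0.01 *and* a per-site localization probability ≥ 0.95. Each residue
of a multiply phosphorylated peptide is assessed separately, so a single
peptide row can contribute several sites, and the same residue can pass
via one digest while failing via another; the table keeps the best
localization probability per protease. Positions are 1-based protein
coordinates counting the initiator methionine. The filter is monotone in
the threshold (lowering it never removes sites), which the property tests
assert.

## iBAQ complex composition

`normalize_run()` divides each protein's raw iBAQ intensity by the summed
iBAQ of all proteins identified in that replicate and rescales so the
bait equals 100%, making the output invariant to per-run multiplicative
effects. Missing values are treated as "not identified" — excluded from
the run sum — rather than as zeros, since iBAQ absence reflects
non-identification, and entries named in `contaminants` are excluded from
the denominator (whether the original run sums included contaminants is
not documented; excluding them is the default here). Replicates are
aggregated with mean and sample SD (n − 1; for two replicates this is the
"standard deviation across both replicates"), with proteins seen in only
some replicates flagged by their n.

## Numerical and degenerate-input conventions

* Quantiles use linear interpolation (R type 7); the background statistic
  averages the `floor(n × fraction)` (at least 1) smallest values.
* A uniform image segments to an empty region list rather than an error;
  an empty image is an error.
* Welch/paired tests on constant samples return the documented p = 1 /
  p = 0 conventions instead of failing.
* The site filter over an empty evidence table returns an empty table.
* All generators restore the caller's RNG state; identical configs and
  seeds give bit-identical outputs, and the pipeline writes a JSON run
  manifest (parameters, seed, package version) for auditability.

## Known limitations

* Touching or overlapping cells are not split (no watershed); the
  generator never produces them.
* Only rectangle-based intensity statistics are provided, matching the
  quantification being reproduced — no per-organelle (focus) intensities
  or colocalization.
* The phosphoproteomics engine consumes search-engine confidence scores
  (PEP, localization probability); it does not compute them, nor does it
  perform database searching or spectrum scoring.
* iBAQ values are taken as given; computing iBAQ from peptide-level
  intensities is out of scope.
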