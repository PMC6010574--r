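---
title: "Methods: quantifying immunofluorescence expression domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying immunofluorescence expression domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothmap)
```

## The measurement problem

Immunofluorescence photomicrographs of tooth-germ sections carry three kinds
of quantitative information: how much of a structure expresses a factor (the
*expression domain*, the area at or above a baseline intensity), how that
expression is distributed over intensity (the *hotmap* bands), and whether
two stains occupy the same pixels (*co-localization*). All three are
confounded by autofluorescent background, by red/green spectral
bleed-through, and by the 8-bit quantization of the camera. `toothmap`
implements the full chain from raw 8-bit channels to rank-based group
statistics, with every stage testable against a synthetic phantom whose
ground truth is known exactly.

All pixel arithmetic is 8-bit-faithful: values clip to [0, 255] and round
half up, so results are reproducible integer rasters rather than
floating-point approximations of them.

## Background equalization

Autofluorescence raises every pixel by a roughly constant offset. The
classical darkroom remedy is a black-point (dark-point) level move: choose a
dark point $d$ and remap

$$v \mapsto \operatorname{round}\!\left(255 \cdot \frac{\max(0, v-d)}{255-d}\right).$$

`dark_point_adjust()` iterates this at most three times, choosing each pass's
$d$ as the current maximum intensity at *marker points* — positions placed in
structures known to be negative for the stain (cell nuclei for factor
channels, inter-nuclear spaces for the nuclear stain) — and stopping as soon
as every marker reads at or below the target. Residual background within
0–15 intensity units is considered sufficient; 15 is also the banding
baseline, so "background suppressed" and "not part of the expression domain"
coincide.

Two design choices are deliberately conservative:

- the per-pass dark point is capped at `target + 10`. An uncapped pass would
  set $d$ to the worst marker outlier and could clip dim true signal in one
  aggressive move; the cap spreads the correction over passes (hence the
  *triple* adjustment) while the linear remap keeps the intensity *ordering*
  of all pixels intact, which the tests verify exhaustively on crops.
- a marker reading 255 aborts with an error: 255 is a fixed point of the
  remap, so a saturated marker can never be brought below any target and
  indicates a mis-placed marker or a useless exposure.

The remap never increases a pixel and fixes 0 and 255; it does *not* move
the white point. A white-point move would rescale all intensities and change
band membership; it is out of scope here, and the hotmap bands assume the
acquisition's original intensity scale above background.

## Bleed-through correction

Spectral leakage is modeled as linear: a fraction of the clean green signal
appears in the red channel and vice versa. The correction is literal
counter-channel subtraction, `green' = median(clip(green − red, 0))` and
symmetrically, with a 3×3 median filter (configurable radius; the kernel
size is a convention — 3×3 is the smallest window that removes
single-pixel subtraction speckle without eroding compartment-scale
structure). This is *not* scaled spectral unmixing: where both factors are
genuinely present at comparable intensity, subtraction suppresses both.
Consequently co-localization analysis reads the *adjusted but unsubtracted*
channels — after subtraction the two supports are disjoint by construction
and any overlap statistic would be vacuous. The subtraction is antisymmetric
and idempotent once channels are separated, both of which are property
tests.

The median filter is EBImage's constant-time 8-bit median (replicate
borders), verified bit-exact against a brute-force window median in the test
suite.

## Intensity banding, hotmaps and domain size

Thresholding is inclusive: the threshold image at level $t$ is
$\{v \ge t\}$. With the default levels (15, 30, 45, 55, 70, 85, 95), each
consecutive pair of threshold images is merged and the overlap (the pixels
above the higher level) subtracted, producing six *subtraction-product* band
images — exactly the half-open intervals $[t_i, t_{i+1})$ — plus the open
top band $\ge 95$, labeled yellow. The half-open convention is forced by the
subtraction construction itself: the overlap of the two colorized threshold
images is precisely the higher threshold mask, so the remainder is
$[t_i, t_{i+1})$. The seven bands partition the above-baseline domain, and
band areas therefore sum exactly to the domain area — an invariant the tests
check on random images against a brute-force per-pixel oracle.

`domain_size()` reports the domain as a percentage of a supplied ROI
(whole frame, cervical loop, inner enamel epithelium, or any drawn mask —
ROIs are inputs, not auto-segmented). `sample_unit_bands()` repeats the
banding at 5-pixel increments over 15–95, giving 16 bands per image; each
band's ROI-area fraction is one statistical observation ("sample-unit
image"). Magnification is carried as metadata (`pixel_size` in cm) and never
resampled.

## Densitometry

Step-tablet readings (nominal OD vs measured pixel) define a piecewise-linear
monotone map from pixel value to optical density. Linear interpolation was
chosen over splines because it is exact at the knots and cannot overshoot —
monotonicity is a contract, checked over all 256 pixel values. Out-of-range
pixels clamp to the endpoint ODs rather than extrapolate, avoiding negative
or super-range densities. OD is anti-monotone in pixel value (brighter =
less dense).

The bundled `inst/extdata/step_tablet_synthetic.csv` is a *synthetic* ideal
tablet: pixel $= \operatorname{round}(255 \cdot 10^{-\mathrm{OD}})$ over the
nominal 21 steps (0.05–3.05 OD). In 8-bit data the deepest steps collapse
onto the same pixel value, leaving 17 distinct readings — the same
quantization phenomenon that makes fewer than 21 physical measurements
sufficient in practice. `build_calibration()` accepts any ≥ 2 readings with
distinct pixels and rejects anti-monotone pairs.

Plot profiles scan the OD grid vertically (one value per row, positions =
row offset × pixel size, in cm). The per-row reduction is configurable:
`"mean"` (default) tracks overall expression, `"max"` tracks the row's peak
signal, i.e. its *minimum* OD. The default is a choice of convention — any
per-row statistic yields a valid profile; mean is the least sensitive to
single-pixel noise.

## Co-localization

Scatterplots are exact 256×256 joint histograms over ROI pixels. Because
the original analysis read these plots visually, the numerical summary here
is an explicit convention: Pearson correlation over *qualifying* pixels
(either channel ≥ baseline — co-absent background is not co-localization and
must not inflate $r$), plus the overlap fraction (percentage of channel-A
domain pixels that are also ≥ baseline in channel B). Against a nuclear
channel, the pattern is called `nuclear` when $r \ge 0.5$ *and* overlap
≥ 50 %, `non_nuclear` when both fall below, `mixed` otherwise. Both cutoffs
are arbitrary defaults, exposed as arguments and documented as such; the
phantom fixes the truth in tests by painting factor signal either onto or
between the nuclei.

`serial_coloc()` reproduces the serial-threshold merger: the reference
channel at baseline against the probe at rising levels (default 15, 30, 45,
55 — the first four hotmap levels, since the four probe levels are otherwise
unspecified). Overlap masks are nested by construction, and the series is
flagged *baseline-only* when the baseline overlap exceeds the next level's
by a factor of 2 (configurable) — the signature of co-localization confined
to the 15–30 band, as residual bleed-through produces.

## Rank statistics

Sample-unit fractions are compared across (stage, ROI) groups with the
tie-corrected Kruskal–Wallis statistic

$$H = \frac{\frac{12}{N(N+1)} \sum_i n_i \bar r_i^2 - 3(N+1)}
           {1 - \sum_j (t_j^3 - t_j)/(N^3 - N)},$$

with $p$ from the $\chi^2$ upper tail at $k-1$ df, followed by Dunn's
pairwise

$$z_{ij} = \frac{\bar r_i - \bar r_j}
  {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_j(t_j^3-t_j)}{12(N-1)}\right)
  \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}$$

with two-sided normal $p$-values, Bonferroni-adjusted by default (the
documented behavior of the commercial implementation this mirrors; Holm and
unadjusted are available). Fully constant data yields $H = 0$, $p = 1$
rather than an error. Both statistics are implemented from the formulas; the
test suite verifies them to $10^{-10}$ against a direct-from-definition
recomputation with manually counted mid-ranks, and cross-checks $H$ and $p$
against `stats::kruskal.test`. The $\chi^2$ approximation is used at all
sample sizes; for groups under ~5 observations it is only approximate (no
exact permutation option). Simulated type-I error at nominal 0.05 (two
groups of 50, 2000 replicates) is required to land in [0.035, 0.065].

One caveat is inherited from the design: each sample-unit image counts as an
independent observation, although the 16 units of one photomicrograph share
the same section. `compare_domains()` records this pseudo-replication caveat
on its report.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds, per seed:

1. parametric compartment masks — an enamel-organ ellipse enclosing a
   papilla, the epithelium as their difference, an inner-enamel-epithelium
   band along the interface and two cervical-loop disks at the lateral
   margins, with stage-dependent proportions (`bud`, `cap`, `bell_cl`,
   `bell_iee`). The masks are pairwise disjoint and tile the frame; only the
   topology matters for testing, not anatomical fidelity;
2. clean factor rasters: per-compartment mean intensity plus a linear
   gradient (direction and peak-to-peak span configurable); defaults put a
   graded green domain in the epithelium, strongest in the cervical loops
   and inner enamel epithelium, and red in the papilla — mirroring the
   epithelial/mesenchymal split the real stains show;
3. DAPI-like nuclei: radius-2 disks at uniform positions over tissue, ~200
   intensity, at 6 nuclei per 1000 px² of tissue (a dense embryonic
   epithelium has nuclei covering on the order of 10 % of the area);
4. observed channels:
   `clip(clean + leakage × clean_counterchannel + background + noise)`,
   with defaults background 25, Gaussian noise SD 3 (the background regime
   the dark-point stage is designed to suppress to ≤ 15), and leakage 0.15
   (green→red) / 0.10 (red→green);
5. ground truth: domain fractions from the *clean* rasters at threshold 15
   (the pipeline's baseline, making truth and measurement commensurable),
   per channel and compartment, plus channel-pair co-localization fractions.

The default frame is 192×144 px (tests use 96×80) — a scaled-down stand-in
for full 1360×1024 acquisitions; all operations are resolution-agnostic, and
the sizes keep the complete suite and the acceptance script within seconds
to a couple of minutes on one CPU.

The negative control (`negative_control_phantom()`) zeroes the factor
signal, keeping background, noise, nuclei and a faint (0.05×) nuclear bleed
into the factor channels — emulating staining with primary antibodies
omitted.

What the phantom does *not* model: point-spread optics, staining texture
(flat vs spiky profiles), uneven illumination, section-to-section thickness
variation, and cellular-scale morphology. Passing the ground-truth-recovery
tests therefore demonstrates that the *pipeline arithmetic* is correct under
additive background, noise and linear bleed-through — not that the
procedure is robust to every artifact of real histology.

## Numerical conventions

- clip-to-[0,255] and round-half-up everywhere (R's `round()` rounds half
  to even and is not used on pixel data);
- thresholds inclusive at the level; bands half-open;
- ties in ranks take mid-ranks; the tie correction reduces to 1 with no
  ties (tested);
- calibration interpolation exact at knots; clamped outside;
- all randomness (phantom noise, nuclei, marker sampling) flows from
  explicit integer seeds; the pipeline splits its root seed as
  `seed + 1000·stage_index + replicate`, and `run_study()` writes a manifest
  of md5 checksums that an identical rerun reproduces exactly.

## Known limitations

- Counter-channel subtraction is not spectral unmixing; genuinely
  co-expressed pixels lose signal in both channels. The co-localization
  module therefore works on unsubtracted (level-adjusted) channels.
- The nuclear/non-nuclear cutoffs (r ≥ 0.5, overlap ≥ 50 %) are
  conventions, not estimated quantities.
- The χ² approximation for H and the normal approximation for Dunn's z are
  asymptotic; with the default 16 sample units per group they are adequate,
  for much smaller groups they are not exact.
- ROI masks are supplied by the user (or derived from phantom ground
  truth); no automatic anatomical segmentation is attempted.
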