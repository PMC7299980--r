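---
title: "Quantifying enhancement intensity and kinetics on CESM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enhancement intensity and kinetics on CESM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesmr)
```

## The measurement model

Contrast-enhanced spectral mammography (CESM) produces, for each breast, a
pair of iodine subtraction images in the two standard projections (CC and
MLO). Because the projections are exposed minutes apart after a single
contrast injection, the pair is a crude two-point sample of the lesion's
enhancement kinetics. `cesmr` quantifies that signal in two steps.

**Enhancement intensity.** For one projection, with a lesion ROI and a
background ROI drawn on the subtraction image,

$$\mathrm{CNR} = \frac{S_a - S_b}{S_b},$$

where $S_a$ is the *maximum* pixel value inside the lesion ROI and $S_b$
the *mean* pixel value of the background ROI. Using the lesion maximum
rather than its mean makes the index robust to intra-lesional
heterogeneity. Two conventions are fixed in `measure_roi()`:

* a negative raw ratio is clamped to zero. Positivity is defined as
  "stronger than background", so a darker-than-background ROI is
  non-enhancement, not negative enhancement;
* a view counts as enhancing only when CNR exceeds the detection
  threshold *strictly* (`detect_enhancement()`, default threshold 0). The
  threshold is configurable because "stronger than background" has no
  canonical numeric definition.

Masks must be pixel-aligned logical matrices and must not overlap; an
overlap is rejected rather than silently resolved, since a pixel claimed
by both ROIs has no defensible interpretation.

**Kinetics.** The two measurements of one lesion are ordered by
acquisition time — never by view name, since either CC or MLO may be
exposed first — giving $\mathrm{CNR}_1$ (former projection) and
$\mathrm{CNR}_2$ (latter). The relative signal difference

$$\mathrm{RSD} = \frac{\mathrm{CNR}_2 - \mathrm{CNR}_1}{\mathrm{CNR}_1}
\times 100\%$$

classifies each lesion into four patterns (`classify_pattern()`):
*ascending* (RSD > +10%), *steady* (|RSD| ≤ 10%, boundary inclusive),
*descending* (RSD < −10%), and *none* (both projections non-enhanced,
scored as RSD = 0). The ±10% band is a configurable constant.

Two degenerate cases needed decisions the formula does not make:

* $\mathrm{CNR}_1 = 0 < \mathrm{CNR}_2$: the ratio is undefined.
  Enhancement that appears over time is a rise, so the lesion is
  classified ascending, with RSD stored at a +100% cap and the row
  flagged (`one_view_enhancement`) so such lesions are auditable.
* $\mathrm{CNR}_2 = 0 < \mathrm{CNR}_1$ needs no special case: the
  formula gives −100%, descending.

A subtlety worth knowing: swapping the projections maps ascending to
descending and vice versa *except* in a narrow band near the threshold,
because RSD's denominator is the former value. A +10.5% rise reversed is
a −9.5% fall; the pair reads ascending one way and steady the other.
This is a property of the published ratio definition, not of the
implementation, and the test suite checks antisymmetry only outside that
band.

## The synthetic cohort generator

No per-lesion data are published for this kind of study; cohorts are
summarised as five order statistics (min, quartiles, max) per group and
projection, plus counts of non-enhancing lesions. The generator is built
around exactly that information, so its defaults *are* the published
study conditions: 102 benign, 17 non-infiltrating and 26 infiltrating
lesions.

**Distribution family.** Each group/projection is a `quantile_spec`: a
zero-inflated distribution whose continuous component has the
piecewise-linear quantile function through the five summary points at
probabilities (0, .25, .5, .75, 1). Any family matching five quantiles is
a modelling choice; this one reproduces the printed quantiles of the
continuous component *by construction*, adds no distributional
assumptions, and is trivially exact to test. Note that for the benign
group the printed 25th percentile is itself zero, so the continuous
component carries a 25% atom at zero in addition to the explicit
zero-inflation (`zero_prob` = 48/102 benign, 1/43 malignant, the observed
non-enhancement fractions). The mixture's total zero mass therefore
exceeds either number alone — the unavoidable price of calibrating both
the zero count and the marginal quantiles to published marginal
summaries without per-lesion data.

**Within-lesion coupling.** No joint
$(\mathrm{CNR}_1, \mathrm{CNR}_2)$ data are published for such cohorts. The two views' latent uniforms
are coupled by a mixture copula: with probability `dependence` the views
share one uniform (comonotone), otherwise they are independent. The
blend weight is the Spearman correlation, up to Monte-Carlo error.
The default `dependence = 0.8` encodes that the same lesion imaged
minutes apart should rank similarly within its group while leaving
enough independent variation to populate all three enhanced patterns,
as the published pattern tables require. Zero-inflation is drawn once
per lesion and applied to both views — a non-enhancing lesion is
non-enhancing in both projections.

**Labels.** Receptor status (ER/PR/HER-2) is drawn for malignant lesions
at the published known-rate and positive-rate proportions, *independently
of CNR*; the generator makes no attempt to encode the receptor–intensity
associations, so receptor contrasts on synthetic cohorts are null
experiments. Benign subtypes are multinomial at the published mix
(fibroadenoma 53/102, adenosis 33/102, papilloma 8/102, other 8/102).
LE-image detectability is Bernoulli conditional on pathology class and
enhancement, with rates read off the published detection cross-tab, so
the synthetic cross-tab matches the published one in expectation. A
random subset of 28 lesions receives a DCE-MRI TIC label drawn from a
per-pattern assignment table (`default_tic_table()`) calibrated so the
expected CESM–MRI coincidence is roughly two thirds (moderate
agreement); the exact published kappa is not forced because the full
4×4 cross-modality table is not published.

**Phantoms.** `render_phantom_pair()` renders each view as a constant
background (default 1000 intensity units) plus a radially symmetric
quartic blob whose peak amplitude is `target_cnr * background_mean`,
plus Gaussian noise (default sd 1). In the noiseless limit the lesion
maximum and background mean are analytic, so measured CNR equals the
target exactly; images are kept real-valued in memory and quantised only
when written to 16-bit TIFF, which keeps the noiseless identity exact
and file round-trips within ±0.05 percentage points. With the default
noise, measured CNRs stay within ±0.3 percentage points of target
(the tolerance the phantom tests assert). Phantoms deliberately model
no parenchyma texture, breast compression, or dual-energy recombination
physics: they validate the *measurement arithmetic*, not radiological
realism, and passing phantom tests says nothing about segmentation or
acquisition effects in clinical images.

## Statistical conventions

All published analyses are reproduced with explicit, fixed conventions
wherever the original software's defaults are unrecoverable:

* descriptive percentiles: linear interpolation between closest ranks
  (R type 7);
* group tests: Wilcoxon signed-rank (paired; zero differences dropped),
  Mann–Whitney U, Kruskal–Wallis, all two-sided at α = 0.05; completely
  degenerate inputs return p = 1 with a warning rather than NaN;
* Bonferroni adjustment multiplies by the comparison count and caps at
  1, so hopeless pairwise contrasts print exactly p = 1;
* ROC: empirical curve over midpoint thresholds with "positive = score
  strictly above cut-off"; AUC equals the Mann–Whitney identity
  $U/(n_1 n_0)$ with tied pairs counted ½; the 95% CI is a Wald interval
  on the DeLong variance, truncated to [0, 1]; among Youden-optimal
  cut-offs the smallest is chosen, favouring sensitivity, the natural
  posture for a screening adjunct;
* paired AUC comparison: DeLong structural components with a normal z
  test; a zero standard error with a nonzero difference reports p = 0
  with a warning;
* contingency: chi-square without continuity correction, switching to
  Fisher's exact test for 2×2 tables with any expected count of 5 or
  fewer; zero-margin rows/columns are dropped with a warning;
* agreement: Cohen's kappa on the 4×4 pattern-vs-TIC table, with CESM
  patterns mapped onto the TIC axis (ascending↔persistent,
  steady↔plateau, descending↔washout, none↔none).

## Problem sizes and what the tests show

The validation suite works at sizes chosen to make Monte-Carlo error
negligible while keeping a full run interactive: sampler calibration is
checked at $n = 10^5$ draws against a 3-standard-error band (asymptotic
quantile SE with the steeper adjacent quantile-function slope as the
conservative density reciprocal), and the diagnostic direction is
checked on 200 independent 145-lesion cohorts, where the
replicate-median AUC of the former projection falls inside the published
confidence interval and above the latter projection's. These checks
validate calibration and direction; they cannot — and do not claim to —
reproduce the study's exact AUCs, sensitivities or kappa, which depend
on the unpublished per-lesion data.

## Known limitations

* Two timepoints only; the design has no notion of multi-phase kinetics.
* ROIs are inputs. There is no segmentation; clinical use would inherit
  whatever inter-reader ROI variability the drawing protocol allows.
* The generator reproduces marginal summaries and expected rates, not
  the unpublished joint structure of real lesions; estimates that depend
  on that joint structure (exact kappa, exact AUC) vary across synthetic
  replicates.
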