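---
title: "Methods: chemotype classification and quantitation of wild hops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotype classification and quantitation of wild hops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopchem)
```

## The model

Hop subspecies identity is read off chemistry. `hopchem` implements two
classification rules and the quantitation chain that feeds them.

**Cone rule.** Native North American ssp. *lupuloides* cones contain both
xanthogalenol (XGA) and 4'-*O*-methylxanthohumol (MXH); European ssp.
*lupulus* cones contain neither. `classify_cone()` calls *lupuloides* when
both markers exceed a presence threshold, *lupulus* when neither does, and
*atypical* when exactly one does. The surveyed collection contains no
single-marker cones, so the rule is deliberately not extrapolated to them.
The default presence threshold (0.001 % dw) corresponds to the lowest
calibration level: a concentration floor rather than a detector floor, so
noise-level integration artifacts cannot flip a call. It is overridable.

**Leaf rule.** The proportion of malonylated flavonol glycosides among
total leaf flavonols is bimodal across the collection: below 0.10 in
*lupuloides*, above 0.20 in *lupulus*. `classify_leaf()` returns
*indeterminate* inside [0.10, 0.20]; the published chemotypes never fall
there, and the convention of refusing to call the gray zone is this
package's, not the survey's. `concordance()` counts only accessions where
both rules produce a subspecies call.

**Traits.** `cone_profile()` and `leaf_profile()` derive the standard
quantities: total prenylchalcones (XHU + DXH + XGA + MXH), total alpha
acids (COH + n+ADH), cohumulone proportion COH/Σα, total beta acids
(COL + n+ADL), alpha ratio Pα = Σα/(Σα+Σβ), total flavonols, and the
malonyl proportion (Qmal + Kmal)/Σflavonols. Ratios with zero denominators
are undefined (NA), never zero. Replicates aggregate as mean ± SE
(n−1 denominator, SE undefined at n = 1); group summaries are unweighted
means over accessions, which is how the published class averages reproduce
from per-accession values.

## Quantitation

Chromatograms are quantified channel-wise: 370 nm for prenylchalcones
(xanthohumol equivalents), 320 nm for bitter acids (ICE-3 standard),
350 nm for flavonols (quercetin-3-*O*-rutinoside equivalents). Equivalents
quantitation means compounds sharing a channel share a response factor, so
abundance ratios equal area ratios.

Peak detection finds local maxima of a lightly smoothed trace above a
height threshold (default 5 mAU over the trace median) with topographic
prominence of at least 3 mAU. Windows run valley to valley, clipped to
±0.15 min around the apex so isolated peaks on long flat stretches keep
tight windows.

Integration is trapezoidal with a linear baseline. For partially resolved
clusters the baseline is anchored at the *cluster* edges and peaks are
split at the valley (drop-line integration): anchoring a linear baseline
at an elevated valley would cut a wedge out of every peak in the cluster,
a 15–20% error for the flavonol region, while the drop-line keeps
noiseless recovery within 1%. Baseline anchors average a five-sample
neighbourhood to suppress single-sample noise.

Calibration is unweighted ordinary least squares, `area = m·conc + b`,
over seven geometrically spaced levels spanning 0.001–0.5 mg/ml in three
independent series, matching the published design and its r² > 0.999
contract. Bitter acids instead use single-point response factors from the
ICE-3 reference extract (defined w/w composition 13.88% cohumulone, 30.76%
n+adhumulone, 13.44% colupulone, 10.84% n+adlupulone), which passes
through the origin by construction. Concentrations convert to percent dry
weight via the extraction record (cones: 0.5 g into 50 ml pooled; leaves:
200 mg into 10 ml). The cone extract is read neat at 370 nm but at a
4-fold dilution at 320 nm, so the abundant bitter acids and the trace
markers both fall inside the calibrated range. Areas implying
concentrations above the calibrated range are an error (dilute and
re-run); below the lowest calibrant they are reported with a flag rather
than censored, because trace-level marker detection matters for
classification.

**Co-elution.** Kaempferol-3-*O*-rutinoside (4.18 min) and
quercetin-malonyl-glucoside (4.20 min) are closer than a peak width and
are quantified as one flagged joint peak — deconvolution is out of scope.
`apportion_coeluting()` then estimates the quercetin malonyl ester from
the well-resolved kaempferol analogue divided by the
kaempferol:quercetin malonyl ratio (default 5, the observed leaf
abundance ratio) and assigns the remainder to the rutinoside. This is a
flagged heuristic: exact when the configured ratio holds (as in the
generator), approximate on real leaves where the ratio varies.

## The synthetic generator

`generate_panel()` draws per-accession ground truth for a two-class panel
(default 19 *lupuloides* + 11 *lupulus*, the surveyed composition). Each
trait is truncated normal with the class mean and the printed class range;
the location parameter is re-centred (closed-form truncated-normal mean)
so the distribution mean equals the class mean despite asymmetric
truncation. Quantities the survey does not print are fixed modelling
choices: xanthohumol takes 72% of the non-marker prenylchalcone pool (XHU
is the dominant prenylchalcone, DXH second); the colupulone share of beta
acids equals the sampled cohumulone share of alpha acids (co-analogs draw
on the same branched acyl precursor pool); non-malonyl leaf flavonols
split 40/25/15/20 across Qrut/Qglc/Krut/Kglc; total leaf flavonols spans
the published 0.28–2.77 % dw range with a 1.2 % dw mean in both classes.

Replicate noise is multiplicative log-normal with CV 5% (mean-corrected),
which reproduces the order of the printed standard errors (2–10% of trait
means); the survey states no within-replicate variance model, so the CV is
a flagged configuration choice. Chromatograms are sums of Gaussian peaks
(σ = 0.02 min, i.e. ~2.8 s FWHM, typical of sub-2-µm UPLC) on a 2 mAU
baseline with white noise (default 0.2 mAU), sampled at 20 Hz over 8 min;
each peak's true area is response factor × concentration, and every random
stream derives from (seed, accession, tissue, replicate), so all
generators are pure functions of their arguments. The peak width is
deliberately narrower than first sketched (0.03 min): at 0.03 min the
4.20/4.30 min flavonol pair overlaps enough that the 1% noiseless
round-trip contract cannot hold without deconvolution.

Calibration response noise is proportional with 0.5% RSD, the
injection-precision class of modern UPLC autosamplers and consistent with
r² > 0.999 over 2.5 orders of magnitude.

What the generator does *not* emulate: retention-time drift, peak
tailing, detector saturation, matrix interferences, MS spectra, and
between-year or developmental variation in absolute flavonol levels.
Passing round-trip tests therefore demonstrate that the integration,
calibration and classification machinery is correct under the stated
forward model — not that the method is robust to real-instrument
artifacts it does not model.

## Numerical choices and degenerate inputs

- Trait sampling: rejection sampling against the truncated range;
  `uniroot` re-centring to the target mean (tolerance 1e-10).
- Windows sharing one boundary sample are treated as disjoint; the shared
  trapezoid panel has zero width.
- `quantify()` clips negative implied concentrations to zero; 0/0 trait
  ratios are NA and excluded from group means.
- Classification thresholds are strict inequalities on the stated sides:
  a marker exactly at the presence threshold counts as absent, and a
  malonyl proportion exactly at 0.10 or 0.20 is indeterminate, matching
  the published "< 0.10" / "> 0.20" bands.
- Annotation ties break by absorbance-maximum proximity, then retention
  time, then candidate id, making rankings deterministic and
  permutation-invariant. Relative abundances are carried but never
  scored: they are matrix- and tune-dependent.
- The [M−CO₂]⁻ fragment printed for malonyl esters is modelled as the
  deprotonated molecule minus neutral CO₂ (a constant 43.9898 Da loss);
  the printed notation omits the hydrogen but the numeric values fit this
  interpretation within unit resolution (0.5 Da), which is also the
  default match tolerance of the tandem-quadrupole class instrument.

## Known limitations

- Quantitation at or below the lowest calibrant is limited by the
  unweighted-OLS intercept, whose scatter is set by the top calibration
  levels (~0.1–0.2% of the top-calibrant response). Trace analytes there
  carry a systematic uncertainty of order 10% that replicate averaging
  cannot remove; weighted (1/x²) calibration would fix this but the
  package matches the published unweighted design.
- One published secondary ion (the kaempferol-rutinoside aglycone
  fragment at m/z 287.7) deviates 0.65 Da from protonated kaempferol
  (287.055) and is treated as an observed-value outlier; all twelve
  base-peak ions fit within unit resolution.
- Class averages recomputed from rounded printed rows can differ from the
  published averages in the last digit (the originals were computed on
  unrounded data); one accession's alpha ratio sits exactly on a 0.005
  rounding boundary.

## Problem sizes

The default study is the surveyed size: 30 accessions × 3 replicates × 3
channels (270 chromatograms of 9601 points), which runs in a few seconds;
distributional checks of the generator use panels of 800. These sizes are
the package's defaults for its own validation study.
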