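---
title: "Models and methods: quantifying primate face stimuli and their rated attractiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying primate face stimuli and their rated attractiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primface)
```

## The problem

When people score photographs of primate faces for "beauty" on a 1–7 Likert
scale, what drives the scores? Candidate cues fall into three families:
**morphology** (proportions of inner facial features — eyes, nose, mouth —
versus outer ones — face outline, hair), **colour and pattern** of the facial
fur, and **human-likeness**, which connects the question to the uncanny-valley
literature. `primface` implements the full quantitative chain needed to ask
this question: quantifying stimuli, summarising landmarks, measuring rater
agreement, and modelling species-level attractiveness. A synthetic-data module
generates images, landmarks and rating matrices with controlled structure, so
every stage runs — and is tested — without any external download. The same
pipeline runs unchanged on user-supplied photographs, landmark files and
rating CSVs.

## Colour quantification

Stimuli are RGBA rasters whose background has been cut out (alpha = 0); only
opaque pixels enter any statistic. Each pixel is converted to HSL and
classified by a fixed precedence:

1. **excluded** if alpha < 0.5 (the threshold only matters for anti-aliased
   edges; synthetic stimuli are binary);
2. **black** if $L < 0.20$; **white** if $L > 0.71$; **gray** if $S < 0.15$;
3. otherwise by hue bin: red $[350°, 360°) \cup [0°, 18°)$ (reddish brown in
   primate fur), orange $[18°, 45°)$, yellow $[45°, 75°)$ (yellowish brown),
   bluish tint $[170°, 270°)$, all half-open with the lower bound included;
4. **unclassified** for the remaining hues ($[75°,170°) \cup [270°,350°)$).

The achromatic gates come first because the bin definitions overlap (a very
dark red pixel is both "red" and "black"); separating achromatic content
before hue assignment is the convention of colour-quantification tools in this
literature and is applied uniformly. Keeping an explicit *unclassified* class
rather than dropping those pixels preserves the partition property — every
opaque pixel is counted exactly once — which the tests exploit. Fractions are
arcsine-square-root transformed (`transform_fraction`) before they enter
linear models. Mean lightness and saturation are averaged over *all* opaque
pixels, including achromatic ones (no exclusion rule is applied). An optional
mask removes user-specified regions (e.g. the truly blue facial parts of a
mandrill when one wants the bluish *tint* only); fractions are renormalised
over the remaining pixels, and this renormalisation is a package decision that
is documented rather than configurable.

**Pattern.** The fur-pattern score is the fraction of eligible pixels whose
Sobel lightness-gradient magnitude (normalised by 4, so a unit lightness step
scores 1) exceeds a threshold, default 0.1 on the $[0,1]$ lightness scale. A
pixel is eligible only if its full 3×3 neighbourhood is opaque, so the face
outline against the transparent background never counts. High scores
correspond to fine, agouti-like fur speckling. Two caveats are deliberate
documentation: the score depends on pixel *arrangement* (unlike the colour
fractions, which depend only on the pixel multiset), and the 3×3 Sobel kernel
is blind to a 1-pixel checkerboard — the Nyquist pattern cancels exactly — so
the finest alternation it can report is at a 2-pixel scale. Operator and
threshold are configurable; only ordinal properties of the score are asserted
anywhere.

## Morphometry

Nineteen named landmarks (top of head A, face sides B/C, chin D, eye corners
E1/E2/G1/G2, reference-cross centre F, nose sides H/I and tip J, mouth ends
K/M and midpoint L, hair tips N/O1/O2, beard tip P) are converted to 14
traditional distance traits (face height A–D, width B–C, forehead A–F, eye
size as the mean eye width, nose length F–I, nose width H–J, mouth width K–M,
side/top hair, beard, interocular E2–G2, eyes-to-mouth F–L, philtrum I–L,
chin L–D). The nose pairings follow the printed trait definitions even though
H–I would be the geometrically natural width; `nose_convention = "geometric"`
switches to F–J/H–I. Traits are used raw, in pixels — the stimuli are assumed
size-standardised — with rigid-motion invariance and scaling equivariance
property-tested.

Traits are summarised by **maximum-likelihood factor analysis** with varimax
rotation under Kaiser row normalisation (`stats::factanal`), on standardised
traits, with regression factor scores. Two conventions make output
reproducible: factors are reported in extraction order and each factor is
oriented so its largest-|loading| trait loads positively. In data like these,
one factor collects the outer facial features and one the inner ones.
Heywood cases are floored (uniqueness ≥ 0.001) and flagged. ML factoring of
14 traits needs clearly more species than traits; panels too small for it
fall back to a PCA-based summary with the same fields, with a warning
(`method = "pca"` on the result).

**Group structure.** Canonical variate analysis is computed from the
eigenstructure of $W^{-1}B$, with $W$ the unbiased pooled within-group
covariance (divisor $n-g$) and $B$ the size-weighted between-group covariance
(divisor $g-1$). Axes are scaled to unit within-group variance; items are
reassigned to the nearest group centroid, and a leave-one-out variant refits
without each item. The implementation is checked against an independent
whitening-route eigensolve. A ridge ($\lambda \cdot \overline{\mathrm{diag}
(W)}$) is available for singular $W$. PCA defaults to the correlation matrix
because the traits have heterogeneous scales.

## Rater agreement

The agreement statistic is the two-way **consistency ICC** with stimuli as
objects and raters as judges (this orientation fixes $k$ in the
Spearman–Brown relation and is therefore stated, not implied): from the
two-way ANOVA without interaction,
$\mathrm{ICC}_{single} = (MS_{rows} - MS_{err}) / (MS_{rows} + (k-1)
MS_{err})$ and $\mathrm{ICC}_{avg} = (MS_{rows} - MS_{err}) / MS_{rows}$.
The average measure equals the Spearman–Brown step-up
$k\,s/(1 + (k-1)s)$ of the single measure algebraically, which is
property-tested to $10^{-10}$ and anchors the package's reproduction of the
printed agreement figures (e.g. a single-measure consistency of 0.182 among
286 raters steps up to 0.985).

Gender differences per stimulus use a two-sided Mann–Whitney U with tie and
continuity corrections (exact enumeration only when both groups have ≤ 8
raters and no ties), with Bonferroni correction by the number of stimuli
tested. MANOVA with Wilks' Λ covers demographic effects; because a
raters × stimuli response with more stimuli than raters leaves a singular
error matrix, responses are first reduced by PCA retaining 95% of variance
(logged with a warning) — the reduction step itself is an assumption, flagged
as such. Nested variance components (group ⊃ genus ⊃ species ⊃ individual)
use method-of-moments estimates from the sequential nested ANOVA — not REML —
because the balanced synthetic designs used in testing make the closed-form
estimator adequate and transparent; negative solutions are truncated at zero
and flagged. Spearman correlation screens use the tie-tolerant t
approximation and report degenerate (constant) inputs as flagged NAs rather
than errors.

## Species-level models

- **LG dimorphism ratio**: (larger-sex mass / smaller-sex mass) − 1, negative
  when males are larger.
- **Linear models**: least squares with treatment contrasts (catarrhine
  reference for the group factor), *sequential* (Type I) ANOVA in formula
  order, Gaussian AIC. Backward reduction repeatedly drops the term whose
  removal lowers AIC most, but refuses any drop that makes a likelihood-ratio
  test of the candidate against the *original full model* significant at
  0.05; the elimination trace is part of the result. The retained term set is
  data-dependent by design — the procedure, not a particular final model, is
  the contract.
- **Tukey HSD** (Tukey–Kramer for unbalanced groups) compares group means on
  the inverted display scale (8 − score, so higher = more attractive;
  inversion is display-only, models use raw means).
- **RDA**: fitted through vegan. The default response is the species × raters
  score matrix; species × gender-means is available
  (`rda_response = "gender_means"`). This choice matters for the headline
  "% variance constrained": with raw rater columns the explainable share is
  bounded by the between-species share of variance (roughly the single-
  measure ICC), so the same covariates yield a much smaller percentage than
  they would on aggregated responses. Sequential ("Type I") term tests
  permute residuals of the reduced model with $p = (\mathrm{exceed}+1)/
  (n_{perm}+1)$, seeded. Forward model building enters, at each step, the
  candidate with the smallest sequential permutation p (ties by constrained-
  variance gain), stopping when none reaches α; an AIC analogue
  ($n \log(RSS/n) + 2\,\mathrm{npar}$) is tracked as an advisory criterion
  and its agreement reported. Note that forward selection at entry level α
  admits one inert term with probability ≈ $1-(1-\alpha)^m$ at the stopping
  step; the tested guarantee is that active terms enter, and enter first.
- **LOWESS** (tricube weights, 3 robustness iterations, span 2/3) draws the
  attractiveness vs human-likeness curve for the catarrhines — the
  uncanny-valley diagnostic.

## The synthetic-data generator

The generator emulates the study conditions: 107 species (50 catarrhines, 24
platyrrhines, 33 prosimians), 286 beauty raters (about 32% men, ages 15–69),
60 human-likeness raters, all rating all stimuli.

**Panel.** Each group has a hand-built 19-landmark template whose trait
differences (eye size, nose length, hair lengths, face proportions) are tens
of pixels. Species-level variation adds jitter (SD 8 px) and a size scale
(±15%) — large enough that within-group morphological spread is realistic
(species within an infraorder differ substantially, and the inner-features
factor must carry within-group signal for the models to have anything to
find), yet small enough that CVA still reassigns ≥ 95% of species to their
group leave-one-out. Colour weights are Dirichlet draws with group-specific
concentrations (reddish catarrhines, yellow-orange platyrrhines, dark/gray
prosimians with high pattern levels); LG ratios are truncated normals per
group spanning about [−1.4, 0.31]; true human-likeness is uniform per group
(catarrhines most human-like).

**Stimuli.** A face is an opaque axis-aligned ellipse on a transparent
background; geometric realism is deliberately out of scope since the
quantification code only sees pixels. Opaque pixels are ordered by angle and
partitioned into contiguous colour sectors with *exact* integer counts
(largest-remainder apportionment), so colour recovery is exact, not
approximate — the round trip `color_profile(render_stimulus(spec))` is tested
as identity. Pattern is a parity lightness texture on a `pattern_level`
fraction of pixels, with both lightness variants kept inside the pixel's own
class gates so texture never moves a pixel between classes.

**Ratings.** The latent score of rater $r$ for species $s$ is
$\mathrm{lp}(s) + b_r + \varepsilon_{rs}$ with $b_r \sim N(0,
\mathrm{rater\_sd}^2)$, standardised by its total SD and discretised through
fixed global cutpoints (default: 7 equal-probability categories of the
standard normal) — per-rater cutpoints were considered and rejected as
unnecessary for the target regimes. The survey's true latent model is
unknown; this linear-latent + cutpoint model is an assumption and is flagged
as such. Discretisation attenuates a latent correlation $r$ to
$\sum_{i,j}\int_0^r \phi_2(c_i, c_j; t)\,dt \,/\, \sigma^2_{cat}$ (about
$0.92 r$ at small $r$ for 7 equal categories); `target_single_icc=` inverts
this curve numerically so the *observed* single-measure ICC of the discrete
scores hits the requested value. The default beauty regime targets 0.18
(which steps up to ≈ 0.985 across 286 raters) and human-likeness targets
0.553; the calibration is exact for Gaussian species effects, and the
strongly trimodal human-likeness distribution makes its realized agreement
run slightly above target, which stays within the intended "excellent"
regime. A configurable subset of species (default 5) receives an additive
male-rater offset (default −1), which is what the Mann–Whitney screen's power
is tested against.

The default beauty signal mirrors the direction and rough magnitude of the
reported species-level effects: positive weights on raw human-likeness and
pattern, negative on LG and bluish tint, an inner-features factor effect,
plus a latent "taste" component that no model covariate observes (keeping
reduced-model $r^2$ in a realistic 25–55% band rather than near 1). The
direct prosimian offset (−1.0 on the latent scale) is larger in magnitude
than the human-likeness-mediated penalty prosimians carry, so the default
study reproduces the qualitative finding that prosimians come out most
attractive overall. What the generator does **not** emulate: photographic
lighting and pose variation, fur rendering, phylogenetic covariance between
species, rater-specific responses styles beyond an additive intercept.
Passing tests therefore validate the *estimators and pipeline plumbing*, not
the field realism of any particular dataset.

## Numerical and design choices

- Single master seed; every stage seed is derived from it (all below
  $2^{31}$), so full runs are byte-reproducible (`run_study` twice on the
  same config writes identical CSVs).
- Colour classes partition opaque pixels exactly; fractions sum to 1 within
  $10^{-9}$ and are checked against a brute-force per-pixel loop.
- CVA clamps tiny negative eigenvalues at 0; the ridge default is off and an
  informative error suggests it for singular $W$.
- `reduce_aic` requires a strict AIC decrease to accept a drop and never
  applies a drop that the LRT-vs-full rejects; the log-likelihood decreases
  monotonically along the trace (tested).
- Exported CSVs round floats at 6 significant digits; the JSON report keeps
  full precision and round-trips.
- Desk-scale problem sizes in the test suite (e.g. 200 null replicates with
  199 permutations for size calibration, 20 replicates for the end-to-end
  recovery check, a 24-species pipeline fixture) are the package's choice of
  smallest sizes at which the asserted statistical properties are
  well-powered.

## Known limitations

- The pattern score is operator- and threshold-dependent; cross-study
  comparability requires fixing both. Only ordinal claims are tested.
- Consistency ICC is the only implemented agreement form (no absolute
  agreement, no Kendall's W).
- No phylogenetic correction: species are treated as independent, as in the
  modelled analyses.
- The MANOVA response-reduction step and the rating latent model are
  assumptions, documented above.
- Colour covariates of flat synthetic stimuli are nearly collinear with mean
  lightness/saturation by construction; real photographs decouple these.
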