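---
title: "The RMRS model: triangular areal similarity for metabolic syndrome severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RMRS model: triangular areal similarity for metabolic syndrome severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmrs)
```

## The problem

Metabolic syndrome (MetS) is diagnosed dichotomously: a subject is positive
when at least three of five risk factors — fasting glucose, blood pressure,
triglycerides, HDL-cholesterol and waist circumference — exceed their
AHA/NHLBI cutpoints. The binary rule discards severity information: a
subject with three factors barely over their cutpoints receives the same
label as one with five factors far beyond them, and a subject with all five
factors just *under* their cutpoints is called healthy. Continuous
alternatives built from cohort statistics (z-score composites and the like)
inherit the cohort: their scale, and any threshold tuned on them, changes
with the sample. The RMRS (Robust MetS Risk Score) is a continuous severity
score in $[0,1]$ whose scale and diagnostic cutoff are fixed by
construction, not estimated from data.

## Scaling the axes

Each factor $f$ with raw value $x_f$ and cutpoint $d_f$ is first normalized
so the cutpoint sits at zero and 10% of the cutpoint is one unit:

$$Z_f = \frac{x_f - d_f}{0.1\,d_f},$$

with the sign flipped for HDL (low HDL is the risk) and, for blood
pressure, the larger of the systolic and diastolic cutpoint exceedances
divided by a common unit, 10% of the gap between the two BP cutpoints
(4.5 mmHg at the default 130/85). The normalized value is then passed
through the Elliot sigmoid

$$S_f = \frac{0.5\,Z_f}{1 + |Z_f|} + 0.5,$$

a bounded, strictly monotone map onto $(0,1)$ that fixes three anchors:
the cutpoint maps to $0.5$ and one unit below/above to $0.25$/$0.75$. It is
most sensitive near the cutpoint, where diagnostic uncertainty lives, and
compresses outliers instead of letting them dominate. Analytic boundary
configurations use the closed interval $[0,1]$, admitting $0$ and $1$ as
limit values the sigmoid itself never reaches.

```{r anchors}
elliot_sigmoid(c(-1, 0, 1))
```

## Triads and the TAS score

Plotting three scaled factors on a radar chart with axes $120^\circ$ apart
gives a triangle whose area,

$$\mathrm{area}(x_1,x_2,x_3) = \tfrac{1}{2}\sin(\tfrac{\pi}{3})\,(x_1x_2 + x_2x_3 + x_3x_1),$$

does not depend on the order of the axes. The five factors yield
$\binom{5}{3} = 10$ such triads; because diagnosis requires *any* three
abnormal factors, each triad is a potential diagnostic route, and scoring
all ten captures co-occurrence structure no single chart can.

Each triad is scored by comparing four triangles: the *threshold* triangle
(all radii $0.5$, area $C_\alpha$), the *maximum* triangle (all radii $1$;
its excess over the threshold triangle is $C_\beta = 3C_\alpha$), and the
*internal*/*external* measurement triangles through the clipped
($x_i' = \min(x_i, 0.5)$) and raw scaled values. Writing
$X = x_1x_2 + x_2x_3 + x_3x_1$ and $X'$ for its clipped analogue (the
areas with the common factor $\tfrac12\sin(\pi/3)$ divided out), the
triangular areal similarity is

$$\mathrm{TAS} = \tfrac12\left(\underbrace{\frac{X}{0.75 + X - X'}}_{\text{closeness}} \;+\; \underbrace{I \cdot \tfrac{4}{9}(X - X')}_{\text{severity}}\right),$$

where the indicator $I$ is 1 exactly when all three factors reach their
cutpoints. Before onset, area beyond the threshold can only *dilute*
closeness; after onset it is credited directly as severity, relative to its
capacity $C_\beta$. TAS is the average of the two components: the averaged
form is the one that reproduces every published boundary value (0.387,
0.707, 0.547 and the per-count range endpoints), and the package applies it
consistently, also in the interaction reformulation below. The indicator is
implemented as `all(x >= 0.5)` rather than an equality test on the clipped
area, which would be fragile in floating point.

## RMRS and the fixed cutoff

$$\mathrm{RMRS} = \sqrt{\tfrac{1}{10}\textstyle\sum_{i=1}^{10}\mathrm{TAS}_i} \in [0,1].$$

The square root spreads the lower range; permutation invariance is
inherited from the triads. A factor beyond its cutpoint contributes excess
area in the six triads it joins, so multi-factor severity compounds
structurally rather than through fitted weights.

The count-based rule draws its line at three abnormal factors, but the
three-factor RMRS range overlaps the two-factor range. The fixed cutoff is
the midpoint of that overlap: the minimal three-factor score
(three factors exactly at their cutpoints, the rest at the scale minimum)
and the supremum of the two-factor score (two factors maximal, three
approaching the cutpoint from below):

```{r threshold}
derive_diagnostic_threshold()
```

The supremum is a limit; it is evaluated at $\varepsilon = 10^{-9}$ below
$0.5$, far below the $10^{-3}$ resolution at which scores are reported, and
reported values are rounded half-away-from-zero to 3 decimals to match the
published precision. The cutoff depends only on the score's structure —
the same 0.547 applies to every cohort. (One figure caption in the source
literature prints 0.574; the derivation yields 0.547 and the midpoint
construction confirms it, so 0.547 is used.)

Theoretical RMRS ranges by abnormal-factor count $k$ follow from the same
boundary configurations: $[0, 0.707]$ for $k \le 1$, $[0.224, 0.707]$,
$[0.387, 0.742]$, $[0.548, 0.837]$ and $[0.707, 1]$ for $k = 2..5$.

## The interaction view

Substituting $x_i = 0.5 + \alpha_i$ decomposes TAS into interaction masses:
a reference $I_T = 0.75$, a non-negative part $I_P$ collecting the
deviations at or above the cutpoint (with their pairwise products), and a
non-positive part $I_N$ from those below:

$$\mathrm{TAS} = \tfrac12\left(\frac{I_T + I_P + I_N}{I_T + I_P} + I\cdot\tfrac49 I_P\right),$$

with the split determined by how many deviations are non-negative (four
cases, 0 through 3). The identity $X = I_T + I_P + I_N$ and
$X - X' = I_P$ makes this algebraically exact, and the package uses it as a
second, independent computation route: `tas_decompose()` +
`tas_from_interactions()` agree with `tas_score()` to machine precision,
which the test suite checks on random and boundary inputs. The published
case formulas assume the non-negative deviations are listed first, so the
deviations are sorted before the formulas apply; TAS is symmetric, so
nothing is lost. $I_N$ acts purely as a penalty: an excess beyond some
cutpoints can be offset by a deficit below others — the mechanism by which
a near-threshold-everywhere subject can outscore one barely past three
cutpoints. The strict bound $|\alpha_i| < 0.5$ printed with the
decomposition excludes the boundary $\alpha_i = 0.5$ that the limit
configurations themselves use; the package accepts the closed bound.

## Risk-factor counting

Counting stays in raw measurement space with the published inequality
directions: $\ge$ for glucose, BP, triglycerides and waist, strict $<$ for
HDL. A subject with HDL exactly at its cutpoint is therefore *normal* on
that factor even though its scaled axis sits at $0.5$; the scaled space is
never consulted for counting. Waist and HDL cutpoints resolve from
(region, sex); absent region defaults to Korean with a warning.

## The synthetic cohort generator

No generative model is published, so the generator is the package's own
design, chosen as the minimal structure able to mimic the published
marginal moments and induce realistic co-occurrence: a Gaussian copula with
per-sex marginal means and standard deviations taken from the large Korean
reference cohort (American alternatives included), triglycerides given a
moment-matched lognormal marginal (its sd approaches its mean, so the
distribution is strongly right-skewed), and a fixed correlation matrix —
systolic/diastolic 0.7, moderate positive links among glucose,
triglycerides, waist and BP, negative links to HDL. The source tables
report no inter-factor correlations; the matrix is a stated assumption, not
an estimate. Measurements are clamped to plausible positive ranges
(e.g. waist 40–200 cm) to keep normalized deviations finite, and rows with
systolic $\le$ diastolic are resampled. The default male fraction is
0.307, the reference cohort's.

What passing tests on these cohorts show is that the pipeline is correct
and its metrics behave (per-count means rise with the count, AUC against
the count diagnosis is high); they do not reproduce any published
cohort-dependent statistic, since those depend on real populations the
generator does not claim to match jointly. A second generator,
`simulate_scaled_vectors()`, samples directly in scaled space with an exact
abnormal-factor count (uniform on $[0.5,1]$ / $[0,0.5)$ per component) to
probe the theoretical per-count ranges; containment runs use 10,000 draws
per count, other property suites a few hundred to a few thousand draws —
sizes at which every check is stable and the whole suite runs in well under
a minute.

## Evaluation conventions

The published evaluation machinery is reimplemented with its conventions
made explicit, since the source does not state them: AUC is the rank-based
Mann–Whitney statistic with tied pairs counting one half; classification is
positive at or *above* the cutoff (the fixed cutoff is inclusive by its
midpoint construction); Youden's $J$ is maximized over midpoints of
adjacent distinct scores plus sentinels beyond both ends, ties resolved
toward the lower cutpoint; adjusted $R^2$ comes from the simple linear
regression of score on count. Subgroups with a single diagnostic class
report `NA` metrics rather than failing.

## Limitations

* The ten triads are equally weighted and the per-factor unit is fixed at
  10% of the cutpoint; both are structural choices, not clinically tuned.
* The score inherits the cutpoints' step-free view of risk between
  factors: no factor interactions beyond pairwise products within triads.
* Synthetic cohorts match marginals and a plausible dependence, not any
  real population's joint distribution; prevalence and metric values on
  them are illustrative only.
* Comparator scores (cMetS, ASD, siMS, MetSSS) are out of scope; the
  evaluation tools accept any numeric score column, so they can be
  compared externally.
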