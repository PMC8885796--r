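---
title: "Scoring spatial TIL patterns on whole-slide annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring spatial TIL patterns on whole-slide annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilpatterns)
```

## The assessment model

Tumor-infiltrating lymphocytes (TILs) in invasive breast cancer are
conventionally scored as a single number — the fraction of stromal tissue
occupied by lymphocytes. This package implements a *spatial* refinement of
that score on annotated whole-slide images. Three compartments are built
from the pathologist's region annotations:

* **TC (tumor center)** — the annotated tumor area more than one band-width
  away from the tumor boundary;
* **IM (invasive margin)** — the band of the tumor area within `im_width`
  (default 500 µm) of the tumor boundary, lying entirely *inside* the
  annotated boundary so that TC and IM tile the tumor area exactly;
* **Para (para-tumor lobular area)** — a separately annotated region of
  adjacent lobular tissue, clipped to exclude the tumor.

Confounder regions (necrosis, tertiary lymphoid structures, intermixed
normal tissue) are subtracted from all three compartments before any area
is measured, and cells inside them never contribute to scores.

The scoring unit per compartment is the **lymphatic-nucleus-area ratio**:
the summed nucleus area of stromal lymphocytes (plasma cells included)
divided by the stromal area of the compartment. Measuring nuclei rather
than whole cells makes the quantity robust to cytoplasm segmentation; a
single linear calibration connects it back to the conventional stromal-TIL
percentage. The calibration is pinned at the lymphocyte-predominant breast
cancer (LPBC) threshold — a nucleus-area ratio of 0.20 in the TC
corresponds to 50% stromal TILs — giving

$$\text{sTIL\%} = 250 \times r_{\text{nuc}},$$

equivalently a global nucleus-to-whole-cell area ratio of 0.4. The factor
is applied globally and logged; it is not asserted per cell.

## The five-pattern classification

The ratio triple $(r_{TC}, r_{IM}, r_{Para})$ is classified by a fixed
decision tree with inclusive cut-offs 0.20 / 0.10 / 0.20:

1. $r_{TC} \ge 0.20$ — lymphocyte-predominant ("hot") tumor:
   **IP1** if $r_{Para} \ge 0.20$ (hot para as well), else **IP2**;
2. otherwise $r_{IM} \ge 0.10$ — margin-restricted infiltration: **IP3**;
3. otherwise $r_{Para} \ge 0.20$ — cold tumor with hot para: **IP4**;
4. otherwise **IP5** — cold everywhere.

Merged prognostic groups are IP1/2, IP3/4 and IP5.

```{r}
classify_ip(c(0.25, 0.25, 0.05, 0.02, 0.01),
            c(0.30, 0.30, 0.15, 0.03, 0.02),
            c(0.25, 0.05, 0.05, 0.30, 0.01))
```

Three classifier conventions were genuinely open and are fixed as follows,
with the reasoning:

* **Inclusive cut-offs.** Whether a case exactly at a threshold is high or
  low is not specified by the clinical definition; we include the boundary
  (`>=`) so the LPBC calibration point 0.20 itself is LPBC. The cut-offs
  are configurable (`ip_cutoffs()`, YAML keys `cut_tc`, `cut_im`,
  `cut_para`).
* **IP3 ignores the para ratio.** The decision order places the IM test
  before the Para test for non-LPBC cases, so an IM-high/Para-high case is
  IP3, not IP4. This keeps the tree a strict hierarchy (TC evidence
  strongest, then IM, then Para) and matches IP4's description as a
  *low-TIL* high-PIL pattern. Users can audit such cases through the
  returned ratios.
* **TC-high/IM-low discordance.** High TC infiltration with a quiet margin
  is biologically implausible (margin infiltration precedes central
  infiltration) and absent from the cohorts that motivated the scheme.
  Such cases remain classifiable (the LPBC branch wins) but carry a
  `tc_im_discordant` flag.

## Geometry: how the compartments are built

Regions are polygons in micrometre coordinates (image convention, origin
top-left). The TC is the inward offset (morphological erosion) of the
tumor polygon by `im_width`, computed with the Clipper polygon engine; the
IM is the set difference tumor ∖ TC, so the partition
$\,\mathrm{area}(TC) + \mathrm{area}(IM) = \mathrm{area}(\text{tumor} \setminus \text{exclusions})$
holds by construction (`partition_check()` verifies it to < 0.1%
relative). A tumor narrower than twice the band width has an empty TC;
this is legal and flagged, not an error.

Cells are assigned by centroid point-in-polygon with the priority
EXCLUDED > IM > TC > PARA > OUTSIDE. Boundary points count as inside,
and the priority order resolves points on shared boundaries, so repeated
runs are deterministic. Stromal area is either `stromal_fraction ×
compartment area` (the manual two-pathologist assessment surrogate) or
computed from explicit stroma polygons when provided; with neither, the
fraction defaults to 1 with a warning.

Numerical notes: the inward offset uses round joins (arc-approximated
erosion, exact for convex corners — an axis-aligned square erodes to the
exact inner square); areas are signed shoelace sums over the clipper
output, so holes subtract correctly; the self-intersection check is an
O(n²) segment test, appropriate for annotation rings of ≲ a few hundred
vertices.

## Statistics

The cohort statistics mirror the conventions of the clinical software this
field reports with (SPSS): Pearson chi-square without continuity
correction, a linear-by-linear (N−1)r² trend test, two-sided Fisher exact
p-values, Kruskal–Wallis with tie correction, and a Mann–Whitney U test
reported as a tie-corrected normal z without continuity correction. All
tests are two-sided and p-values are reported raw; `holm_adjust()` is
available (off by default) for reuse across many pairwise comparisons.

Survival uses Kaplan–Meier product-limit estimates (median = first time
with $S(t) \le 0.5$) and the weighted log-rank family with weights 1
(log-rank/Mantel–Cox), $n_i$ (Breslow/generalized Wilcoxon) and
$\sqrt{n_i}$ (Tarone–Ware) at each event time — the Breslow and
Tarone–Ware members are computed from the risk tables directly because the
standard G-rho family does not contain them. Cox regression uses the
partial likelihood with Breslow tie handling; its score test at β = 0
equals the log-rank statistic for a two-group factor, which the test suite
checks to 1e-6. The cohort follow-up summary is the plain median/IQR of
observed times regardless of event status; a reverse Kaplan–Meier
alternative is exposed via `median_followup(reverse_km = TRUE)` since the
field does not standardize this summary.

## The synthetic cohort generator

`simulate_slide()` and `simulate_cohort()` generate data with the
statistical structure the analysis assumes, so every pipeline stage is
testable without patient material. What is emulated:

* **Geometry** — a smooth star-shaped tumor blob (2–8 mm diameter, low-order
  harmonic boundary), a 1 mm para-tumor band with 3–10 lobules, 0–3
  exclusion discs.
* **Cells** — homogeneous Poisson point patterns per compartment. The
  intensity is $\lambda = r^\ast / \bar A$ where $r^\ast$ is a ratio target
  drawn from the pattern's configured interval and $\bar A = 30$ µm² the
  mean nucleus area (log-normal, CV 0.3 — a typical lymphocyte nucleus
  scale; exposed in the configuration since no distribution is dictated by
  the assessment itself). Cells are flagged stromal with probability equal
  to the stromal fraction, which makes the expected stromal ratio equal
  $\lambda \bar A$ independent of the fraction. Marker mixes are T-cell
  skewed in tumor compartments and B-cell skewed in the para, matching the
  direction of the reported subpopulation differences.
* **Covariates** — pattern-conditional probabilities for lobular
  involvement, cancerous embolus, late clinical stage, molecular subtype,
  grade and PD-L1 positivity default to the published per-pattern
  proportions.
* **Survival** — Weibull disease-free survival (shape 1.2, mild aging) with
  per-(merged pattern × subtype) scales set through hazard ratios that
  encode the published qualitative orderings: in luminal B the cold
  pattern IP5 fares best (HR 2.5 for IP3/4), in TNBC the
  lymphocyte-predominant group fares best (HR 0.4 for IP1/2). Censoring is
  uniform on [36, 120] months, mimicking a roughly three-year accrual
  window with bounded follow-up.

What is *not* emulated — and what passing tests therefore do not show
about real slides: nucleus segmentation error, spatial clustering of
lymphocytes (hotspots), within-slide stromal heterogeneity, annotation
disagreement between pathologists, and any correlation between ratio
targets and covariates beyond the pattern label. The generator validates
that each pattern's target-ratio intervals are consistent with the
classifier cut-offs at construction time; the default intervals keep at
least 0.02 clearance from every cut-off so that Poisson fluctuation
(relative error $\approx 1/\sqrt{N}$ on tens of thousands of cells) cannot
flip a label.

The per-patient cohort table shipped in `inst/extdata` reconstructs a
579-case clinicopathological table from published marginal counts and
per-pattern cross-tabulations; entries the publication does not pin down
are filled with neutral deterministic values and enumerated by
`table1_fixture_notes()`. No joint structure beyond the published tables
should be read into it.

## Problem sizes used by the checks

The automated checks run at sizes chosen to make Monte-Carlo error
negligible relative to the tolerances while keeping the suite quick on a
laptop: the classifier sweep uses a 0.01-step grid over [0, 0.5]³ (132,651
triples); the geometry oracle uses 360-gon circles, an exact square, and
100 random blobs; the round-trip study uses 200 virtual slides (40 per
pattern) at the default 2–8 mm diameters; the survival operating
characteristics use 100 cohorts of 300 luminal-B cases for power and 500
null replicates of 200 cases for the type-I error.

## Known limitations

* The erosion-based band is measured inside the annotated tumor boundary.
  Workflows that define the invasive margin as a band straddling the
  boundary (partly outside the tumor) need their annotations re-expressed
  before import.
* Fisher tests on large sparse r×c tables fall back to seeded Monte-Carlo
  (10⁵ tables) when exact network evaluation is infeasible.
* PD-L1 immune-cell percentages are treated as an opaque pathologist
  input; whether the underlying score is area- or count-based is outside
  the package's scope.
* The classification is purely categorical; no continuous immune score is
  derived beyond the calibrated stromal-TIL percentage.
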