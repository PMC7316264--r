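---
title: "Methods: from ROI time series to a significant subnetwork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ROI time series to a significant subnetwork}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `restconn`, the
numerical choices made where the design was genuinely open, what the
synthetic cohort generator does and does not emulate, and the known limits
of what a green test establishes.

## The analysis model

The unit of analysis is a subject-by-timepoint ROI×ROI **functional
connectivity matrix**: Fisher-z transformed Pearson correlations,
`z = atanh(r)`, between cleaned BOLD series. The Fisher transform
variance-stabilizes correlations so that group-level linear models on
matrix cells are defensible. The cleaning cascade is, in order:

1. `discard_initial(k = 5)` — drop pre-stabilization volumes;
2. `regress_nuisance()` — OLS residuals against an intercept plus the
   white-matter and CSF average signals;
3. `detrend_poly(order = 2)` — remove a per-ROI quadratic in the volume
   index (thermal drift);
4. `bandpass(0.01, 0.1)` — retain the canonical resting-state frequency
   band.

The order follows the narrative of standard connectome-mapping pipelines
(nuisance before detrending before filtering) but is configurable
(`preproc_config(steps = ...)`) because published descriptions rarely pin
it; each step is idempotent, so the order matters little in practice for
well-behaved data.

**Mixed matrices.** Path-based graph metrics are not computed on raw
correlation matrices — correlations are statistical dependence, not
information routes. Instead a **consensus structural backbone** is built
from the individual binary structural connectomes of *both groups pooled*:
a connection survives if present in at least 50% of subjects (the
threshold is inclusive: 13 of 26 passes). Pooling guarantees a single
template, so group differences in structural connectivity cannot bias the
functional comparison. Each functional matrix is gated cell-wise by this
mask to yield the subject/timepoint-specific *mixed* matrix.

**Network measures.** For a named node set (default VAN, 19 ROIs; DAN, 6
ROIs):

* *connectivity strength* — mean Fisher-z over the member-pair upper
  triangle of the **full** functional matrix; connections to outside nodes
  are excluded by construction, and negative z values are averaged as-is
  (strength is defined on signed correlations);
* *global efficiency* — mean inverse shortest-path length over ordered
  member pairs of the member-induced subgraph of the **mixed** matrix;
* *local efficiency* — per node, the cube-root-weighted efficiency among
  its neighbors with interneighbor paths restricted to the
  neighborhood-induced subgraph, averaged (unweighted) over member nodes.

Edge lengths are reciprocal weights, `d = 1/w`. Nonpositive (and masked)
weights carry no path: negative correlations have no defensible
interpretation as routing capacity, so they are excluded from efficiency
(but kept in strength). Both conventions are flagged config points in the
code; the subgraph (rather than whole-graph-restricted) variant is the one
implemented, since the scientific question is posed *within* each network.

**Statistics.** Every upper-triangle edge (or network metric) is analyzed
with a classical mixed 2×2 ANOVA — between-subject factor Group, within-
subject factor Timepoint. With exactly two within-subject levels the design
collapses to two independent strata:

* Group: pooled-variance two-sample t on per-subject means, F = t²,
  df (1, N−2);
* Timepoint: t on the unweighted average of the two groups' mean change
  scores (Type III, so the 14/12 imbalance does not contaminate the main
  effect);
* Group×Timepoint: pooled-variance two-sample t comparing change scores
  between groups, F = t², df (1, N−2).

This reproduces the textbook mixed-ANOVA F statistics exactly (verified
against R's `aov()` least-squares decomposition on balanced designs) and
yields the df (1, 24) appropriate to a 14+12 cohort. Interaction p-values
are corrected with Benjamini–Hochberg across the full 8256-edge family by
default; restricting the family to backbone edges is available as an
option because real pipelines differ on this point. Flagged edges are
assembled into connected components, and uncorrected two-tailed post-hoc
t-tests (paired within each group, pooled-variance unpaired at each
timepoint) are attached, mirroring common reporting practice.

Degenerate inputs follow explicit conventions: an all-equal cell gives
F = 0, p = 1 (the 0/0 case), while a nonzero effect with zero residual
variance gives F = ∞, p = 0; the functional-matrix diagonal is 0 by
convention, and r is clipped at ±(1−10⁻⁷) before `atanh`.

## The synthetic cohort: what it emulates

`generate_cohort()` produces the stated world of a two-group (14/12),
two-timepoint resting-state study: 129 ROIs, 242 volumes at TR = 2 s.
Defaults:

| parameter | default | meaning |
|---|---|---|
| `base_within_r` | 0.35 | correlation inside a community |
| `base_between_r` | 0.05 | correlation across communities |
| `delta_z` | −0.4 | planted Fisher-z interaction shift |
| `nuisance_amplitude` | 0.3 | shared WM/CSF-like signal, fraction of BOLD s.d. |
| `drift_order` | 2 | per-ROI polynomial scanner drift |
| `structural_flip_rate` | 0.05 | per-cell noise on the structural backbone |

Group sizes, ROI count, volume count and TR are the study design being
emulated; Δz = −0.4 is the planted intervention effect on the scale the
analysis operates on. Community structure (eight lobe-by-hemisphere
modules) gives the base covariance a realistic modular profile; the exact
base correlations are not calibrated to any dataset (none is available)
and were fixed once at values typical of parcellated resting-state data.
The nuisance and drift amplitudes only need to be large enough that a
pipeline which skipped cleaning would visibly fail; they are removed
exactly by the regression/detrending steps, so they do not govern power.

Targets are built per design cell on the Fisher-z scale (so downstream
z statistics see an additive shift) and mapped back with `tanh`. If a
planted configuration breaks positive definiteness, the matrix is repaired
by eigenvalue clipping at 10⁻⁶ followed by re-normalization to unit
diagonal — the simplest reproducible projection; generation *stops* if the
repair would move any non-planted cell by ≥ 0.01, so leakage of the effect
into untouched cells is bounded by construction. With the default 11-edge
effect the repair moves non-planted cells by about 2×10⁻³.

Not emulated: image space (no voxels, no registration), hemodynamics, head
motion, scan-to-scan trait stability of connectivity, and heavy-tailed
physiological noise. A green recovery test therefore establishes that the
*pipeline arithmetic* recovers planted effects at the stated noise level —
not that the method would behave identically on real BOLD data.

## Power of the recovery experiment: an information bound

The recovery experiment plants Δz = −0.4 on 11 edges and asks the scan to
flag them all. After band-passing to 0.01–0.1 Hz, a 237-volume scan at
TR = 2 s contains about 0.09 Hz × 474 s ≈ 85 independent samples, so the
per-scan Fisher-z standard error is ≈ 1/√82 ≈ 0.11 — an *information
bound* set by scan duration and bandwidth, not by any generator dial. The
group contrast on change scores then has SE ≈ 0.11·√2·√(1/14+1/12) ≈
0.061, i.e. an interaction noncentrality of ≈ 6.6, while flagging ~11 of
8256 edges at BH q = 0.05 requires |t(24)| ≳ 5. Each planted edge is
therefore missed with probability ≈ 0.1, the median recovered count is
10–11, and *all* 11 edges are recovered in only ≈ 30% of cohorts; a ≥ 90%
all-11 rate would need |Δz| ≈ 0.5 or ≈ 370 retained volumes. The
acceptance test that asserts the 90% rate is left failing deliberately,
with this analysis as the explanation; the companion checks (median
recovery, FDR control under the null, df, boundary behavior) pass.

## Numerical choices

* **Filter.** Zero-phase filtering is implemented as a DFT mask (exact
  gain 1 in [f_lo, f_hi], 0 outside, DC removed) rather than a Butterworth
  forward-backward pass: no filter-design package is required, the
  contract (≥ 90% mid-band retention, ≤ 10% at 0.002/0.2 Hz) is met
  exactly, and the operation is perfectly reproducible. The trade-off is
  rectangular spectral truncation (mild ringing for strongly non-stationary
  series), irrelevant for correlation estimation on stationary series.
* **Shortest paths** use `igraph`'s Dijkstra; the test suite proves
  equality with exhaustive simple-path enumeration on all ≤ 4-node weighted
  graphs (4⁶ weightings of {0, 0.25, 0.5, 1}) and on 1000 sampled 5-node
  weightings — the full 5-node space (4¹⁰ ≈ 10⁶ graphs) is sampled, not
  enumerated, to stay inside the test-time budget.
* **BH-FDR** delegates to `stats::p.adjust(method = "BH")`, verified
  against a hand-executed step-up in the tests; ties and the inclusive
  boundary (single p = 0.04 at q = 0.05 rejected) behave per the step-up
  definition.
* **Seeds.** All randomness derives from one master seed through a
  fixed-offset scheme (`seed*2048 + offset`, kept below 2³¹), making every
  bundle byte-reproducible; subject, backbone and structural draws use
  disjoint offsets.

## Known limitations

* The ANOVA engine is specific to the 2×2 mixed design (the design of
  interest); it does not generalize to more levels or covariates.
* Efficiencies assume nonnegative weights after masking; heavily negative
  matrices yield sparse usable graphs and efficiencies near 0.
* The consensus backbone binarizes weighted structural input at > 0; no
  minimum-streamline-count rule is applied (upstream tractography filters
  are out of scope).
* No permutation/cluster-based (NBS-style) component inference — only the
  FDR mode is implemented.
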