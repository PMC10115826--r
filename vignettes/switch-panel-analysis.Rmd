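---
title: "Methods: quantifying orthogonality and logic in Cas-responsive switch panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying orthogonality and logic in Cas-responsive switch panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocircuit)
```

## Scope and model

`orthocircuit` analyses panels of Cas-responsive translational switches:
reporter mRNAs whose translation a cognate Cas protein (the *trigger*)
represses (OFF switch) or activates (ON switch). The measured object is
always a two-channel fluorescence readout per cell or image region — a
*reporter* channel carrying the regulated signal and a co-delivered
*reference* channel marking transfected cells — and every quantity the
package computes is a function of per-cell reporter/reference ratios.
Effects are treated as steady-state multiplicative factors on reporter
expression; no attempt is made to model mRNA kinetics, decay pathways or
dose–response, which is why a planted "ground truth" can be expressed as
a single trigger × switch matrix of positive factors.

## The synthetic event generator

Because raw per-cell cytometry tables for such screens are rarely
deposited, the generator is a first-class module: it produces event
tables from a planted effect matrix so that gating, normalization,
orthogonality screening and gate scoring can all be validated against
known truth.

The fluorescence model is log-normal throughout, the standard choice for
flow-cytometry intensities and the one under which median-ratio
statistics behave cleanly:

* transfected cells draw reference intensity from
  `10^N(ref_mean_log10, ref_sd_log10)` (default 10^4 a.u., 0.3 dex);
* their reporter intensity is `basal × effect × (reference / 10^ref_mean_log10)
  × 10^N(0, noise_sd_log10)` — proportional to the reference (co-delivery),
  scaled by the switch's basal level and the planted effect, with
  multiplicative noise (default 0.0212 dex ≈ 5%);
* untransfected cells and debris draw autofluorescence in both channels
  (default 10^2 a.u., 0.2 dex), two decades below the transfected
  population, so a mock-derived reference gate separates them cleanly;
* debris additionally has low forward/side scatter; a fixed fraction of
  intact-cell events is clamped to a channel limit to emulate edge
  events.

Default composition is 70% transfection, 5% debris and 1% edge clamps.
Counts are rounded rather than binomially drawn, so gating bookkeeping
has exact targets; all randomness lives in the channel draws. Each
sample's random stream is seeded by a 32-bit FNV-1a hash of
`(master seed, sample_id)`, which makes samples byte-reproducible and —
more importantly — *extension-stable*: adding triggers, switches or
replicates to a screen never changes the draws of existing samples. The
per-switch basal variation (0.1 dex around 2000 a.u.) is sub-seeded per
switch id for the same reason.

What the generator does **not** emulate: spectral spillover and
compensation, instrument drift between replicates, correlated
transfection of multiple plasmids, non-log-normal autofluorescence
tails, or saturating dose–response. Passing the recovery tests therefore
shows the *analysis chain* is correct and unbiased under a clean
multiplicative model — not that any particular wet-lab panel will behave
this way.

## Gating

The three gates mirror how cytometry operators work but are fully
deterministic:

1. **Debris**: keep events with `fsc ≥ fsc_min` and `ssc ≥ ssc_min`
   (defaults 3×10^4 and 1.2×10^4 a.u., between the simulated debris and
   intact-cell scatter modes).
2. **Edge**: drop events whose reporter or reference equals a channel
   limit exactly — only saturation clamps can produce exact equality on
   a continuous scale.
3. **Reference-positive**: keep events whose reference strictly exceeds
   the 99.9th percentile (type-7 quantile) of a mock, untransfected
   sample's reference channel. The mock passes through the debris and
   edge gates first, since its own debris and clamped events would
   otherwise inflate the percentile.

The order is fixed (debris, edge, reference), removal counts are
conserved, and gating only changes membership, never channel values, so
it is idempotent. The 99.9th percentile and the rectangular debris
bounds are conventions, recorded in every gating report; there is no
attempt to reproduce hand-drawn polygonal gates.

## Normalization chain

Per sample, `NI = 1000 × median(reporter/reference)` over surviving
cells; the even-count median is the mean of the two central order
statistics. The ×1000 factor is applied exactly once, in NI — it cancels
in every downstream ratio and exists only to put typical values in a
readable range. `RI = NI(trigger+)/NI(trigger−)` cancels switch-intrinsic
basal expression; dividing by the No-gRNA control's RI cancels
switch-independent burdens of trigger expression, and maps the control
itself to exactly 1. The imaging chain (DV → RV → normalized fold
change, and NFI against a stated control condition) is the same algebra
on image-region medians, with inputs assumed background-subtracted
upstream.

Zero or non-positive denominators raise classed errors rather than
propagating `Inf`/`NaN`: a degenerate sample should fail loudly at the
stage that produced it. Replicate spread is reported as mean ± sample SD
(n−1); with a single replicate the SD is reported as absent rather than
0. Both RI-level and fold-change-level replicate summaries are exposed,
since either can be the quantity of interest.

## Orthogonality statistic and subset search

Profiles are centered by subtracting 1 — the fold change of "no effect" —
so that two triggers sharing no targets have orthogonal (zero-dot)
centered profiles. The pair distance is `1 − cosine similarity` of the
centered profiles: ~1 means orthogonal behaviour, ~0 identical crosstalk
patterns, and values up to 2 are possible when deviations oppose
(repression vs activation of the same switch). A trigger whose centered
profile is the zero vector within the switch scope has no defined
direction; this raises an error rather than silently scoring. A
combination's orthogonality is its *minimum* pairwise distance — the
weakest link — and combinations below 0.7 are flagged as crosstalking;
the flag is inclusive at the boundary.

One genuine design choice is whether a combination C restricts profiles
to the switches matched to C (notation-faithful to the conditional
FC(i|C); requires a square, matched panel) or uses full profiles. Both
modes are provided; `"restricted"` is the default and neither is
asserted to be the only defensible reading. The choice matters
computationally: in full mode pair distances are subset-independent, so
the optimal size-N subset is a maximum max–min diversity problem that
can be solved exactly by binary search over the sorted unique pairwise
distances with a maximum-clique feasibility test (via `igraph`) on the
graph keeping edges at or above the candidate threshold; the
lexicographically smallest N-clique at the optimal threshold is then
recovered by depth-first extension, so the optimized search returns the
*identical* subset as exhaustive enumeration under the tie rule. In
restricted mode distances change with C and no subset-independent bound
is available, so the sweep enumerates subsets exhaustively, pruning each
as soon as its running pair minimum falls to the incumbent optimum.
Ties everywhere resolve to the lexicographically smallest sorted index
set, making all searches deterministic.

A second deliberate choice: OFF-switch entries enter the matrix as raw
normalized fold changes (< 1 on target) by default. An
`orient_off_reciprocal` flag re-orients them as reciprocals; the cosine
geometry differs between the two conventions, and both are exposed.

## Circuit scoring

Gates are scored on the state order `[0,0], [1,0], [0,1], [1,1]` (first
input varying fastest). The net fold-change divides the mean ON-state NI
by the mean OFF-state NI; for tables with several ON states (XOR, NAND)
the arithmetic mean of ON states is a stated generalization of the
single-ON definition. An ideal gate with exactly zero OFF-state signal
has unbounded net fold-change; panel evaluation reports `Inf` there
instead of failing, while the scalar `net_fold_change()` treats a zero
OFF mean as the domain error it is. The vector proximity angle is
computed in degrees with the cosine clipped to [−1, 1] before `acos` to
absorb floating-point rounding; it is invariant to rescaling the
observed vector, which is why per-state normalization choices (raw NI vs
[0,0]-normalized) do not change θ within a single channel. The pass
cutoff of 20° is inclusive. The half-subtractor evaluator normalizes
each output channel to its [0,0] state first (so mixed channels become
comparable), then scores the difference against XOR and the borrow
against NIMPLY; the operand order of the borrow (which input survives
alone) is a configuration option with `"first_nimply_second"` as the
default convention.

The repression-cascade expectation uses the fixed-point iteration
`level_k = r^(level_{k-1})`, i.e. each stage's regulator scales the next
stage's log-output in proportion to its own level. This is the simplest
steady-state model that yields the qualitative signature of interest —
output alternating low/high with each added stage while converging — and
it is used only for sign-pattern checks, never for magnitudes.

## Problem sizes and numerical conventions

The validation suite and analysis drivers use sizes chosen to make
sampling error negligible relative to the ±10% recovery band while
keeping a full run in the tens of seconds: 5000 events/sample and 3
replicates for screens (≈ 3300 events survive gating under default
composition), 16 triggers for the planted recovery screen, 25 for the
sweep stress case, 1000–2000 events/state for gate panels. With 5%
multiplicative noise the median-ratio estimator's relative error at
these depths is well under 1%, so recovery failures indicate logic
errors, not noise. All tabular outputs serialize doubles with 17
significant digits so that written matrices round-trip bit-exactly;
reruns under a fixed seed and config produce byte-identical tables.

## Known limitations

* The generator's clean separation between transfected and
  autofluorescent populations makes the reference gate nearly lossless;
  real panels with dim reference expression will lose more events and
  inflate NI variance.
* Restricted-mode subset search is exponential in panel size; it is
  practical to ~20 triggers at moderate N, beyond which full-profile
  mode (polynomial per threshold probe, exact max–min) is the intended
  tool.
* When two triggers in a planted crosstalk pair are otherwise
  symmetric, which member the best subset excludes is decided by
  measurement noise; analyses should treat the excluded-member identity
  as arbitrary and only the pair-breaking itself as meaningful.
* The statistic flags *pairwise* crosstalk; a combination can pass the
  0.7 threshold while exhibiting higher-order interactions the pairwise
  geometry cannot see.
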