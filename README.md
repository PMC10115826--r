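# orthocircuit

Quantitative analysis of Cas-responsive translational switch panels.

CRISPR–Cas proteins can be repurposed as sequence-specific translational
regulators in mammalian cells: a switch mRNA carrying the cognate
sgRNA/crRNA motif in its 5'-UTR is repressed (OFF switch) or, with a
switch-inverting module, activated (ON switch) when its trigger Cas
protein is co-expressed. Building multi-input circuits from such parts
requires knowing (a) how strongly each trigger moves each switch, (b)
which trigger subsets act orthogonally — without crosstalk — and (c) how
close an assembled logic gate comes to its intended truth table. This
package implements that entire analysis chain for flow-cytometry and
imaging readouts, together with a synthetic-data generator with planted
ground truth so every stage can be validated end to end.

It is intended for synthetic biologists characterizing regulator–target
panels and for anyone who needs a tested reference implementation of the
orthogonality statistic and circuit scores described below.

## The statistics at the core

**Median-ratio normalization.** After gating (debris removal on scatter,
exact edge-clamp removal, and a reference-positive gate at the 99.9th
percentile of a mock sample's reference channel), each sample is reduced
to its normalized intensity

    NI = 1000 × median( reporter_i / reference_i )

over surviving cells *i*. Relative intensity RI = NI(trigger+) /
NI(trigger−), and relative reporter expression = RI / RI(No-gRNA
control) removes switch-independent effects of trigger expression; the
same chain applies to imaging medians (DV → RV → normalized fold
change). Fold change is RI for ON switches and 1/RI for OFF switches.

**Orthogonality.** With FC(i) the normalized fold-change profile of
trigger *i* across the switches in scope, the distance between two
triggers is the cosine distance of their 1-centered profiles,

    d(i, j) = 1 − (FC(i) − 1)·(FC(j) − 1) / ( ‖FC(i) − 1‖ ‖FC(j) − 1‖ ),

and the orthogonality of a combination C is min over pairs {i, j} ⊂ C of
d(i, j). Distances near 1 indicate ideal orthogonality (disjoint
centered profiles); combinations below 0.7 are flagged as crosstalking.
The best combination of each size N is found either by exhaustive
enumeration or, when profiles are not restricted to the combination's
own switches, by an equivalent max–min search (binary search over the
sorted pairwise distances with a maximum-clique feasibility test on the
threshold graph).

**Circuit scores.** A gate measured across the input states
[0,0], [1,0], [0,1], [1,1] is scored by the net fold-change (mean ON-state
NI over mean OFF-state NI) and the vector proximity angle

    θ = arccos( t·v / (‖t‖ ‖v‖) )  ∈ [0°, 90°],

between the ideal 0/1 truth-table vector *t* and the observed intensity
vector *v*; θ = 0° is a perfect gate, 90° the worst case, and gates with
θ ≤ 20° pass. The half-subtractor evaluator scores its difference output
against XOR and its borrow output against NIMPLY after normalizing each
state to the [0,0] state.

## Worked example

Simulate a 4-switch OFF panel with one planted crosstalk entry
(Cas01 also represses sw02 to 50%), run the full pipeline, and screen
combinations:

```r
library(orthocircuit)

panel <- build_ground_truth_panel(
  4, "OFF", on_target_effect = 0.1,
  crosstalk_spec = list(list("Cas01", "sw02", 0.5)))
screen <- simulate_orthogonality_screen(
  panel, cell_population_model(), n_events = 5000, replicates = 3, seed = 7)
summ <- summarize_screen(screen)
round(summ$fc_matrix, 3)
#>        sw01  sw02  sw03  sw04
#> Cas01 0.100 0.501 1.002 1.002
#> Cas02 1.001 0.100 1.000 1.001
#> Cas03 1.003 1.002 0.100 1.002
#> Cas04 0.999 0.997 0.998 0.100

sweep_best_combinations(summ$fc_matrix, 2:4)[, 1:4]
#>   N  distance orthogonal combination
#> 1 2 1.0059689       TRUE         1,3
#> 2 3 1.0002576       TRUE       1,3,4
#> 3 4 0.5160969      FALSE     1,2,3,4
```

The measured fold-change matrix recovers the planted effects (0.1 on
target, 0.5 at the planted crosstalk entry, 1 elsewhere) to well within
1%. The sweep finds every set size up to 3 orthogonal (distance ≈ 1, by
excluding one member of the crosstalking pair {Cas01, Cas02}), while the
full 4-set is forced to include that pair and drops to distance 0.516 —
below the 0.7 threshold, flagged as crosstalking.

A perfect AND gate scores θ ≈ 1°:

```r
vector_proximity_angle(c(0.1, 0.1, 0.1, 10), truth_table("AND"))
#> [1] 0.9922928
```

## The analysis workflow

The `analysis/` directory holds the end-to-end study as numbered
drivers over the package (each writes its tables under `results/`):

1. `01_simulate_screen.R` — planted 16-switch screen (three crosstalk
   pairs at 0.5), 5000 events/sample, 3 replicates.
2. `02_gate_and_normalize.R` — gating, NI, fold-change matrix
   (max relative error vs planted truth: 0.004).
3. `03_orthogonality.R` — pairwise distances and the best-combination
   sweep; finds the largest orthogonal set at N = 13 and flags
   N = 14..16 as crosstalking.
4. `04_logic_gates.R` — the 60-circuit AND-gate panel (21 of 60 pass at
   θ ≤ 20°), the half-subtractor and a repression cascade.

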