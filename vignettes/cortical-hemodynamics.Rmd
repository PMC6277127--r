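---
title: "Biphasic hemodynamics of synthetic cortical microvascular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic hemodynamics of synthetic cortical microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vasonet)
```

This vignette is the package's account of its science: the flow model and
its assumptions, the constructive network generator and what it does and
does not emulate, the numerical choices, and the known limitations.

## 1. The biphasic network flow model

Blood in the microcirculation is a suspension of red blood cells (RBCs) in
plasma. On a vascular graph the model couples three balances — per-segment
Poiseuille flow `R(h,d) Q = C1 p`, nodal mass conservation `C2 Q = 0`, and
RBC advection `C3(Q,d) h = 0` — in the unknowns pressure `p`, signed flow
`Q` and discharge hematocrit `h`. The model is steady-state and rigid:
no pulsatility, no compliance, no autoregulation, no oxygen transport.

**Viscosity.** Apparent blood viscosity depends on tube diameter and
hematocrit (the Fåhræus–Lindqvist effect). Three published closed forms
are selectable in `rheology_params()`:

* `in_vivo` (default) — the in-vivo apparent-viscosity core curve
  `μ*₄₅(d) = 6 e^(−0.085 d) + 3.2 − 2.44 e^(−0.06 d^0.645)`, generalized
  to arbitrary hematocrit through the shape exponent `C(d)`;
* `in_vivo_esl` — the same curve multiplied by the `(d/(d−1.1))²`
  endothelial-surface-layer wall factor. This raises capillary apparent
  viscosity to 10–15× plasma at `d ≈ 4 µm`;
* `in_vitro` — the glass-tube law with core `220 e^(−1.3 d)`, whose
  viscosity minimum near 7 µm is the classical in-vitro dip.

The default was chosen by a physical-scale argument: on networks meeting
the morphometric targets of Section 3, the three laws yield sample
perfusions of roughly 98 (`in_vitro`), 66 (`in_vivo`) and 21
(`in_vivo_esl`) ml/100g/min under the standard 120→5 mmHg boundary
conditions. Only the core in-vivo law is consistent with the reference
perfusion scale of ~69 ml/100g/min and with the cited physiological range
40–163 ml/100g/min leaving margin on both sides. The wall-factor variant
is retained because it is the better-validated law for single in-vivo
vessels; at network scale it concentrates essentially the entire pressure
drop in the capillary bed, which the pressure–diameter path profiles do
not support.

**Plasma skimming.** At each diverging junction the RBC flux fraction
routed to daughter `i` is `φᵢ = Qᵢ^((m+1)/m) / Σⱼ Qⱼ^((m+1)/m)`: a kinetic
split rule with one coefficient, `m = 8` by default. Its properties are
exactly the ones network computation needs: it handles multifurcations, is
linear in the upstream hematocrits (so the advection operator `C3` is a
sparse linear map and convergence is well behaved), conserves RBC flux to
machine precision, keeps hematocrits bounded (clamped at `h_max = 0.95`
with conservative redistribution, in practice never active under the
standard boundary conditions), and reduces to a skimming-free proportional
split as `m → ∞`. Stronger daughters are enriched; weak side branches skim
cell-poor plasma. Converging junctions mix flux-weighted. The kernel is
isolated in `kpsm_split()` so a different published split rule can be
swapped in without touching the solver.

**Solver.** Picard alternation: a sparse symmetric-positive-definite
pressure solve (Cholesky on the conductance-weighted graph Laplacian after
eliminating `Q`) alternates with a sparse linear advection solve assembled
junction-by-junction on the flow-directed graph (sparse LU; meshed
capillary beds have flow-directed cycles, so no topological sweep is
assumed). The hematocrit update is under-relaxed (`ω = 0.5`) and the
advection operator is rebuilt every pass, so flow-direction reversals
between iterations are handled. Convergence is declared when the relative
L∞ change of both `h` and `Q` falls below `10⁻⁶`; study-scale samples
(~27k segments) converge in 30–50 iterations, a few seconds each.

**Numerically stagnant segments.** A meshed bed always contains a few
segments whose flow is numerically zero (|Q| below 10⁻⁹ of the median).
Their hematocrit is physically undefined; they are excluded from the
advection system, assigned the mixed hematocrit of their higher-pressure
endpoint, flagged, and excluded from the convergence norm (their
placeholder value can dither between equivalent assignments without
affecting any flux).

## 2. Constructive synthesis

The generator emulates the architecture of the cortical angioarchitecture
tier by tier; all parameters live in `synthesis_config()`.

* **Penetrating vessels.** Arteriole and venule surface sites are placed
  by Poisson-disc sampling at 13/mm² each. Capillary-bed entry points
  (300/mm³ per side) are assigned to their nearest penetrating vessel and
  connected to it by CCO growth: each terminal is attached where the total
  tree volume increase is minimal among the 20 nearest candidate segments,
  the bifurcation position being the weighted Fermat point of the local
  triad (safeguarded Weiszfeld iteration, 0.1 µm tolerance, collinear
  degeneracies falling back to the segment midpoint).
* **Diameters.** Murray's law `d_parent^γ = Σ d_child^γ` with `γ = 3`,
  maintained incrementally as power sums. With pre-capillary terminals of
  4.15 µm and ~23 entries per penetrating vessel, Murray closure alone
  yields ~12 µm penetrating trunks — the observed caliber — which fixed
  the per-vessel entry count as a study condition rather than a free knob.
* **Pial tier.** A pial arterial tree (and a reverse-grown venous tree)
  collects the penetrating vessels into a single inlet and outlet. Pial
  terminal calibers carry an over-capacity factor of 1.3 relative to the
  trunks they feed: a sample cut from cortex is supplied by vessels that
  also serve adjacent territory, and without this factor about a quarter
  of the total dissipation lands in the pial network, contradicting
  path-pressure profiles in which pressure stays near the inlet value
  until the penetrating tier. For self-contained territory synthesis
  (`synthesize_mca_territory()`) the factor is 1, and the prescribed
  feeding conduit (the 142 µm M1) is prepended above the pial root as a
  degree-2 joint, so no Murray bifurcation constraint is violated.
* **Capillary bed.** A mesh, not a set of independent chains: capillary
  junction nodes at 11,000/mm³ are wired to their nearest neighbours with
  junction degree capped at 3, pruned to the 2-core (no dangling chains),
  and bridged into a single component. Entry terminals attach by
  *splitting the nearest capillary edge*, which inserts a degree-3 node
  and therefore can never create a multifurcation; synthetic samples end
  up with ~10 multifurcations, well under the target budget (<250), while
  the experimental tally (~5–7% of segments adjacent to one) can be
  emulated in fixtures where needed. Capillary diameters are truncated
  normal, 4.5 ± 0.55 µm within [2.8, 5.9] — below the 6 µm
  capillary/venule cutoff.
* **Tortuosity.** Every interior segment becomes a symmetric quadratic
  Bezier whose control-point offset reproduces an arc/chord ratio drawn
  from a shifted-gamma distribution (mean 1.12, sd 0.08); endpoints are
  fixed and arc lengths updated through a precomputed arc/offset lookup
  (interpolation error < 10⁻⁴).

**Equal terminal outflow.** The classic constructive-optimization growth
principle demands that total inflow discharge in equal amounts through the
terminals. It enters here twice. During growth, equal per-terminal flow
demand is what the Murray power bookkeeping encodes when evaluating volume
increases. As a *post-hoc hydraulic constraint*, `grow_tree(balance =
TRUE)` additionally reallocates Murray power between sibling subtrees
(preserving every parent's power sum, hence Murray closure) until subtree
conductances are proportional to terminal counts; a standalone balanced
tree then delivers terminal flows equal within a few percent. The sample
generator deliberately leaves this pass **off** (`balance_outflow =
FALSE`): real penetrating trunks under-compensate for path length, deeper
entries see lower feeding pressure, and that under-compensation is
precisely what produces the depth-declining bulk flow — and hence the
RBC-flux homogenization — seen in the converged solutions. With full
balancing the layer-median flow profile is flat and the homogenization
phenomenon disappears, which contradicts the converged-solution behaviour
this package is built to study.

**What the generator does not emulate.** Samples are statistical clones,
not reconstructions: no specimen's actual layout is reproduced. The
capillary mesh is spatially homogeneous (no layer-IV density peak); vessel
self-intersection is not prevented; the domain is a flat slab (no cortical
curvature); sub-cortical white-matter supply is excluded; the convex-hull
tissue-volume convention degrades to a bounding box (the box convention is
the default and the one all reported ratios use). Passing tests on
synthetic ensembles therefore demonstrates correctness of the method under
these idealized conditions, not fidelity to any individual imaged
specimen.

## 3. Calibration and study conditions

Generator defaults were calibrated once against the printed morphometric
targets for ~1×1×1 mm cortical samples — segment count ~24.7k, 16,710
segments per mm² of pial coverage, total length 1.33 m, intravascular
volume 27 nL, vascular surface 17.7 mm², capillary surface-to-volume
(blood-brain-barrier) ratio 8.8 mm²/mm³, multifurcations < 250 — under a
1.2 × 1.2 × 1.0 mm box domain (the printed tissue volumes are mutually
inconsistent with any single convention; the box convention is used
throughout). Perfusion was not a calibration objective (beyond the
viscosity-law choice of Section 1); at the frozen defaults it emerges at
~66 ml/100g/min for samples and ~53 ml/100g/min for the reduced-scale MCA
territory.

Problem sizes used by the test-suite and the reproduction script: unit
tests run on fixtures and on reduced 0.5 × 0.5 × 0.8 mm samples (~3k
segments); acceptance-style checks synthesize ten full-size samples and
solve three of them plus one 5%-scale MCA territory (~37k segments). A
full-scale territory (~10⁶ segments) is supported by the same code paths
but is a long-running computation.

## 4. Layer analysis

Flow paths are traced from arterial inlets downstream to venous outlets,
by default as flux-weighted random walks with deduplication (the reference
path counts, 2,300–22,052 per dataset, are reproduced by sampling a few
thousand walks); exhaustive enumeration is available for small networks.
Each path is labelled with the cortical depth of its deepest segment.
Layer statistics are segment-based (each segment assigned by midpoint
depth); path-based grouping is available through the traced paths
themselves, and both are emitted rather than guessing which grouping a
given figure used. Default layer boundaries (µm): I [0,100), II/III
[100,420), IV [420,590), V [590,890), VI [890,∞) — configurable, and
recorded in outputs. Depths on a boundary go to the deeper layer.
`VarRBCFlux` is computed over capillary segments per layer, matching the
phenomenon's description (capillary RBC-flux variability). One-way ANOVA
of hematocrit across layers uses the classical F test; a
zero-between-group-variance degenerate case (the `m → ∞` uniform field)
returns F = 0, p = 1 by definition rather than 0/0.

## 5. Known limitations

Steady rigid-vessel flow only; the skimming kernel is junction-local (no
cell-resolved partitioning); the advection model assigns one discharge
hematocrit per segment (no Fåhræus distinction between tube and discharge
hematocrit inside a segment); equal-pressure single inlet/outlet boundary
conditions (no distribution of inlet pressures); and the reduced-scale MCA
territory preserves intensive properties but not territory-scale pial path
lengths, so its perfusion should be read as a scaled reproduction, not a
prediction for the full territory.
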