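---
title: "Thermoring analysis: model, criteria and design notes"
author: "thermoring package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermoring analysis: model, criteria and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoring)
```

## The model

Thermosensitive TRP channels open at sharp temperature thresholds. The
thermoring model rationalizes those thresholds structurally: along a
defined gating pathway of one subunit (for rat TRPV2, residues F330 to
L719), the side-chain noncovalent interactions form a grid-like mesh
network. A *thermoring* (grid) is a closed round path in that network;
its *size* `s` is the number of *free* residues along the path — residues
that participate in no noncovalent interaction and therefore contribute
conformational entropy but no enthalpy. A small grid holds its
least-stable interaction tightly (high melting temperature); a large one
melts early.

Four quantities summarize a gating state and its transitions:

* **Systematic thermal instability** `Ti = S / N`, where `N` is the total
  number of intra-pathway interactions and `S` the total grid sizes of
  the network. Dimensionless; higher is looser.
* **Melting threshold** of a grid's controlled bridge(s),
  `Tm(°C) = 34 + (n − 2)·10 + (20 − s)·2`, with `n` the number of basic
  H-bonds (about 1 kcal/mol each) energetically equivalent to the
  controlled bridge(s). The constants are the model's fixed empirical
  calibration and are deliberately not fit by this package.
* **Structural thermosensitivity**
  `Ω10 = [(Sc − So)·E/2]^(Nc/No)` for a transition from an initial state
  (subscript c) to a final state (subscript o), with `E` the mean energy
  intensity of one interaction (default 1 kcal/mol). The exponent is the
  enthalpy ratio `Hc/Ho = E·Nc/(E·No) = Nc/No`.
* **Functional thermosensitivity** `Q10 = (X2/X1)^(10/(T2 − T1))`
  (temperatures in Kelvin), the standard activity-ratio normalization,
  provided for side-by-side comparison with Ω10.

On the exponent reading of Ω10: the defining expression can be typeset
ambiguously as a product or a power. This package evaluates it as a
power. The power reading reproduces the published state-comparison
values for rTRPV2 within about 1%
(`structural_thermosensitivity(99, 71, 67, 35)` = 156.3 against a
reported ≈154.6; 3.83 against 3.85; 4.645 against 4.64; 14.74 against
14.8 — the residual is consistent with rounding the exponent `Nc/No`
before exponentiation), whereas the product reading is off by a factor
of about six for the largest transition. The package always reports
full-precision values.

Activation enthalpy uses explicit per-subunit bookkeeping rather than a
network difference: `ΔH = (broken_intra + broken_inter − formed) ×
subunits × E`, because intersubunit contacts live outside the
single-subunit pathway network but still break or form during gating.

## From coordinates to the network

`load_structure` reads PDB or mmCIF through `bio3d` and keeps **author
residue numbering** (the mmCIF `auth_seq_id` field), because that is how
pathway bounds and named bridges are cited in the structural literature.
Only the first model of multi-model files is used. For alternate
locations the highest-occupancy copy is kept, ties resolved to the first
encountered — deterministic and standard.

`select_pathway` restricts one chain to `[start, end]` and records
unmodeled residue numbers inside the range as explicit *gaps* (disordered
pore turrets are the canonical case). By default gaps count as free
residues when sequence-edge weights are computed: a disordered segment
contributes no interactions, which is precisely what "free" means here.
`count_gaps_as_free = FALSE` switches to counting modeled residues only.

Deposited assemblies carry several copies of the subunit, and published
analyses rarely state which chain was used. The package takes an explicit
`chain_id` argument (defaulting to the first chain) rather than imposing
a consensus rule; looping over chains and comparing is a one-liner for
the caller, and the report layer records the chain analyzed.

## Geometric criteria

Six interaction classes are detected between side chains (backbone N/O
atoms are admissible for hydrogen bonds only when
`include_backbone = TRUE`; the default is side-chain-only within the
pathway and backbone-permissive for intersubunit scans, where swapping
H-bonds to backbone amides are an established motif). The default
windows, all overridable through one YAML config
(`read_criteria`/`write_criteria`):

| class | distance | angle |
|---|---|---|
| hydrogen bond | donor–acceptor ≤ 3.5 Å | antecedent–donor–acceptor ≥ 90° |
| salt bridge | charged-group N–O ≤ 4.0 Å | — |
| π–π stacked | centroid–centroid ≤ 5.5 Å | inter-normal ≤ 30° |
| π–π T-shaped | centroid–centroid ≤ 6.0 Å | inter-normal ≥ 60° |
| cation-π | cation center–centroid ≤ 6.0 Å | off-axis ≤ 45° |
| CH-π | aliphatic C–centroid ≤ 4.5 Å | off-axis ≤ 60° |
| lone-pair-π | O/N–centroid ≤ 4.0 Å | off-axis ≤ 60° |

Notes on the choices:

* Cryo-EM models carry no hydrogens, so the hydrogen-bond angular filter
  is a surrogate measured at heavy atoms: the angle at the donor between
  its covalent antecedent and the acceptor. The familiar D–H⋯A ≥ 120°
  criterion translates to roughly ≥ 90° at the heavy-atom level (an sp3
  hydroxyl donor in ideal geometry shows ~109.5°), which is the default
  here.
* The off-axis windows on CH-π and lone-pair-π keep in-plane ring-edge
  atoms from being miscounted as face contacts; distance-only variants
  can be restored by setting the angles to 90°.
* Histidine is treated both as an aromatic ring and as a possible
  cation; protonation states are not inferred. Tryptophan contributes
  both rings and the closer centroid wins. Phe/Tyr use the six-ring.
* A pair qualifying as both salt bridge and hydrogen bond is recorded
  once, as a salt bridge (one bridge per pair); a π–π pair is not
  additionally CH-π or lone-pair-π, and a cation-π pair is not
  additionally CH-π. Genuinely distinct remaining types may coexist on
  one pair — they then close a zero-size two-cycle grid, which is how
  doubled bridges appear as "smallest grids" in state networks.
* Detection has no randomness; records are sorted by residue pair and
  type, and the result is invariant under rigid motion and iteration
  order (verified by tests to ~1e-10 Å).

Per-type energy equivalents default to 1 basic H-bond; published state
tables print grid-level `n` values directly (2.0, 2.6, 2.0/3.0), which
enter either through `assign_energy_equivalents` overrides (a group of
pairs sharing a total `n`) or through the `n_override` argument of
`thermoring()`.

## Grids as a minimum-weight cycle basis

The network has one node per engaged residue; consecutive engaged
residues are joined by a sequence edge weighted by the count of
intervening free residues (author-numbering differences, so gaps count
by default); every interaction contributes a zero-weight edge. Two
graph quantities matter:

* **Per-edge grid size** (`grid_size_of_edge`): the weight of the
  shortest round path through an interaction edge — computed as the
  shortest path between its endpoints with the edge removed. This is the
  number printed next to individual bridges on network maps. Shortest
  paths go through `igraph`; all-pairs algorithms such as
  Floyd–Warshall compute the same quantity.
* **The grid set** (`enumerate_grids`): a minimum-weight cycle basis of
  the network, with `interaction_edges + sequence_edges − nodes +
  components` cycles. `S` is the basis' total weight. The alternative
  operationalization of "total grid sizes" — summing per-edge minima over
  all edges — double-counts shared rings and is rejected; the basis
  cardinality matches the number of independent meshes in the published
  maps, and on a local 12-interaction mesh reproduces the printed
  `(N, S) = (12, 22)` structure.

Implementation: candidate cycles are the Horton set (shortest-path trees
from every vertex combined with each edge), augmented with each edge's
shortest cycle and with the fundamental cycles of a spanning tree (a
rank guarantee); a greedy pass under GF(2) independence selects the
basis. Ties between equal-weight cycles break on the lexicographically
smallest node sequence, making output deterministic. Exactness is not
taken on faith: `brute_force_grid_oracle` enumerates *all* simple cycles
by depth-first search (guarded at 15 interaction edges) and derives the
exact per-edge minima and minimum basis weight; the test suite requires
bit-identical agreement on over one hundred seeded random networks.

Edge cases: an interaction edge on no cycle has no round path and
reports `NA` ("acyclic"); an acyclic network has `S = 0` and an empty
grid list. Open chain ends never form grids — only closed cycles count.
Parallel interaction edges between one pair close a legitimate zero-size
grid. Each interaction edge is also assigned its *controlling grid*, the
smallest basis cycle containing it; within a grid the *controlled*
(least-stable) interactions are its members of minimal energy
equivalent, with ties reported together.

## The estimator interface

`thermoring()` is the central fitting generic (file path →
`structure_model` → `pathway_selection` → `interaction_set` →
`thermoring_network` all accepted) returning a classed fit with
`print`, `summary`, `coef` and `plot` methods;
`thermoring_transition()` compares two fits (or bare `N`/`S` totals) and
`analyze_state`/`compare_states`/`table1_report` wrap fitting into
versioned JSON/TSV reports. There are no `predict`, `simulate` or
`residuals` methods: the estimator has no response variable or noise
model to predict from or simulate under.

## The synthetic-data generators

Two generators make every stage testable with no downloads:

* `geometry_blueprint()`/`generate_structure_fixture()` build a
  coordinate model in which each interaction class is planted once as an
  ideally posed rigid pair (idealized side-chain templates covering
  Arg/Lys/His/Asp/Glu/Phe/Tyr/Trp/Ser/Ala; no rotamer library), at
  distances at least 0.2 Å inside the default cutoff, plus decoy pairs
  at least as far outside every cutoff. Poses sit in separate 40 Å
  regions, and the seed drives a random rigid motion per pose, so
  fixtures vary while detection — being rigid-motion invariant — must
  recover exactly the planted set. Identical seeds give byte-identical
  files.
* `generate_network_fixture()` plants random interaction pairs along an
  abstract pathway and attaches the brute-force oracle's per-edge sizes
  and `S` as ground truth at generation time — expected values are never
  hand-entered.

What passing these tests shows — and does not. The geometry fixtures
prove the detectors fire exactly inside their windows and stay silent
outside, under arbitrary orientation; they do not emulate real cryo-EM
coordinate error, B-factors, alternate conformers or crowded
environments where several marginal contacts compete. The network
fixtures prove the graph machinery exact on graphs of the same size and
topology class as real pathway networks; real-structure totals
additionally depend on the chosen geometric cutoffs, for which the
published supplementary tables remain the reference where available.

## Problem sizes and runtime

The routine test suite runs networks of up to 60 residues and 15
interaction edges (the oracle guard), one hundred seeded replicates for
the oracle comparison, and three-seed replicates of the geometry
fixtures; the whole suite completes in about a minute on a single CPU,
with the oracle comparison itself well under that. Real pathway networks
(about 70 engaged residues, up to ~70 interactions) fit comfortably: the
fast path is polynomial and takes well under a second per state.

## Known limitations

* Default criteria stand in for unpublished per-study cutoff tables;
  absolute `N`/`S` values from full structures therefore depend on the
  configured criteria, which is why the config file exists and why
  interaction tables export in a diffable TSV dialect.
* No protonation-state inference, no water-mediated bridges, no
  protein–lipid energetics: lipid occupancy enters only as a state
  label.
* Intersubunit detection deduplicates symmetric copies to one record per
  residue-pair class, assuming a symmetric homo-oligomer; genuinely
  asymmetric assemblies would need per-interface reporting.
* The empirical constants of the melting model are fixed calibration,
  valid in the regime they were established for; the package evaluates,
  never refits, them.
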