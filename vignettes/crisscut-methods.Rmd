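---
title: "Modeling crisscross ribbon scission: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling crisscross ribbon scission: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisscut)
```

## The system and the abstraction

Crisscross polymerization assembles elongated DNA "slat" monomers into
ribbons: each slat presents an ordered array of weak binding sites, one
half-turn (5–6 bp) per perpendicular neighbor, so that stable capture of a
new slat requires jointly engaging many existing ones. A ribbon carrying
single-stranded toehold extensions can be severed by invader ("cut") slats:
each cut slat binds the extensions of one ribbon face and then competes,
site by site, with the incumbent growth slats across a designed cut
interface — a coarse-grained, half-turn-resolution version of
toehold-mediated strand displacement (TMSD). When every cross-interface
bond has been displaced, the ribbon falls into two capped halves, each able
to seed further growth; growth plus scission yields exponential
amplification.

Nucleotide-level simulation of this process is out of reach (dozens of
unique monomers, stochastic scission, seconds-to-hours time scales).
`crisscut` therefore models the system as a *site graph*: slats are agents
with named binding sites, bonds are graph edges, and dynamics are a
continuous-time Markov chain over bind/unbind events. The package makes no
claim of quantitative prediction for any particular DNA sequence; its
purpose is qualitative exploration of design parameters — ribbon width,
extension length, wobble (deliberately weakened) sites and their
arrangement — under a kinetically explicit, exactly simulated model.

## The generated model

`build_scission_model()` generates the static system from a handful of
parameters. Growth slats come in two orientations, `X_i` (`i = 1..N`,
`N = R*L`) and `Y_j` (`j = 1..N+L-1`), with a growth bond `(X_i, Y_j)`
whenever `0 <= j - i <= L - 1`: the canonical stagger-1 crisscross
parallelogram for a ribbon of width (core slat length) `L` with `R` repeat
units. Terminal slats holding fewer than two bonds in this layout are
pruned in a single pass (exactly the two one-bond terminal `Y` slats); any
stagger-1 parallelogram is equivalent at the site-graph level, so counts
are well defined under this one convention. Slats with index up to
`floor(N/2)` form half A, the rest half B; the `L*(L-1)/2` bonds joining
the halves (for `R = 2`) are the cut interface.

Each B-half `Y` slat holding cross-bonds defines a cut-y slat type, each
A-half `X` slat holding cross-bonds a cut-x type — 9 of each at `L = 10`.
A cut slat carries one *competed* site per cross-bond site it invades (the
cut-y slat competes for the X-side site of each of its cross bonds, the
cut-x slat for the Y-side site) plus `E` *toehold* sites, each bound
exclusively by a dedicated *extension-host* site on a growth slat of the
half the cut slat will cap. Toehold `k` of cut-y slat `CY_j` is hosted on
`X_{j-L+k-1}`, toehold `k` of `CX_i` on `Y_{i+L-1+k}`; host indices are
clamped into the kept slats of the capped half. The clamp serves two
purposes: it keeps every host in range for any `E <= L + 2`, and it
guarantees that no cut slat can ever bond growth slats of both halves.
The second point is essential. An early version of this package followed
the unclamped formulas, which for large `j` place cut-y toeholds on B-half
hosts; such a cut slat, toehold-bound on one half and competing on the
other, holds the ribbon together after every cross bond has been displaced,
and the simulated scission time becomes dominated by this artifactual
tether rather than by strand displacement (the slat-length dependence
flattens out almost completely). Cut slats cap a half; they must never
bridge the interface.

Branch migration needs no dedicated machinery: a competed site and the
incumbent growth partner are simply two sites compatible with the same
target, and a site holds at most one bond, so displacement emerges as
site-by-site unbind/rebind competition at half-turn resolution.

## Kinetics

Rates are dimensionless, with the off-rate `k_off = 1` defining the time
unit (the model is not calibrated to seconds). Defaults:

| parameter | default | meaning |
|---|---|---|
| `k_off` | 1 | off-rate of any bond; sets the time unit |
| `k_on_inter` | 0.04 | on-rate per free monomer copy joining a complex |
| `alpha` | 1000 | intra/intercomplex on-rate ratio at unit concentration |
| `k_on_intra` | 40 | `alpha * k_on_inter`; on-rate inside one complex |
| prebound `k_on_inter`, `k_off` | 0.05, 0.8 | rate set for runs started with cut slats toehold-bound (intra = `alpha * 0.05 = 50`) |
| wobble on, off factors | 2/3, 1.5 | scaling of growth-bond rates at wobble positions |
| `cut_excess` | 100 | free copies of each cut-slat type per single ribbon |

`alpha` encodes the positional-entropy penalty of capturing a free monomer
from solution relative to closing a bond within one complex. It is treated
as a property of a generic monomer type, not an estimate for any specific
chemistry; copy numbers stand in for concentration, with `alpha` defined at
one copy. The prebound intracomplex on-rate is not independently
specified anywhere; we preserve `alpha = 1000`, giving `50`. Wobble factors
apply only to growth–growth bonds at wobble positions, never to cut-slat
bonds — a wobble is a weakened *growth* pairing that the invader (forming
a regular pair at the same position) does not share.

## The engine

Simulation is an exact Gillespie chain. Event classes:

- **unbind**: any bond, at `k_off` times the wobble off-factor where
  flagged;
- **intercomplex bind**: a free site on a free monomer against a free site
  on an in-complex slat, at `k_on_inter` per free copy. Binding between
  two free monomers, and joining of two complexes, are excluded: the
  modeled system is one ribbon plus free slats;
- **intracomplex bind**: two free compatible sites whose slats are already
  connected *within two intermediate slats* (a bond path of at most three
  bonds) at `k_on_intra`. This three-point constraint is the graph proxy
  for physical proximity that a pure site graph otherwise lacks.

The compiled engine keeps one propensity slot per realizable site pair in
a binary sum tree: concrete growth–growth pairs, one pooled slot per
cut-slat pair template (carrying `k_on_inter` times the free-copy count),
and per-pair slots for each ribbon-engaged cut-slat instance. A slot's
propensity depends only on local state — occupancy of its two sites, bond
degree of their owners, pool counts — so each event refreshes a handful of
slots. The locality constraint is enforced by thinning: same-complex
candidate pairs carry the full `k_on_intra` as an upper bound, and a
breadth-first search over at most three bonds decides acceptance when the
candidate fires; a rejected firing is an exact null event whose waiting
time still elapses. Since locality over at most three bonds implies
membership in one complex, this also excludes complex–complex joining
without any global connectivity bookkeeping. Connected components are
maintained only for the observables (complex sizes, number of complexes,
and how many complexes still *bridge* the two half labels).

A slat that loses its last bond returns to the free pool and may rebind at
intercomplex rates (`displaced_growth = "recycle"`, the default, the
simplest rule consistent with mass action); `"delete"` removes it instead.
Whether the original rule-based formulation recycles or deletes such slats
is not determinable from the available description, so both are supported
behind the flag.

A pure-R reference engine (`initial_state()`, `enumerate_candidates()`,
`gillespie_step()`) re-enumerates the full candidate set from scratch at
every step. It is the readable, direct transcription of the semantics and
the compiled engine's cross-check: the test suite verifies that both
enumerate identical candidate sets with identical propensities, and that
both reproduce the exact mean first-passage times of small models'
Markov chains solved by linear algebra.

Reproducibility: all draws flow through R's generator; a run is
deterministic given `(model, mode, seed)`, and replicate `r` of an
ensemble uses `base_seed + r`. When conditions are compared (sweeps), all
conditions of one sweep share the same `base_seed`, so a sweep is fully
reproducible from `(grid, base_seed)`.

In audit mode (`audit = TRUE`) the engine verifies after every event that
a full rebuild of the propensity set, the complex partition, site
occupancy, instance degrees and per-type copy conservation all match the
incrementally maintained state; `audit_trajectory()` additionally replays
the event log in R, independently re-checking occupancy exclusion,
locality of every applied intracomplex bind at its event time, and
molecularity of intercomplex binds.

## Observables and detection

Scission is detected two ways. The *half-label* detector — the primary
ground truth, available because the generator labels every growth slat A
or B — reports the first sampled time at which no complex contains growth
slats of both halves. The *size-drop* detector mimics what one would
measure without labels: the first time the largest complex falls to at
most `1 - f` of its running maximum, default `f = 0.3`. The threshold is
operational and arbitrary, which is exactly why the half-label method is
primary; the suite checks that the two agree within one sampled event in
at least 90% of detected scissions at the default configuration.
"Comparable" products are operationalized as both post-scission complexes
holding at least 25% of the initial growth slats. Replicates that never
scission within `t_max` are reported as censored and excluded from means
— never imputed, since any imputation would bias the means and no
censoring convention is given for this system.

The default horizon `t_max = 3000` is roughly three orders of magnitude
above the mean scission time of the default geometry (about 5 time units
at `L = 10`, `E = 5`), so censoring is a structural signal (e.g. a
cut-free ribbon) rather than a truncation artifact.

## Study conditions and what the sweeps show

The packaged analyses use a single two-repeat ribbon (`R = 2`), a 100-fold
excess of each cut slat, extension length 5, and 100 replicates per
condition in standard mode or 300 in prebound mode. Under these
conditions:

- mean time to scission increases strictly with core slat length over
  `L = 4, 6, 8, 10` — more simultaneous strand displacement has to happen;
- five cross-interface wobbles (factors 2/3 and 1.5) shorten the prebound
  mean scission time relative to none — the designed kinetic-ratchet
  effect. The effect is a few percent of the mean under these rates, so
  the n = 300 comparison resolves it at roughly the two-standard-error
  level and arrangement effects among five-wobble layouts are near the
  resolution limit of this model variant;
- cut-y-only and cut-x-only designs both complete scission; the model is
  symmetric in the two families, so no numeric asymmetry claim is made
  (experimental asymmetries are sequence effects outside the model's
  scope).

Wobble layouts for sweeps are restricted to cross-interface bonds: in a
growth-free simulation only those bonds affect scission. The default
five-wobble arrangement spreads the wobbles evenly along the canonical
cross-bond order; `wobble_arrangement()` also provides contiguous-block
and random layouts for arrangement sweeps.

## The coarse growth-and-cut model

`simulate_population()` abstracts amplification to its two essentials:
deterministic elongation at rate `v` per growing end (one end per ribbon;
each cut creates one new growth front) and stochastic cutting at sites
spaced `Delta` apart, each firing independently at hazard `lambda` once
armed. "Armed" means the repeat distal to the site is complete: the site
at `k*Delta` starts its clock when the ribbon reaches `(k+1)*Delta`. The
alternative reading — arming as soon as the ribbon merely passes the site
position — degenerates in the instantaneous-cut limit (every fragment
would shed vanishing-length fragments continuously); the chosen rule
reproduces the clean limits that make the model useful as a mental
benchmark: `lambda = 0` gives a single ribbon of length exactly `v*t`, and
`lambda = Inf` gives binary fission with ribbon count doubling every
`Delta/v` and all fragment lengths in `[Delta, 2*Delta)`. Cut-site clocks
are exponential, so fragments inheriting sites keep their law under
redraw (memorylessness), and mass is conserved exactly at every cut by
construction. Monomer depletion is deliberately not modeled; the model
addresses the exponential phase only.

## Kappa export

`export_kappa()` writes the generated model as KaSim-4-style text: one
agent per slat type, unbinding and intercomplex binding rules per
compatible site pair, and one intracomplex rule per *traversal template* —
an explicit left-hand-side chain of at most three context bonds placing
the two slats within two intermediates, enumerated over the compatibility
map exactly as the three-point constraint demands. Rates in the text equal
the engine's propensity coefficients, wobble-scaled where flagged. The
bundled `parse_kappa()` is a structural reader (syntax, counts, exact
round trip: export, parse, re-export is byte-identical); it does not
execute Kappa semantics, and running KaSim is never required. Only
structural equivalence with any other rule set is claimed — rule counts
and rates, not file identity. A largest-complex observable is noted as a
comment because complex-size tracking is engine-specific. At `L = 10`,
`E = 5` the export holds about 42,000 intracomplex traversal rules and
renders to roughly 9 MB of text, so the round-trip tests run on smaller
widths.

## Numerical and testing choices

Tiny models are cross-checked against exact chains: the `L = 2` toy
ribbon's scission reduces to a single constant-hazard bond break (mean
exactly `1/k_off`), and first passage to full engagement of its cut slat
is solved from the linear first-step equations of the enumerated chain and
compared with Gillespie means within three standard errors. The engine's
event-choice frequencies at a frozen state are checked against propensity
proportions by chi-square, and its waiting times against the total
propensity. Simulation sizes in the test suite (10,000 toy replicates;
100–300 replicates per condition at `L` up to 10) were chosen so the whole
suite completes in a few minutes while keeping every statistical margin at
three standard errors or better.

Known limitations: no growth during scission (the site-graph model is
scission-only); no spatial geometry beyond the three-point constraint; no
nucleotide-level thermodynamics, so wobble strength is a rate factor, not
a free-energy estimate; copy numbers stand in for concentration; and the
coarse model ignores monomer depletion. Passing tests demonstrate internal
correctness of the stochastic model and the qualitative parameter
dependences built into it — not quantitative agreement with any particular
experimental system.
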