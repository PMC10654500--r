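---
title: "Models and methods: split-GFP strand photodissociation analysis"
author: "strandgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: split-GFP strand photodissociation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandgate)
```

# The scientific problem

Split GFPs reassemble from complementary fragments into the 11-stranded
β-barrel that matures the chromophore. In photodissociable circular
permutants cut between strands 10 and 11, strand exchange proceeds in two
steps: light drives chromophore *cis→trans* isomerization about the
methine-bridge dihedral φ_I, and the resulting trans complex — which has
fewer stable inter-strand interactions — loses strand 10 in a
light-independent step. An excess labelled strand then binds the empty
groove and shifts the absorbance, so the pseudo-first-order exchange rate
reports the photodissociation rate.

Engineering faster photodissociation therefore reduces to two separable
structural questions, and this package implements the analyses that answer
them:

1. Which sidechain interactions anchor strand 10 in the *trans* complex,
   and in what order are they lost as the strand leaves?
2. Which residues gate the isomerization step itself, and which of those
   can be mutated without also perturbing dissociation?

# The synthetic fixture: what it emulates, and what it does not

Microsecond explicit-solvent ensembles cannot be regenerated inside a test
suite, so the package carries a generator whose outputs *stand in* for
them with fully known ground truth. `barrel_fixture_spec()` describes an
idealized antiparallel three-strand fragment of the barrel:

* Strands lie on a cylinder (radius 9.274 Å about the barrel axis, giving
  a 4.8 Å inter-strand chord) with Cα atoms every 3.4 Å along the strand
  direction. Each residue carries backbone N, CA, C, O plus a reduced
  sidechain: CB and one interaction-site pseudo-atom `SC`. The analysis
  operates on interaction geometry, not chemistry, so rotamers are not
  modelled.
* The interaction registry is *planted*: backbone hydrogen-bond ladders
  between cross-strand aligned residues, and a configurable list of
  sidechain interactions (hydrogen bond, salt bridge, aromatic stacking),
  each placed so that it satisfies the default geometric detection
  criteria with margin in noise-free frames. Interactions may alternate
  between two partners on odd/even frames, reproducing the behaviour of a
  serine hydroxyl that swaps between acceptors on the two neighbor
  strands.
* The chromophore is a seven-heavy-atom group around the methine bridge;
  φ_I and φ_P are set by internal-coordinate construction, and
  residue–chromophore contacts are planted per φ_I interval, so umbrella
  windows along the coordinate show contacts appearing and vanishing where
  the spec of the fixture says they should.
* Thermal motion is isotropic Gaussian noise per atom per frame — the
  simplest model that exercises detection thresholds. Dissociation events
  are planted as an ordered schedule of anchor losses (the mobile atom is
  displaced 6 Å away from its partner) followed by rigid drift of the
  strand after the onset frame; the cleaved terminus can be displaced off
  the sheet from the start ("solvated").

`split_gfp_fixture()` encodes the split-GFP registry itself in four
states: `cis` (chromophore at 0°, contacts with the Thr203/Thr205 analogs
on strand 10 and the His148 analog on strand 7); `trans` (180°, the
strand-10↔7 sidechain contacts lost and none formed, terminus solvated);
`trans_anneal` (the trans complex entering heating, with the strand-11
anchors Lys214/Arg215/His217 to the strand-10 mainchain still formed and a
planted loss order ending with Lys209); and `trans_postheat` (sidechain
interactions reduced to the Tyr200 and Ser202 analogs).

What passing tests on these fixtures show is that the *analysis* is
correct: detection matches an independent brute-force oracle, planted
event structure is recovered exactly, and the design rules reproduce the
intended classification. What they cannot show is anything about force
fields, solvent, rotamer packing or real thermodynamics — the fixture has
none of those. One consequence of a dense planted registry is worth
noting: as in a real structure, atoms placed to satisfy one interaction
occasionally fall within the geometric cutoffs of a neighboring pair, so
the split-GFP states contain a handful of incidental contacts alongside
the planted ones. Tests that require exact planted/detected equivalence
therefore use sparse registries; tests on the split-GFP states assert the
registry-level facts.

# Interaction detection

`detect_interactions()` reports, per frame, every qualifying pair on
distinct barrel strands (or between anything and the chromophore group):

| criterion | default | notes |
|---|---|---|
| H-bond donor–acceptor distance | ≤ 3.5 Å | heavy atoms |
| H-bond angle proxy | ≥ 90° | donor–acceptor–antecedent, used because frames carry no hydrogens; with explicit H the usual D–H…A ≥ 120° would apply |
| salt bridge distance | ≤ 4.0 Å | basic SC vs acidic SC |
| stacking centroid distance | ≤ 5.5 Å | aromatic SC sites |
| stacking axis angle | ≤ 30° | angle between CB→SC axes, folded to [0°, 90°] |
| persistent occupancy | ≥ 0.5 | "present in a state" |
| alternating occupancy | ≥ 0.2 | per partner, with co-occurrence Jaccard ≤ 0.2 |

These are literature-standard geometric cutoffs; none of them is fitted.
Kind precedence is salt_bridge > stacking > hbond: an oppositely charged
sidechain pair is evaluated only as a salt bridge, an aromatic–aromatic
pair only as stacking, so one atom pair yields one interaction. Canonical
interaction identity (residue, mainchain/sidechain, atom, kind, partners
sorted) is stable under atom-order permutation, which the tests assert.

`occupancy()` computes presence fractions over a stated frame range and
retains the per-frame mask, from which `find_alternating()` reports
sidechains whose two partners are both well populated yet essentially
never co-occur. `diff_networks()` partitions interactions into broken /
formed / persistent between two states, and `pathway_profile()` tabulates
occupancy per umbrella window along φ_I together with each interaction's
last populated window (its break point).

# Solvent accessibility and orientation

SASA is Shrake–Rupley with a deterministic 960-point Fibonacci sphere per
atom and probe radius 1.4 Å. Relative per-residue accessibility divides by
the residue's SASA in a tripeptide-style reference (the residue plus the
backbone of its chain neighbors), so covalent-neighbor occlusion does not
count against exposure — the Gly-X-Gly convention adapted to the reduced
representation, for which tabulated reference areas would be meaningless.

Orientation labels come from the barrel axis, defined as the first
principal component of the barrel-strand Cα cloud: a residue is "in" or
"out" by the sign of (Cα→Cβ)·(radial direction). Residues in the
cleaved-terminus region whose relative SASA reaches the exposure threshold
are overridden to "exposed". The threshold default is 0.65 rather than the
0.5 customary for full-atom structures: in the reduced open-sheet
geometry, ordinary out-facing residues plateau near 0.55 relative SASA
while genuinely solvated terminus residues reach 0.75–1.0, so 0.65 is the
midpoint that separates the two populations. Glycine, lacking Cβ, is
labelled from backbone exposure alone.

# Periodic WHAM

`generate_umbrella_samples()` draws i.i.d. samples from the biased
Boltzmann density ∝ exp(−[V(φ) + ½k·Δφ²]/k_BT) by inverse-CDF sampling on
a 0.1° grid (Δφ is the minimal periodic image). Direct sampling rather
than Markov-chain dynamics makes the windows *exact*, which is what an
oracle test needs. The default bias constant 0.025 kcal·mol⁻¹·deg⁻² gives
a harmonic width of ≈ 4.9° at 300 K, matched to the 10° window spacing
(neither the force constant nor the spacing of the original simulations is
prescribed anywhere, so both are exposed as parameters).

`wham()` iterates the standard self-consistent equations on a 72-bin
(5°) periodic grid with bias energies computed from minimal-image
distances, converging when window free energies move by less than
10⁻⁴ kcal/mol (cap 10⁵ iterations; R = 1.98720425864083×10⁻³
kcal·mol⁻¹·K⁻¹). Two practical points:

* Bins with fewer than `min_count = 10` total samples are treated as
  unsampled. A nearly empty bin at the edge of the sampled arc has a tiny
  bias-weighted denominator, which inflates its estimated probability and
  would otherwise plant a spurious deep minimum that corrupts the
  zero-anchor of the whole profile.
* Populated bins must form one contiguous circular arc; a gap between
  populated regions raises a coverage error naming the gap.

`barrier_height()` takes the maximum of the profile along the lower of the
two circular paths between the cis-side and trans-side minima, minus the
cis minimum; unsampled bins invalidate a path. The conical-intersection
window (90–100°) is annotation only: classical sampling is unreliable
there, so the bins are flagged but reported, and no reweighting correction
is attempted. `compare_pmf()` returns barrier differences between two
profiles at the same temperature, the quantity used to compare variants.

# Annealing analysis

The native-contact fraction Q uses inter-strand residue pairs whose
minimum heavy-atom distance is ≤ 5.5 Å in the reference frame, retained
while within 1.2× that cutoff. Dissociation onset is the first frame of a
run of at least `persistence = 10` frames with Q < 0.2; absence of such a
run is a valid (negative) result, as for the cis complex, which stays
intact at high temperature. The thresholds are configuration, not physics:
the underlying description of dissociation is qualitative, so the event
definition must be, too.

`anchor_loss_order()` tracks every inter-strand sidechain interaction
involving the dissociating strand that is present at the start, and
reports the last frame of its final presence run of at least
`smoothing = 5` frames. Absence gaps of up to `flicker_gap = 2` frames
flanked by presence are bridged first: at realistic thermal noise an
interaction sitting 0.6 Å inside its distance cutoff flickers off in ~2%
of frames, and a single-frame flicker is not a broken anchor. A genuinely
broken anchor (its atom displaced several angstroms) stays absent and can
never be bridged, so the smoothing distinguishes "rapidly separates" from
"remains stable" without moving real loss times. Ties in loss frame break
deterministically by residue number, then kind.

`terminal_solvation()` reports the first sustained crossing of the mean
relative SASA of the cleaved-end residues above 0.5, which on the planted
trans states precedes the Q-based onset — the mechanistic ordering the
analysis is meant to expose. `register_shift_scan()` reports, per frame
and neighbor strand, the integer residue shift that maximizes cross-strand
Cα pairing within 6 Å; the late-stage scenarios (gap opening vs stepwise
register shift) are left as raw signals because no classifier for them is
defined.

# The design rules

`nominate()` encodes three rules operating on assembled evidence
(`design_evidence()`):

* **Dissociation class** — residues on the dissociating strand, oriented
  "out" or "exposed" in the trans state, whose sidechain holds an
  inter-strand interaction at occupancy ≥ 0.3 in the pre-dissociation
  trans segment *or* which appear among the anchor losses. The trans
  threshold is deliberately lower than the cis persistence threshold
  (0.5) because the trans complex has fewer stable inter-strand
  interactions. Candidates are ranked by trans occupancy sum with ties
  broken toward later anchor loss; the ranking is a heuristic (no
  quantitative rate rule exists for ordering the sites) and is documented
  as such.
* **Isomerization class** — residues whose sidechain contacts the
  chromophore in an *interior* window of the pathway profile (strictly
  between the cis and trans endpoint windows), i.e. residues that crowd
  the rotation itself.
* **Exclusivity** — a residue qualifying for both classes is flagged
  excluded: if it sits on the dissociating strand, or holds any
  interaction (mainchain or sidechain) with it at qualifying occupancy,
  the contribution of its mutation to the two steps could not be
  untangled experimentally. In the worked example this removes the Thr205
  analog (on the strand) and the His148 analog (hydrogen-bonded to the
  strand), leaving the Asn121 analog — on the far side of the chromophore,
  with no strand-10 interactions — as the clean isomerization site.

`propose_substitutions()` implements the two mutation strategies (alanine
to remove polar interactions; Ile/Val/Leu/Trp to introduce steric clash),
and `candidate_combinations()` emits all 1–3 site combinations of the
non-excluded dissociation sites, because single-site results do not
predict combination effects: a site can be unimproved alone yet essential
to the best triple mutant. `name_variant()` renders the community naming
convention (letters at the named positions N→C, hyphen suffix for
off-strand additions).

# Kinetics

`simulate_two_step()` integrates the linear scheme

cis ⇌(k_iso, k_rev) trans →(k_diss) empty →(k_bind) exchanged, plus
cis →(k_dark) empty,

with `deSolve` (lsoda, rtol 10⁻⁹, atol 10⁻¹²); a matrix-exponential
solution serves as an independent oracle in the tests. Light dependence is
folded into the single effective rate k_iso, since all exchange
measurements the model targets were taken at one incident power. When
binding is fast and isomerization rate-limiting, the exchanged fraction is
pseudo-first-order with k_obs = k_iso·k_diss/(k_rev + k_diss), which the
integration reproduces to within 1%.

`fit_exchange()` fits `signal = offset + amplitude·(1 − e^(−kt))` — the
single-exponential form assumed for the pseudo-first-order readout — by
Levenberg–Marquardt least squares with starting values from
log-linearization; a constant trace returns k_obs = 0 flagged with
infinite standard error rather than an error. `rate_ratio()` propagates
first-order uncertainty into the mutant/reference and light/dark ratios in
which results are reported.

# Validation scale and limitations

The validation suite runs at desk scale, chosen so the full test suite
completes in roughly a minute: umbrella reconstruction uses 19 windows ×
5000 exact samples on a 10 kcal/mol double-well (profile RMSE ≈ 0.03–0.10
kcal/mol against the analytic curve); event recovery uses 50 annealing
fixtures of 120 frames at 0.2 Å noise; detection equivalence uses 100
random single frames; rate recovery uses 200 noisy traces of 30 points.
The planted rate contrasts (20× mutant-vs-reference, 85× light-vs-dark)
are scenario parameters of the generator, not physical predictions: the
package recovers planted truth, it does not compute rates from structure.

Known limitations: the fixture's pseudo-atom sidechains carry no
chemistry, so detection there validates geometry only; relative SASA and
the exposure threshold are calibrated to the reduced representation and
should be re-examined (threshold 0.5 is conventional) before use on
full-atom structures; the classical PMF is a ground-state object and
values inside the flagged conical-intersection window should not be
interpreted; and binary trajectory formats (DCD/XTC) are out of scope —
trajectories enter as multi-model PDB with a JSON topology sidecar.
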