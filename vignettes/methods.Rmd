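---
title: "Methods: quantifying the pyrin-domain conformational switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the pyrin-domain conformational switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrinswitch)
```

## The scientific model

Pyrin domains (PYDs) are death-domain-fold modules: six antiparallel
α-helices around a conserved hydrophobic core, with a characteristically
short helix α3. The fold supports two states. In the *closed* state all six
helices pack into the bundle. In the *open* state the two C-terminal
helices α5 and α6 fuse into a single extended stem-helix (α5/6), the core
is partially exposed, and two such open monomers can pair into a symmetric
homodimer mediated by the stem.

Two coupled structural elements decide the state (NLRP14 author numbering
throughout, never renumbered):

* **The charge relay.** A basic side chain at position 84 can bridge two
  acidic anchors, Glu26 (helix α2) and Asp86 (helix α6 start), locking α6
  onto the bundle. Wild-type NLRP14 carries Leu84 — no bridge — and opens;
  an L84R substitution restores the bridge and the closed fold. Removing
  an anchor (D86V) breaks the bridge the same way. At the sequence level
  the element reads E/D at 26, the conserved M82-N83 motif, R/K or not at
  84, D/E or not at 86; an intact triad predicts a closed-monomer
  propensity, a broken one an open/dimerization propensity.
* **The switching element.** Trp72, Leu76 and Leu87 bury either into the
  intramolecular core (closed) or across the dimer interface (open) — the
  same three side chains pay for either state.

The package turns each claim into an explicit, testable computation.

## Surface areas

`sasa()` implements Shrake–Rupley quadrature: each atom's van der Waals
sphere is inflated by the probe radius (default 1.4 Å, water), covered with
a deterministic golden-spiral lattice (default 960 points/atom), and a
point is exposed when it lies outside every neighbouring inflated sphere;
the per-atom area is the exposed fraction times $4\pi (r+p)^2$. The
lattice is fixed, so results are bit-stable across runs; the isolated
sphere is reproduced to ~10⁻¹⁴ relative error and two-sphere overlaps match
the analytic spherical-cap formula to well under the 1.5% quadrature
tolerance. Radii use a fixed Bondi-style heavy-atom table (C 1.70, N 1.55,
O 1.52, S 1.80 Å); hydrogens are dropped at parse time (2–3 Å crystal
structures do not resolve them) and unknown elements raise rather than
defaulting. An independent Monte-Carlo estimator (`sasa_oracle_mc()`,
uniform sampling on each inflated sphere with neighbour rejection) serves
as a cross-check only; quadrature and sampling agree within 2% on random
clusters at the defaults.

Interface burial follows the two-side-averaged convention used by common
interface servers: $[S(A) + S(B) - S(A{+}B)]/2$. Because the stated dimer
interface number in the source structures comes from that convention, the
averaged value is the headline result, but the unaveraged per-side and
per-residue burials are always exposed (`per_residue`, sums to twice the
averaged total). A residue with more than 0.1 Å² per-side burial counts as
an interface residue. `group_contact_area()` applies the same formula to
arbitrary disjoint atom groups; the *hydrophobic-core contact area* is
operationalized as the core side chains against the rest of the same
monomer, because the upstream server's exact atom bookkeeping is not
published — this definitional freedom is why reproduction tolerances on
deposited structures are set at ±15%.

Neighbour search is an exact all-pairs cutoff scan; at this package's
problem sizes (≤ ~2,500 atoms) it is both faster to validate and provably
identical to any spatial-grid optimization.

## Helix geometry and the state call

Secondary structure is assigned from Cα geometry alone — deposited
structures lack hydrogens and the synthetic bundles carry schematic
backbones, so hydrogen-bond criteria (DSSP-style) would be both unavailable
and untestable here. A 4-residue window *i* is helical when
$d(C\alpha_i, C\alpha_{i+3}) \in [4.5, 6.0]$ Å and the virtual torsion
$C\alpha_{i-1..i+2} \in [35^\circ, 75^\circ]$ (an ideal right-handed
α-helix with 1.5 Å rise, 100°/residue twist and 2.3 Å radius sits at
5.05 Å and +50°). A passing window marks its four residues helical;
maximal helical runs become segments (≥ 4 residues by construction), and
axes are fitted to segments of ≥ 5 residues by taking local centers (means
of 4 consecutive Cα, which cancels the helical wobble) and their principal
direction, signed N→C.

`call_conformation()` decides open/closed/intermediate for a stem region
(defaults α5 = 70–83, α6 = 84–96; always overridable, since other PYDs
number differently). Two statistics enter:

* the **inter-axis angle** between axes fitted separately to the α5 and α6
  ranges — near 0° for a fused stem, near 180° for the antiparallel packed
  bundle; it is an average over many atoms and extremely noise-stable;
* **junction helicity** — whether the chain stays helical across the α5/α6
  boundary. Single windows are noisy classifiers: with 0.3 Å per-coordinate
  noise an individual window's spacing has ~0.42 Å standard deviation
  against a 0.55 Å margin, so any per-window AND rule would shatter intact
  stems. The call therefore *averages* over the 8 windows spanning the
  junction: helical iff the mean Cα(i)–Cα(i+3) spacing is ≤ 6.2 Å (ideal
  helix 5.05 Å; turns and loops ≥ ~6.5 Å) and the mean virtual torsion lies
  in [25°, 85°]. Averaging shrinks the noise by ~√8 and makes the call
  deterministic in practice at the noise levels studied.

The verdict is **open** iff the junction is helical *and* the angle is
below 35°; **closed** iff the junction is broken *and* the angle is at
least 70°; anything else — including genuinely half-open geometries — is
reported as **intermediate**. The 35°/70° thresholds are package decisions
(the underlying structural work states no quantitative criterion) and are
echoed into every report.

`superpose()` is the standard Kabsch solution (SVD of the coordinate
covariance with the determinant correction, so mirror inputs still yield a
proper rotation). `dimer_symmetry_axis()` superposes chain A onto chain B
over number-matched Cα atoms, takes the rotation angle from the trace and
the axis from the unit eigenvector, solves the screw equation
$(I-R)\,p = t_\perp$ by pseudo-inverse for a point on the axis, warns when
the rotation is outside 180° ± 15°, and reports residue-to-axis distances
as a ranked table rather than a binary "near the axis" call.

## Interaction accounting

Salt bridges are (basic N, acidic O) side-chain atom pairs within 4.0 Å
(Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 × Asp OD1/OD2, Glu OE1/OE2),
aggregated per residue pair with the minimum distance; 4.0 Å is the common
structural-biology convention, adopted because the source work states no
number. His counts as basic for bridge detection but is excluded from net
formal charges (ambiguous protonation). `detect_charge_relay()` applies
the same distance rule to the two legs around the central residue: intact
requires a basic central residue with both N–O legs ≤ 4.0 Å; a missing
anchor reports `absent` (not an error); everything else is `broken`.

The electrostatic character of the dimer interface is summarized at
residue level (acidic D/E, basic K/R/H, hydrophobic AVLIMFWPC, polar
rest) per chain side — a deliberate, discrete surrogate for continuum
electrostatic maps, which are out of scope. On the synthetic dimer the
D86V substitution removes exactly one acidic interface residue per chain
(the "doubled charge removal" of a residue adjacent to the twofold axis).

## Synthetic data: what it emulates and what it does not

The generators provide labelled ground truth in place of crystallographic
data:

* `make_closed_bundle()` — six helices on a 10 Å-spaced circle, adjacent
  helices antiparallel, with the paper-derived spans (α1 10–21 … α6 84–96,
  chain 7–96) threaded on a serine background carrying the core, switching,
  relay and boundary landmarks (`default_pyd_sequence()`). α2 and α6 are
  placed adjacent so the relay anchors face each other, and the relay side
  chains are planted with their charged tips meeting near the anchor
  centroid (N–O legs ~2.7–2.8 Å), so an Arg84 bundle is detectably intact
  under noise while Leu84 (no basic tips) and Val86 (no second acidic
  anchor) are structurally broken.
* `make_open_dimer()` — α5+α6 fused into one straight stem along x, the
  α1–α4 mini-bundle offset to the side, and chain B an exact 180° rotation
  of chain A about z. The stem phase puts Trp72/Leu76/Leu87 on the face
  toward the partner, and the antiparallel register pairs 72↔87 and 76↔83
  across the interface with CB–CB contacts < 6 Å; Asp86 sits in the
  interface on both chains.
* Side chains are CB-only except the five charged residue types, which
  carry ideal-geometry charged tips — exactly what the detectors read.
  Backbone N/C/O atoms are schematic (midpoint offsets), adequate for
  surface bookkeeping but not for bond-geometry validation, which is a
  non-goal.
* `make_family_alignment()` — random sequences with anchors planted intact
  (E/D, R/K, D/E) or broken (non-basic central, or Val at the D anchor),
  plus randomly inserted gap columns; row 1 is an ungapped-anchor,
  NLRP14-like numbering reference.

Noise is Gaussian, i.i.d. per coordinate, seeded; generation is
deterministic (identical spec + seed ⇒ identical bytes). Because the
bundle packing is schematic rather than physically refined, **areas
measured on synthetic structures are never compared with areas of deposited
structures** — synthetic tests assert labels, orderings and differences
(closed core > open core; interface > 200 Å²; acidic count Δ = 2), while
absolute Å² comparisons are reserved for optional, network-gated analyses
of the deposited entries. Passing on synthetic data therefore demonstrates
the correctness of the computations and the separability of the two states
under coordinate noise, not crystallographic realism.

## Numerical choices and degenerate inputs

* Quadrature default 960 points/atom (≈0.5% area accuracy) — the
  speed/accuracy trade-off; tests that only need orderings use 240–480.
* Coincident atoms (< 10⁻⁶ Å apart) are a degenerate-geometry error.
* Altloc conformers: exactly one kept per atom, by highest occupancy with
  ties broken by altloc character order (or `"first"`).
* Axis fits require ≥ 5 Cα; collapsed local centers raise. Kabsch requires
  ≥ 3 non-collinear pairs; rank-deficient input raises.
* SASA is exactly deterministic but, because the quadrature lattice is
  fixed in space, rigid-body invariance holds to quadrature accuracy
  (~1–2%), not to machine precision; the Monte-Carlo oracle is seeded and
  reproducible.
* Validation problem sizes: 120 noisy structures (2 states × σ ∈
  {0.1, 0.2, 0.3} Å × 20 seeds) for state/relay calls; 20 random 10–50-atom
  clusters for the quadrature/Monte-Carlo comparison (10⁵ samples/atom);
  50 families × 200 rows for the sequence classifier — sizes at which the
  whole suite runs in a few minutes on one CPU.

## Known limitations

* Cα-only secondary structure will differ from hydrogen-bond-based
  assignments near frayed helix ends (boundaries are accurate to about one
  residue).
* The junction statistic judges helicity from backbone spacing; a tight
  non-helical turn with near-helical Cα spacing would need the torsion term
  to discriminate, and genuinely half-open states land in the honest
  `intermediate` bin rather than being forced binary.
* The interface charge summary counts residues, not potentials; it ranks
  and differences charge content but cannot reproduce continuum
  electrostatic maps.
* Sequence-level family classification depends on a user-supplied
  alignment and on the stated anchor equivalence classes (E/D, R/K); real
  NLRP1–14 sequences are deliberately not bundled, to avoid transcription
  errors.
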