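---
title: "Measuring unwound XNA/RNA heteroduplex geometry with xnahelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring unwound XNA/RNA heteroduplex geometry with xnahelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xnahelix)
```

`xnahelix` measures the helical geometry of nucleic acid duplexes in
which one strand has an acyclic backbone — serinol nucleic acid (SNA) or
acyclic L-threoninol nucleic acid (L-aTNA) — hybridized with RNA. This
vignette documents the models and conventions the package implements,
the tunable parameters and their defaults, what the synthetic duplex
generator does and does not emulate, and the numerical decisions a
maintainer should know about.

## The structural model

### Base reference frames

Every base carries an orthonormal reference frame obtained by
least-squares (Kabsch) superposition of an idealized, planar base
geometry — expressed in the standard nucleic acid reference frame, with
the origin at the pair center, x toward the major groove and y along
the pseudo-dyad — onto the observed ring atoms. Purines use their nine
ring atoms, pyrimidines their six; at least three are required, so
partially disordered bases can still be framed. The residual RMSD of
the superposition is retained as a per-residue quality measure
(`residuals()` on a fit). Frames are proper rotations (determinant +1)
by construction, and frame fitting is equivariant under rigid motion of
the structure — both properties are asserted in the test suite.

For the base of the complementary strand, the frame is flipped (y and z
axes negated) before averaging, so that a Watson–Crick pair's two
frames nearly coincide; the pair frame is their re-orthonormalized
mean (nearest rotation by SVD).

### Step and local helical parameters

For consecutive pair frames the package reports two complementary
decompositions:

* **Step parameters** (shift, slide, rise / tilt, roll, twist) from the
  symmetric mid-frame construction: the two frames are rotated by half
  the hinge angle onto a common z axis, twist is the angle between the
  half-rotated x axes, tilt and roll resolve the hinge angle along the
  mid-frame axes, and the displacement is the origin difference in
  mid-frame coordinates.
* **Local helical parameters** (X-displacement, Y-displacement,
  inclination, tip, helical rise, helical twist) from the screw axis of
  the relative transform: helical twist is the rotation angle about the
  axis, helical rise the translation along it, X/Y-displacement the
  perpendicular offset of the pair origin from the axis expressed in
  pair-frame coordinates, and inclination/tip the orientation of the
  pair frame relative to the axis. Positive twist means a right-handed
  helix; X-displacement is negative when the pair center sits on the
  major-groove side of the axis, which is the sign convention in which
  unwound XNA/RNA duplexes show values near −6 Å.

The two decompositions are exercised against each other and against the
builder: `step_parameters()` must rebuild the second frame from the
first through an *independently implemented* composition
(`xnahelix:::compose_step`, written forward rather than inverse) to
1e-8 over a thousand random frame pairs.

Duplex summaries derive residues per turn as 360°/mean(helical twist)
and helical pitch as mean(helical rise) × residues per turn; the
identities are enforced on the unrounded means. Minor-groove width
follows the phosphate convention: the closest interstrand P–P distance
minus 5.8 Å for the van der Waals radii of the phosphate groups. The
global minimum is the headline statistic (the convention is a
closest-approach measure); per-position values are reported for
diagnostics. A strand with no phosphorus in the window yields an
explicit undefined flag rather than a number.

### Pair detection and classification

Candidate pairs must satisfy three thresholds, all configurable through
`pairing_criteria()`:

| criterion | default | rationale |
|---|---|---|
| heavy-atom donor–acceptor distance | 2.4–3.5 Å | standard N/O hydrogen-bond window |
| minimum number of such bonds | 2 | a single contact is not a pair |
| inter-base-plane angle | ≤ 65° | permissive enough for propeller-twisted pairs |
| frame-origin distance | ≤ 15 Å | cheap pre-filter |

Classification is pattern-based: any qualifying bond that engages a
purine N7 marks the pair as *Hoogsteen* (the N7/O6 edge is exactly what
distinguishes the quadruplex-like G\*G pairing of the duplex-of-duplex
dimers from Watson–Crick edges); everything else is Watson–Crick. When
one residue qualifies for several candidates of the same class, the
candidate with more bonds, then the smaller mean bond distance, wins —
but a residue may hold one Watson–Crick and one Hoogsteen partner at
once, which is precisely how a C:G\*G triad is represented (one WC pair
plus one Hoogsteen pair sharing the guanine).

Strand orientation is a local backbone criterion: at each paired
residue the direction from the previous to the next glycosidic
attachment atom along its chain; a positive dot product between the two
strands' directions is *parallel*, negative *antiparallel*. This is
deliberately local so it remains meaningful for the Hoogsteen-linked
strands of a triplex region, where one strand of the pair is not the
Watson–Crick complement.

## Backbone chemistries as data

The chemistry dictionary (`default_chemistry_dictionary()`) drives all
chemistry-specific logic and is round-trippable through an editable
YAML config. Each entry records the expected atom set, the bridging
linkage (O3′(i)–P(i+1) or the acyclic equivalent), the glycosidic
attachment atom, donor/acceptor roles and the torsion quadruples.

For the acyclic backbones, the atom naming parallels ribose: C1′–C2′–C3′
backbone carbons, O1′/O3′ ester oxygens, and an amide branch
N4′–C5′(=O5′)–C6′ carrying the base, with the threoninol methyl as C7′.
The six backbone torsions α–ζ follow the six-bond repeat
O3′(i−1)–P–O1′–C1′–C2′–C3′–O3′. Published atom labels define this path
but not explicit quadruples, so the quadruples ship as editable data
rather than code — if deposited component definitions differ, users
adjust the config, not the package. No glycosidic χ exists in the
ribose sense for these chemistries (the base sits four bonds from the
backbone, across an amide); the package instead reports the
base-attachment dihedral C5′–C6′–N9/N1–C4/C2 as a named auxiliary
angle, kept out of the α–ζ summary tables.

Backbone chemistry is classified from atom names, never from residue
component codes (deposited codes for XNA monomers are not
standardized): ribose requires the furanose O4′/C4′ ring, the acyclic
chemistries the amide triad N4′/C5′/O5′, threoninol additionally the
C7′ methyl. The L/D threoninol assignment uses the sign of the signed
volume of the C2′/O3′/C7′ substituents at the C3′ stereocenter; the
sign convention is fixed to the package's own L template and is
documented as such — it is a consistent internal convention, not a CIP
assignment.

### Torsions, pucker, amide

Dihedrals follow the IUPAC sign convention and live on (−180°, 180°].
Sugar pucker uses the standard pseudorotation treatment of the five
endocyclic torsions: the tangent formula for phase P, amplitude from
ν2/cos P, conformer names from the canonical wheel in 36° envelope bins
(so P ∈ [0°, 36°) reports C3′-endo and P ∈ [324°, 360°) C2′-exo), and
hemispheres by phase quadrant (Northern 315–45°, Eastern 45–135°,
Southern 135–225°, Western 225–315°). The inverse relation
(`torsions_from_pucker()`) is exported and the round trip is exact to
1e-6 over the full 18°-grid of phases.

Amide configuration is classified from ω over the C5′–N4′ bond:
|ω| > 90° is *trans*, below *cis*; the measure-zero boundary value is
assigned *trans* with a warning. Angles that cannot be computed
(missing atoms, flagged chain breaks) are undefined and excluded from
averages — never imputed — and each reported mean carries its N.
Averages of angles are circular means, and spreads are circular SDs
mapped to degrees; the guard case mean({179°, −179°}) = 180° (not 0°)
is a regression test, because torsions of these backbones cluster near
the seam.

## CH–O contacts

Contact detection is scheme-driven (`default_contact_scheme()`): each
entry names a donor-carbon selector, an acceptor-oxygen selector, the
allowed residue offsets along the strand, and whether the acceptor must
be an amide carbonyl. The default scheme encodes the classes observed
in these heteroduplexes — O5′–C8 (purine), O5′–C6 and O5′–C5
(cytosine), O5′–C6′ (backbone–backbone) at offset +1 toward the
1′-terminus, and O2(cytosine)–C6′ at ±1. Distances are heavy-atom C–O
(crystal models carry no hydrogens) and no angular criterion is applied
by default, matching how such contacts are tabulated; an extended
reporting range (default 5.0 Å) retains contacts beyond the 3.7 Å van
der Waals cutoff, flagged `within_vdw = FALSE`. Because the acceptor
selectors are chemistry-aware, a pure-RNA duplex yields no O5′-class
contacts at all: the ribose O5′ is an ester oxygen, and matching it by
name alone would be a false positive — this guard is tested.
Water-mediated hydrogen bonds require both legs (donor–water and
water–acceptor) within the cutoff.

## The synthetic builder: what it emulates, what it does not

`build_duplex()` inverts the analysis: pair frames are generated either
in closed form from uniform local helical parameters (an exact screw
about the global z axis, including displacement, inclination and tip)
or by sequentially composing per-step parameters, and ideal
Watson–Crick partners are placed by flipping the standard base geometry
in the pair frame. Because the frame mathematics is implemented twice —
forward in the builder, inverse in the analyzer — recovery of 100
random step-parameter specifications to 1e-6 is a genuine round-trip
oracle, not a tautology. The generator's study conditions are: 5–10 bp
duplexes, Gaussian coordinate noise of σ = 0.05 Å where noise
robustness is asserted (twist recovered within 0.5°), and fixed seeds
throughout; fiber references use conventional parameters (A-form
32.7°/2.81 Å with 19° inclination and C3′-endo sugars; B-form
36.0°/3.38 Å with C2′-endo sugars) — embedded as conventions, not
measurements.

Backbone atoms are attached rigidly from idealized per-chemistry
templates (standard bond lengths and angles; amide C–N 1.33 Å, C=O
1.23 Å, ω = 180°; furanose rings built to a target pseudorotation
phase/amplitude and accurate to about a degree). The templates are
chemically plausible, not refined: inter-residue linkage geometry is
approximate, so sequential P–P distances, groove widths and the α/ζ
torsions of *built* structures are internally consistent but not
literature values. Consequently, passing round-trip tests demonstrates
the correctness of the frame-derived analysis (frames, pairs, steps,
helical summaries, pucker, amide configuration) and the plumbing of the
torsion/contact machinery — it does not validate absolute backbone
torsion values against crystal structures. That validation requires the
deposited coordinate files (PDB 7BPF, 7BPG and the dsRNA reference
3ND4), which users must download themselves; the corresponding checks
in `tests/testthat/test-acceptance.R` look under
`tests/testthat/deposited/` and report an explanatory failure when the
files are absent, since the package ships no third-party coordinates.
`flip_out` displaces named residues by a fixed rigid motion out of the
helix, emulating unresolved or flipped terminal bases for
pair-detection negative tests; it does not model the energetics of
base flipping.

## Mass conventions

The mass module builds elemental formulas from monomer data: ribose
nucleosides as base + ribofuranose − H2O; SNA and L-aTNA nucleosides as
aminodiol (serinol C3H9NO2, threoninol C4H11NO2) + base-acetic acid
(base + C2H2O2) − H2O; each phosphodiester bridge contributes
H3PO4 − 2 H2O; 5-bromouridine is uridine with Br for the C5 hydrogen.
Termini are free hydroxyls (no terminal phosphate). The default mass
scale is **monoisotopic**, because the calculated single-strand values
this package is checked against sum to the corresponding duplex and
dimer values within 0.1 Da only on the monoisotopic scale (average
masses are systematically ~2 Da higher for an 8-mer); average masses
and a deprotonated [M−H]⁻ convention remain available as arguments.
Assemblies are strictly additive — duplexes and dimers of duplexes are
non-covalent — and additivity is exact at the formula level.

## Numerical decisions, degenerate inputs, limitations

* **Degenerate screw**: when the relative rotation of a step is below
  1e-9 (or numerically axis-free), the helical axis is taken along the
  mean frame z, twist is 0 and the displacement is the perpendicular
  offset of the origin difference; the rule is deterministic and
  documented rather than an error, since straight fragments do occur.
* **Alt-loc policy**: the highest-occupancy conformer wins; ties break
  to the alphabetically first identifier. Single-conformer geometry is
  what parameter tables report.
* **Chain breaks**: a bridging linkage longer than 2.5 Å flags a break
  (standard covalent tolerance); torsions spanning a flagged break are
  undefined, not extrapolated.
* **Tie-breaks in pairing** are total and deterministic (bond count,
  then mean distance, then report order), so `detect_pairs()` output is
  stable under chain enumeration order.
* **Author numbering** is preserved everywhere user-visible; internal
  indices are 0/1-based implementation details and never appear in
  reports. Averaging windows are recorded as provenance in summaries
  and the JSON report, so Table-style averages always state their
  window.
* **Performance envelope**: structures here are tiny (hundreds of
  atoms), and the test suite's simulation sizes (100 random specs,
  1000 random frame pairs) complete in seconds; they were chosen as the
  smallest sizes that exercise the parameter space densely.
* **Out of scope**: crystallographic symmetry expansion, refinement,
  map handling and structure download; global best-fit helix axes
  (only local per-step screw axes are computed); major-groove widths;
  BI/BII or syn/anti sub-classification; energetic scoring of CH–O
  contacts.

## A compact session

```{r example}
spec <- build_spec("GCAGCAGC", c("threoninol_L", "ribose"),
                   helical = list(helical_twist = 22.7,
                                  helical_rise = 3.13,
                                  x_displacement = -6.4,
                                  inclination = 1.6))
fit <- helix_fit(build_duplex(spec))
summary(fit)
coef(fit)[c("helical_twist", "residues_per_turn", "helical_pitch")]

oligomer_mass("GCAGCAGC", "latna")$mass
assembly_mass(list(oligomer_mass("GCAGCAGC", "latna"),
                   oligomer_mass("GCUGC[BrU]GC", "rna")), 2)$mass
```
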