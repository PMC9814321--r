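# xnahelix

Geometric analysis of nucleic acid duplexes that contain acyclic xeno
nucleic acid (XNA) strands — serinol nucleic acid (SNA) and acyclic
L-threoninol nucleic acid (L-aTNA) — hybridized with RNA.

Crystal structures of L-aTNA/RNA and SNA/RNA heteroduplexes show
right-handed but markedly *unwound* helices: base pairs stand nearly
perpendicular to the helical axis (inclination ≈ 1–2° instead of the
≈ 17° of an A-form RNA duplex), the pair centers are displaced far from
the axis (X-displacement ≈ −6 Å), the helical twist drops to ≈ 23–24°
and the pitch grows to ≈ 50 Å. The acyclic backbones are held in place
by networks of weak CH–O hydrogen bonds between amide carbonyl oxygens
and polarized aromatic carbons of neighbouring bases, and two duplexes
can dimerize through parallel C:G\*G Hoogsteen triads. `xnahelix`
implements the complete measurement pipeline behind such findings, for
structural chemists working on acyclic XNAs:

* **Coordinate I/O with chemistry annotation** — PDB/mmCIF parsing
  (via `bio3d`) into a residue model annotated with backbone chemistry
  (`ribose`, `deoxyribose`, `serinol`, `threoninol_L/D`), keyed on atom
  names rather than component codes, with an editable chemistry
  dictionary (`read_structure()`, `classify_chemistry()`).
* **Base reference frames and pairing** — least-squares superposition of
  idealized standard-frame base geometries (`fit_base_frame()`),
  Watson–Crick vs. Hoogsteen pair classification from hydrogen-bond
  edge patterns, and parallel/antiparallel strand orientation
  (`detect_pairs()`, `classify_orientation()`).
* **Step and helical parameters** — the six base-pair step parameters
  (shift, slide, rise, tilt, roll, twist) from the symmetric mid-frame
  decomposition and the six local helical parameters (X/Y-displacement,
  inclination, tip, helical rise, helical twist) from the screw axis of
  the relative transform, summarized into residues per turn, helical
  pitch and minor-groove width (closest interstrand P–P distance minus
  5.8 Å) — `helix_fit()`, `step_parameters()`, `minor_groove_width()`.
* **Backbone conformation** — chemistry-aware α–ζ torsions (with XNA
  quadruples stored as data), glycosidic χ, sugar pseudorotation
  phase/amplitude/conformer, amide cis/trans configuration and
  sequential P–P distances (`torsion_profile()`, `sugar_pucker()`,
  `amide_configuration()`).
* **CH–O contact networks** — scheme-driven detection of
  carbonyl-oxygen/aromatic-carbon contacts (O5′–C8, O5′–C6, O5′–C6′,
  O2–C6′, terminal O5′–C5) under a 3.7 Å van der Waals cutoff with an
  extended reporting range, plus direct and water-mediated hydrogen
  bonds (`find_ch_o_contacts()`, `find_hbonds()`).
* **Synthetic duplex builder** — the inverse of the analysis: generate
  duplex coordinates from prescribed step or helical parameters with
  per-chemistry backbone templates, seeded Gaussian noise and
  flipped-out terminal residues, so every stage is testable without
  downloading structures (`build_duplex()`, `fiber_duplex()`,
  `simulate()`).
* **Oligomer mass calculator** — monoisotopic (default) or average
  masses of RNA/SNA/L-aTNA strands including 5-bromouridine, and
  additive masses of duplexes and dimers of duplexes
  (`oligomer_mass()`, `assembly_mass()`).

## Worked example

Build an unwound L-aTNA/RNA-like duplex and measure it back:

```r
library(xnahelix)

spec <- build_spec("GCAGCAGC", c("threoninol_L", "ribose"),
                   helical = list(helical_twist = 22.7, helical_rise = 3.13,
                                  x_displacement = -6.4, inclination = 1.6))
dup <- build_duplex(spec)
fit <- helix_fit(dup)
summary(fit)
#> Average helical parameters (7 steps)
#>   X-displacement [A]    -6.40 (0.00)
#>   Inclination [deg]      1.60 (0.00)
#>   Helical rise [A]       3.13 (0.00)
#>   Helical twist [deg]   22.70 (0.00)
#>   Residues per turn     15.86
#>   Helical pitch [A]     49.64
#>   Minor groove [A]       5.13
```

The fit recovers the prescribed helical parameters exactly: a 22.7°
twist corresponds to 360/22.7 ≈ 15.9 residues per turn and, at a rise
of 3.13 Å per step, a helical pitch of ≈ 49.6 Å — the unwound,
stretched geometry characteristic of these heteroduplexes (an A-form
RNA duplex has ≈ 11 residues per turn and a ≈ 29 Å pitch). The
minor-groove value here reflects the idealized template backbone of the
synthetic builder, not a refined crystal structure.

```r
pairs <- detect_pairs(dup)
table(pairs$pair_class, pairs$orientation)
#>                antiparallel
#>   watson_crick            8

torsions <- torsion_profile(dup$chains$A)
table(torsions$amide_config)
#> trans
#>     8
```

All eight designed Watson–Crick pairs are found in antiparallel
orientation and every backbone amide of the L-aTNA strand is *trans*.

Strand and assembly masses:

```r
lt8a <- oligomer_mass("GCAGCAGC", "latna")
lt8a
#> <mass_result> single_strand  C85H121N42O44P7  2650.7 Da (monoisotopic, neutral)
assembly_mass(list(lt8a, oligomer_mass("GCUGC[BrU]GC", "rna")))
#> <mass_result> duplex  C160H215N70O100P14Br  5228.9 Da (monoisotopic, neutral)
```

A command-line wrapper with `analyze`, `build`, `mass` and `contacts`
subcommands is installed at `inst/cli/xnahelix`.

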