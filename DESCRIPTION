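Package: xnahelix
Title: Geometry of Xeno Nucleic Acid/RNA Heteroduplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the geometric analysis of nucleic acid duplexes that
    contain acyclic xeno nucleic acid (XNA) strands such as serinol nucleic
    acid (SNA) and acyclic L-threoninol nucleic acid (L-aTNA) hybridized with
    RNA.  Provides coordinate parsing with backbone-chemistry annotation,
    least-squares base reference frame fitting, Watson-Crick and Hoogsteen
    base-pair detection with strand-orientation classification, local
    base-pair step and helical parameters with duplex summaries (residues per
    turn, helical pitch, minor-groove width), chemistry-aware backbone
    torsion profiles, sugar pseudorotation, amide cis/trans configuration,
    CH-O contact networks, a synthetic duplex builder that inverts the step
    parameter math for download-free fixtures, and a monoisotopic oligomer
    mass calculator for RNA, SNA and L-aTNA strands and their assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
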