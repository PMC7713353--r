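Package: trscreen
Title: Bi-Directional Target by Ring-System Dual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for repurposing the rarely used fused-ring systems of
    approved drugs by bi-directional target (T) x ring-system (R) dual
    screening.  Provides descriptor-based ring selection (additive van der
    Waals volume, fragment complexity, hydrogen-bond atom counts),
    criteria-based target selection over metadata tables, an open Gaussian
    shape/color overlay engine producing Tanimoto and reference-weighted
    Tversky combo similarities, a multiplicative fused score over per-pair
    similarity statistics, rank-transformed T x R score matrices with
    mutual-best-pair and saddle-point detection, and combinatorial
    N-arylation library enumeration with drug-likeness, PAINS and
    ligand-efficiency scoring.  A synthetic fixture generator creates all
    inputs needed to exercise the full pipeline without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    bio3d
SystemRequirements: OpenBabel (via ChemmineOB); Python 3 with RDKit for
    seeded 3D conformer embedding (invoked as a subprocess)
Config/testthat/edition: 3
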