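Package: flexsaxs
Title: SAXS Characterization of Flexible Multi-Domain Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of small-angle X-ray scattering (SAXS) data from
    flexible multi-domain proteins such as full-length antibodies.
    Implements model-free invariant analysis (Guinier fits, normalized
    Kratky plots, regularized indirect Fourier transform to the pair
    distance distribution P(r), Dmax scanning), Debye forward scattering
    and chi-square fitting of atomic models, ab initio dummy-atom
    envelope reconstruction with NSD-based clustering and averaging,
    envelope-restrained flexible fitting of coarse-grained models with a
    density potential, ensemble optimization with entropy-based
    flexibility metrics (Rflex, Rsigma), geometric descriptors of
    multi-domain architecture (domain distances and angles, inertia
    planes, SASA, Fab elbow angles), and PCA/clustering of profile and
    feature matrices. A synthetic-data module generates antibody-like
    three-domain surrogates with known ground truth so the full workflow
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
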