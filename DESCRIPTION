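Package: respnet
Title: Functional Network Inference from Calcium Imaging of Respiratory Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers functional networks from time-lapse calcium imaging of
    rhythmically active neural tissue such as the preBotzinger complex and
    the parafacial respiratory group. Provides sliding-window dF/F0
    normalization, calcium transient event detection, pairwise Pearson
    correlation with a scrambled-trace (circular time-shift) null cut-off,
    functional graph construction, and small-world network metrics
    (clustering, path length) normalized against degree-preserving
    randomized networks. Includes a synthetic recording generator with
    known network ground truth (small-world coupling, pacemaker cells,
    calcium transient kinetics, imaging noise, pharmacological
    perturbation scenarios) so that every analysis stage can be validated
    against a known topology, plus ROI extraction from image stacks,
    burst detection on rectified nerve-output traces, and per-cell
    frequency and regularity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: igraph, jsonlite, signal, tiff, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), EBImage, withr
Config/testthat/edition: 3
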