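Package: CICRwave
Title: Calcium Wave Propagation in Chain and Branched Endothelial Cell Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates intercellular calcium wave propagation in patterned
    networks of endothelial cells using a discrete reaction-diffusion model of
    calcium-induced calcium release (CICR) with threshold-switched release and
    intake rates and a permanent refractory state, coupled cell-to-cell by
    gap-junction diffusion. Provides builders for chain and branched ("T")
    network architectures with distinct edge-contact and vertex-contact
    coupling coefficients, an explicit synchronous integrator, stimulation
    protocols (single and dual mechano-stimulation), propagation-outcome
    classification and vertex-coefficient sweeps, wave descriptors (per-cell
    response times, cell-to-cell propagation times, pulse spatial extent,
    wave-crossing detection) with dimensionless-to-physical calibration, a
    reimplementation of the fluorescence time-series analysis used for
    Fluo-3AM recordings, and a seeded generator of synthetic fluorescence
    trace sets with ground truth for validating the trace analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
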