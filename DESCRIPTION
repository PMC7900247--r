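Package: sevogranule
Title: Sevoflurane Action on the Cerebellar Granular-Layer Microcircuit
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based modelling of the cerebellar input stage under the
    general anesthetic sevoflurane. Implements a multi-compartment granule-cell
    model with an allosteric (transient/persistent/resurgent) sodium channel
    scheme, a spiking Golgi-cell surrogate, Tsodyks-Markram vesicle-cycling
    presynaptic dynamics, multi-state AMPA/NMDA/GABA-A/kainate receptor kinetic
    schemes with glomerular spillover, Q10 temperature scaling, patch-clamp
    style stimulation protocols (current steps, EPSC/IPSC trains, paired-pulse
    frequency sweeps, EPSP recordings) and the trace metrics needed to compare
    control and sevoflurane parameter bundles, together with a synthetic
    patch-clamp trace generator for ground-truth validation of every analysis
    operator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
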