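Package: fluoroconn
Title: Functional Connectome Inference from Calcium Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functional neuronal connectomes from two-photon calcium
    fluorescence (dF/F0) recordings. The pipeline deconvolves fluorescence
    traces into spike amplitude trains with a sparse non-negative AR(1)
    online-active-set solver, conditions the spikes by neuron-specific
    thresholding and weighted temporal smoothing, and scores functional
    connectivity between neuron pairs by partial correlation computed from
    the precision (inverse covariance) matrix of the smoothed activity.
    Includes a ground-truth spiking-network simulator with fluorescence
    rendering, ranked-edge-list ROC/PR evaluation (AUROC/AUPR), ablation
    variants (binarization, percentile thresholds, frame downsampling), and
    a missing-neuron subsampling robustness experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
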