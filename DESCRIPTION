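Package: switchscan
Title: Detecting Switch Residues and Grading Their Dynamic Stability in
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies amino-acid residues that switch between two distinct
    angular conformational states in molecular dynamics trajectories.
    Residues are reduced to a small selected-atom set, all three-atom angles
    among the selected atoms are measured per frame, and each angle's
    normalized density of states (DoS) is summarized by 14 engineered
    features.  Tree-based classifiers (decision tree, random forest,
    gradient-boosted trees) trained on labeled DoS feature vectors flag
    bimodal "switch" angles; per-frame angular states from two-cluster
    k-means yield an instability ratio (percent of frames with an
    inter-state transition) that a one-dimensional logistic model uses to
    grade each switch as stable (single jump) or unstable (constant
    oscillation).  Residue-level angle switch ratio (ANSR) and atom switch
    contribution (ATSC) metrics, and state-conditioned summaries of global
    properties such as RMSD, complete the report.  Includes a synthetic
    ground-truth generator for angle dynamics and toy 3-D trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
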