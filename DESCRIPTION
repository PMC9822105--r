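Package: GOTriplet
Title: Triplet Metric Learning and Guilt-by-Association Prediction of
    Gene Ontology Terms
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Protein function prediction in the Gene Ontology (GO)
    framework from precomputed protein language-model embeddings. A
    multi-view fusion network is trained with a composite objective that
    couples a batch-hard triplet loss, supervised by protein-protein
    functional similarity, with a sigmoid cross-entropy term; predictions
    are produced by rank-weighted k-nearest-neighbour guilt-by-association
    in the learned metric space, optionally combined with homology-,
    naive-frequency- and interaction-network-based baseline predictors.
    Includes OBO/GAF readers, true-path annotation propagation,
    hierarchical score post-processing, a CAFA-style evaluation suite
    (Fmax, AUPR, AUROC, coverage, information-content-weighted Fmax,
    Friedman/Nemenyi method comparison) and a synthetic-data generator
    that emulates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, FunctionalPrediction, GO, Annotation, MachineLearning
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'metrics-eval.R'
    'metrics-similarity.R'
    'model.R'
    'ontology-io.R'
    'ontology.R'
    'pipeline.R'
    'predictors.R'
    'synthetic.R'
    'utils.R'
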