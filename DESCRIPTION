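Package: cbparc
Title: Connectivity-Based Parcellation of Seed Regions from Tractography Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Parcellates a seed brain region from probabilistic-tractography
    seed-by-target streamline-count matrices. Per-participant matrices are
    turned into seed-by-seed cross-correlation connectivity fingerprints,
    Fisher-Z transformed and averaged across the group, and clustered with
    replicated k-means over a range of cluster counts K. The optimal K is
    selected by a split-half resampling procedure scored with the variation
    of information between half-group solutions; solutions are further
    characterized by a hierarchy index, a left-right hemispheric symmetry
    index, cluster centers of gravity, and cluster-wise tract aggregation
    with a sign-flipping max-statistic permutation contrast controlling the
    family-wise error rate. A synthetic-data generator with planted parcel
    structure, participant noise, nested hierarchy, and hemispheric
    mirroring makes the whole pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
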