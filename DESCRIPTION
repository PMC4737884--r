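Package: lhmap
Title: Whole-Brain Activity Mapping for the Learned-Helplessness Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for brain-wide neuronal-activation studies of
    the learned-helplessness (LH) paradigm. Scores shuttle-box escape trials
    and classifies animals as helpless or resilient (k-means clustering plus
    linear discriminant classification functions; lever-press thresholds for
    rats), screens anatomical regions for differential activation between
    paired helpless and resilient animals with a negative-binomial
    generalized linear model (sequential likelihood-ratio test of the group
    term, Benjamini-Hochberg FDR across regions), converts 3D cell centroids
    into overlapping spherical-voxel density maps with voxelwise testing,
    and tests stereotypy of brain-wide activity profiles via a bootstrap
    null for the difference in mean within-group pairwise Pearson
    correlation. A synthetic-data module generates behavior cohorts, paired
    over-dispersed region-count matrices, cell clouds with a toy label
    atlas, and group-structured activity profiles carrying the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
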