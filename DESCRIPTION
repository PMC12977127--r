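Package: foliakit
Title: Surface-Volume Atlas Construction, Equal-Area Parcellation and
    Diffeomorphic Atlas-to-Subject Reconstruction for Folded Cortices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with densely folded cortical surfaces such as
    the cerebellar cortex: voxelization of closed labeled surface meshes via
    generalized winding numbers with surface-volume label consistency
    enforcement, subdivision of labeled surfaces into approximately
    equal-area connected patches, two-stage diffeomorphic registration that
    reconstructs an atlas-derived cortical sheet in individual subject space,
    and segmentation evaluation with DICE and Hausdorff metrics across
    structural hierarchies. Ships generators for synthetic folded phantoms
    with known smooth deformations so the whole pipeline is testable without
    external data, plus readers and writers for common neuroimaging formats
    (FreeSurfer binary surface and annot, GIFTI, PLY, NIfTI-1, MGH/MGZ).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
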