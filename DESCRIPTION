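Package: morphomap
Title: Tissue Motion and Deformation Mapping for Fragmented 3D+t Live Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies tissue motion and deformation during organogenesis from
    fragmented 3D+t live-imaging datasets. Estimates per-specimen motion with
    free-form-deformation B-spline non-rigid registration anchored at the
    sequence midpoint, propagates triangular surface meshes into continuous
    Live-Shape sequences, stages specimens against a reference atlas with a
    Gaussian-mixture morphometric classifier, projects staged shapes into
    atlas space via robust Student's-t mixture rigid alignment and mask-based
    non-rigid morphing, computes per-triangle finite-deformation growth and
    anisotropy maps, multiplies mean stepwise deformation into cumulative
    deformation across stages, and assembles an in-silico fate map. A synthetic
    scene generator with analytic ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    splines,
    utils,
    Rcpp,
    tiff,
    RNifti,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Collate: 
    'morphomap-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'imaging_io.R'
    'registration.R'
    'utils.R'
    'mesh.R'
    'pointset.R'
    'mapping.R'
    'fatemap.R'
    'staging.R'
    'synthetic.R'
    'validation.R'
    'integrate.R'
    'mechanics.R'
    'pipeline.R'
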