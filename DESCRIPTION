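Package: meniscusdti
Title: Zonal Parcellation, Diffusion Tensor Metrics and Tractography for
    Meniscus Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Alex", "Rowan", email = "alex.rowan@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the collagen fiber architecture of C-shaped
    fibrocartilage (the knee meniscus) from diffusion-weighted MRI.  The
    package fits the diffusion tensor voxelwise and derives FA, MD, axial
    and radial diffusivity maps; automatically parcellates a binary
    meniscus mask into the three vascular zones of Cooper's classification
    (White-White, Red-White, Red-Red), into anterior/body/posterior parts
    by rotation angle, and into their nine combined regions; performs
    deterministic streamline tractography along the principal eigenvector
    with a turning-angle stopping rule; and summarises region-to-region
    structural connectivity as a heatmap.  A synthetic phantom module
    generates crescent-shaped masks, zone-dependent fibrous tensor fields
    and Rician-noise diffusion-weighted volumes so the whole chain can be
    exercised and validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
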