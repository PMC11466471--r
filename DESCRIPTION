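Package: noncopcbct
Title: Limited-Angle Non-Coplanar CBCT Simulation, GAN Reconstruction and
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for cone-beam CT imaging at rotated treatment-couch
    positions, where collision constraints restrict the gantry arc and only
    limited-angle projections can be acquired. Provides a cone-beam
    acquisition simulator (ray-cast digitally reconstructed radiographs over
    couch-angle-dependent arc schedules), synthetic digital head phantoms
    with uniformly sampled rigid setup errors, a generative adversarial
    reconstruction model whose generator fuses a coplanar prior volume with
    the limited-angle projection stack, a joint training loss combining
    adversarial, L1 and a differentiable rigid-bone term built from soft
    bone extraction, Sobel edges and rotation-invariant radial central
    moments, and a quantitative evaluation suite (RMSE, internal rigid
    registration, sphere-integrated overall registration error, bone SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
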