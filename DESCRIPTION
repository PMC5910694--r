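Package: myotract
Title: Muscle Architecture from Diffusion-Tensor Fibre Tractography
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional skeletal-muscle fascicle
    architecture from diffusion-tensor imaging. Fits diffusion tensors
    from diffusion-weighted volumes, derives eigenvalue, fractional
    anisotropy and primary-eigenvector maps, performs deterministic
    streamline tractography constrained by anisotropy and diffusivity
    windows, fits cubic polynomial curves to fibre tracts and
    extrapolates them to triangulated compartment surface meshes, and
    computes fascicle length, 3D pennation angle, Frenet-Serret
    curvature, compartment volume and physiological cross-sectional
    area, together with compartment-level summaries and linear
    mixed-model statistics for change with passive lengthening. A
    synthetic pennate-muscle phantom generator with analytically known
    architecture supports validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
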