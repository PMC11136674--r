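Package: canopyrt
Title: Physically Based Simulation of Annotated Multi-Band Plant Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiative-transfer simulation of plant canopy imagery at desk
    scale. Scenes of planar primitives (procedural plants, textured ground,
    imported meshes) are illuminated by collimated or finite radiation
    sources and a reverse Monte Carlo ray-tracing transport model computes
    per-primitive absorbed and scattered fluxes, iterated over scattering
    events until the residual energy is negligible. A thin-lens camera model
    with per-band spectral response renders multi-band (RGB, multi-/
    hyperspectral, thermal, depth) images together with per-pixel annotation
    maps (object identity, biochemistry, temperature, distance) and YOLO
    bounding boxes. Leaf reflectance and transmittance spectra are generated
    from biochemistry with a generalized plate model of leaf optics, and an
    effective camera spectral response can be recovered from color-target
    observations. Lens distortion (radial and tangential) is applied by
    forward pixel remapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
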