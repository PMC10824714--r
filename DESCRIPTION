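Package: holopol
Title: Polarization Holographic Imaging of Flowing Microplastics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for in-line polarization
    digital holography of birefringent particles flowing in water.
    Generates physically based polarization-mosaic holograms with ground
    truth, recovers Stokes, degree-of-linear-polarization, angle-of-
    polarization and stack-standard-deviation feature maps, reconstructs
    complex fields by the angular-spectrum method, segments and measures
    particles (Feret diameters, circularity, sphere-equivalent volume),
    tracks and counts particles across video frames, classifies particle
    material from birefringence features with a nearest-centroid model,
    and quantifies measurement agreement with Bland-Altman statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
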