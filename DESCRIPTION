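Package: petalkm
Title: Kubelka-Munk Layer-Stack Modelling of Flower Petal Optics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse two-flux (Kubelka-Munk) optics for flower
    petals treated as a stack of diffusely scattering and absorbing layers.
    Computes diffuse reflectance and transmittance of layer stacks with the
    plate adding equations, inverts measured integrating-sphere spectra of a
    corolla to recover the pigmented layer's absorption and scattering
    parameter spectra and the pigment absorbance spectrum, predicts spectra
    for illumination of either petal side, and simulates alternative pigment
    distribution strategies (asymmetric, homogeneous, symmetric) with
    conserved total pigment and scattering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
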