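Package: cardioSAXS
Title: Scanning X-Ray Diffraction and SHG Morphometry of Cardiac Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of scanning micro-focus small-angle X-ray
    diffraction of striated (cardiac) muscle tissue and of second-harmonic
    generation (SHG) micrographs of myofibrils. Detector frames are reduced to
    background-subtracted radial and azimuthal intensity profiles; the
    acto-myosin (1,1) reflection is fitted with a power-law plus Gaussian
    model and converted to filament spacing a = 4*pi/q0; fiber orientation and
    anisotropy are obtained by axial circular statistics of the normalized
    azimuthal profile; per-point parameter maps are clustered by k-means,
    modeled by kernel density and pseudo-Voigt profiles, and thresholded into
    lesion masks; beam dose is estimated from the beam geometry. A
    power-spectral-density cake-integration indicator quantifies myofibril
    undulation in SHG micrographs, with paired group testing. A synthetic-data
    generator produces scan stacks and micrographs with known ground truth so
    that every stage is testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'synthetic.R'
    'reduction.R'
    'peakfit.R'
    'orientation.R'
    'maps.R'
    'segmentation.R'
    'shg.R'
    'io.R'
    'config.R'
    'pipeline.R'
    'cardioSAXS-package.R'
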