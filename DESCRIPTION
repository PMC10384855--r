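Package: voxdose
Title: Voxel-Level Internal Dosimetry for Theranostic Radiopharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based internal dosimetry for theranostic radiopharmaceutical
    pairs. Converts a PET-derived time series of activity-concentration volumes
    acquired with an imaging radionuclide (e.g. Zr-89) into absorbed-dose maps
    for a chemically analogous therapeutic label (e.g. Lu-177): per-voxel
    isotope substitution by decay correction, absorbed dose-rate estimation by
    local energy deposition, dose-point-kernel convolution or simplified Monte
    Carlo photon transport, trapezoidal time integration with explicit head and
    tail extrapolation, ROI standardized uptake values and Gy/GBq dose
    coefficients, and administered-activity prescription under an organ dose
    limit. Includes a synthetic voxelized canine phantom with compartmental
    pharmacokinetics as a stand-in for undeposited PET/CT data, plus NIfTI/JSON
    readers and writers and grid resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
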