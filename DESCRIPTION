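Package: perfmap
Title: Brain Perfusion Imaging Quantification by Truncated-SVD Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise quantification of dynamic contrast (CT or MR)
    brain perfusion series. Concentration time curves are deconvolved
    against a global, local or user-supplied arterial input function by
    truncated singular value decomposition of the lower-triangular
    Toeplitz convolution matrix, yielding parametric maps of cerebral
    blood flow (CBF), cerebral blood volume (CBV), mean transit time
    (MTT), time to peak (TTP) and time of arrival (TA). A serial
    reference engine and a chunked worker-pool engine produce
    bit-identical maps. Includes a digital perfusion phantom generator
    with analytic ground truth, NIfTI-1 input/output, colour-map
    rendering, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    optparse,
    parallel,
    withr,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
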