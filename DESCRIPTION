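Package: inearseg
Title: Automated Endolymphatic Hydrops Quantification from Inner-Ear MR Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of aligned multi-modality inner-ear MR image
    stacks for endolymphatic hydrops (EH) assessment. Composes HYDROPS
    (voxel-wise PPI - PEI) and HYDROPS-Mi2 (HYDROPS x MRC) volumes, segments
    cochleae and vestibules with a three-slice-input encoder-decoder
    convolutional network (3intoUNet or an inception-style variant) trained by
    a two-phase curriculum, selects the representative key slice per organ as
    the slice of largest segmented area, and reports per-organ EH ratios
    (fraction of segmented pixels with negative HYDROPS-Mi2 signal). Includes
    the full evaluation suite (intersection over union, single-score two-way
    intraclass correlation, Pearson correlation, slice-distance histograms,
    subject-level cross-validation) and a synthetic phantom generator with
    known masks, key slices and designed EH ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
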