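Package: pcgseg
Title: Heart Sound Segmentation and Congenital Heart Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-wise segmentation of phonocardiograms (PCG) into the four
    cardiac states (S1, systole, S2, diastole) with a multi-scale temporal
    convolutional network fused with a bidirectional LSTM (TBLSTM), trained by
    hand-authored backpropagation on four envelope features (Hilbert,
    homomorphic, Daubechies-6 wavelet detail, power spectral density).
    Decoded state sequences are cut into overlapping fragments of N cardiac
    cycles; MFCC plus delta and delta-delta features, PCA reduction and a
    random-forest classifier separate normal, atrial septal defect (ASD) and
    ventricular septal defect (VSD) recordings, including a cross-validated
    sweep over the number of cycles per fragment. A labelled synthetic
    pediatric PCG simulator makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
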