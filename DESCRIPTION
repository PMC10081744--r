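Package: frailtynet
Title: Split Frailty Indices and Neural-Network Prediction of Surgical
    Discharge Destinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the 13-item modified frailty index (mFI), its
    high-impact/low-impact split, and the beta-weighted single-index
    variant (mFI-hat) for elective-surgery cohorts; generates synthetic
    NSQIP-like patient cohorts with a latent-ordinal discharge-destination
    model; prepares destination-stratified splits with median-cap partial
    balancing; trains small feed-forward backpropagation classifiers with
    an incremental hidden-layer architecture search; and evaluates model
    variants with accuracy, percent improvement, one-tailed two-proportion
    Z-tests, destination coverage and mortality recall, including replay
    of the published worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
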