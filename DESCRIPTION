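Package: twoconf
Title: Two-Conformation Receptor Pharmacology for Beta-Adrenoceptor Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative pharmacology for receptors that adopt two
    agonist-stabilised conformations, developed around the human
    beta1-adrenoceptor (a high-affinity catecholamine conformation and a
    secondary, antagonist-resistant conformation). Fits radioligand
    saturation and competition binding with Cheng-Prusoff correction;
    fits one-site, two-site stimulatory and inhibit-then-stimulate
    ("dip") concentration-response models to reporter-gene data with
    extra-sum-of-squares model selection; estimates antagonist and
    partial-agonist affinities by Gaddum dose-ratio, Schild regression
    and Stephenson's matched-response method; and applies a four-point
    evidence rubric (A-D) to classify compounds as neutral antagonists,
    conventional agonists, secondary-conformation agonists, biphasic
    agonists or non-binders. Includes a deterministic two-conformation
    assay simulator so the whole pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
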