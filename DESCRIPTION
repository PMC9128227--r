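Package: tetherdrive
Title: Population Dynamics and Inference for Tethered CRISPR Toxin-Antidote
    Gene-Drive Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-locus genotype-frequency models of CRISPR Toxin-Antidote
    Recessive Embryo (TARE) gene drives and the split homing drives they
    support ("tethered" drive systems), as characterised in Drosophila cage
    experiments. Provides exact gamete and offspring distributions under
    germline cleavage, maternal Cas9 deposition, homing conversion and
    recessive-lethal or haplolethal viability rules; deterministic
    generation-by-generation dynamics with introduction-threshold and
    equilibrium location; a Wright-Fisher style finite-population cage
    simulator with effective-size drift; inversion of observed inheritance
    rates into germline and embryo cleavage-rate estimates; and joint
    maximum-likelihood estimation of drive fitness and effective population
    size from cage phenotype trajectories, with profile-likelihood
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
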