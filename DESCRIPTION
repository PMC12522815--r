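Package: hmecea
Title: Markov Cohort Cost-Effectiveness Model for Heat and Moisture
    Exchangers After Total Laryngectomy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A five-state Markov cohort model comparing third-generation
    heat and moisture exchangers (HMEs) with second-generation HMEs and no
    HME in patients after total laryngectomy, from a public healthcare
    payer perspective. Health states are defined by CASA-Q sputum-impact
    score cut-offs plus recurrent cancer and death. Provides empirical
    (non-parametric) transition-probability estimation from patient-level
    panel data, a deterministic cohort trace with discounted costs and
    QALYs and incremental cost-effectiveness ratios, one-way sensitivity
    analysis with tornado ordering and threshold search, probabilistic
    sensitivity analysis with Dirichlet/Beta/Gamma distributions and
    cost-effectiveness acceptability curves, and a synthetic-data module
    that generates panels, life tables and a complete default model
    configuration so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
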