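Package: ionrbe
Title: Dose-Response and RBE Inference for Ion-Beam Radiobiology
    Experiments
Version: 0.1.0
Authors@R:
    person("ionrbe", "maintainers", email = "ionrbe@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for in-vivo ion-beam radiobiology dose-response
    experiments with a censored binary endpoint: actuarial (product-limit)
    response rates with effective sample sizes, maximum-likelihood logistic
    dose-response fitting with ED50 and Fieller confidence limits,
    generalized logistic regression through the linear-quadratic
    biologically effective dose yielding alpha/beta, BED50 and the maximum
    relative biological effectiveness (RBE), RBE error propagation, and
    amorphous-track RBE prediction models (LEM I low-dose approximation and
    the modified microdosimetric kinetic model). Includes a synthetic
    cohort generator emulating a rat spinal-cord study design (dose groups
    of five animals, single and split doses, four LET positions, 300-day
    follow-up with sporadic censoring) so the whole chain is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
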