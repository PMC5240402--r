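Package: multinfusion
Title: Dosing-Error Prediction for Multi-Infusion Syringe Pump Set-Ups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the transient dosing-error boluses that arise in
    multi-infusion set-ups where several syringe pumps feed a single catheter.
    Combines an electric-analog (RC network) model of syringe compliance and
    line resistance, a plug-flow voxel model of the catheter dead volume, and
    a discrete convolution model of Poiseuille (laminar-profile) mixing into
    one framework. Provides closed-form two-exponential transients, bolus
    volume, central time and width by the method of moments, a syringe
    exchange error model, a general linear state-space flow simulator for
    arbitrary channel counts and schedules, and an independent radially
    resolved streamline simulator used to verify the analytic chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
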