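Package: KymoDwell
Title: Kymograph Analysis of Kinesin Microtubule End Residence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-molecule TIRF kymograph analysis for motor proteins:
    measures microtubule end-residence times, translocation velocities and
    run lengths of kinesins from two-channel (microtubule/motor) kymographs,
    and compares residence-time distributions between variants with
    two-sample Kolmogorov-Smirnov tests. Includes a stochastic simulator of
    single kinesin-microtubule interaction events with a TIFF kymograph
    renderer, so that every measurement stage can be validated against known
    ground truth, plus linear fitting of basal ATPase turnover rates from
    ADP-production timecourses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
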