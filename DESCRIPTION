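Package: heattent
Title: Paired-Tent Thermostat Control, Microclimate Simulation and High
    Night Temperature Trait Analysis
Version: 0.1.0
Authors@R:
    person("Field Phenomics", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for field-based high night temperature (HNT) stress
    phenotyping with paired control/stress heat tents. Implements the
    per-minute bang-bang thermostat controller that targets a fixed
    temperature differential above a paired control tent (sensor-array
    averaging, wireless paired-tent messages, reboot-on-error fault
    policy, CSV logging), a closed-loop paired-tent microclimate
    simulator with sensor fault injection, post-hoc environmental
    analysis (treatment differentials, sensor uniformity, hourly
    profiles, vapor pressure deficit), and the agronomic/grain-quality
    response pipeline (percent differences, per-degree-Celsius
    statistics, non-infected seed extrapolation, emergence metrics,
    split-plot ANOVA with Tukey grouping, check-line uniformity tests)
    together with a synthetic replicate-level trait generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
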