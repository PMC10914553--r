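Package: oxyreg
Title: Hypoxia Response Curve Analysis for Closed-System Respirometry
Version: 0.1.0
Authors@R: person("Opal", "Reefworks", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing closed-chamber oxygen drawdown experiments
    on aquatic organisms. Converts raw optode time series (percent air
    saturation) into blank- and volume-corrected oxygen consumption curves,
    fits a family of origin-constrained hypoxia response curve models
    (slope-only linear conformity, constrained polynomials up to degree 12,
    and two-parameter Michaelis-Menten kinetics) ranked by AIC, and extracts
    oxyregulation statistics (total positive regulation T_pos and the air
    saturation levels of maximum and minimum regulation effort, P_cmax and
    P_cmin) from the regulation function rho(x) = f(x)/x - f'(x). Also
    summarises in-situ dissolved oxygen logger deployments (time-at-DO
    histograms, interior-versus-exterior deltas, tide and diel alignment),
    provides the group comparisons used in reef hypoxia field studies, and
    ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
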