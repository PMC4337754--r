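Package: lochull
Title: Time-Aware Local Convex Hull Home Ranges and Time-Use Metrics
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constructs utilization distributions for animal relocation data
    from local convex hulls whose nearest neighbours are selected with a
    time-scaled distance metric, so that hulls are local in both space and
    time.  Provides the k/r/a neighbour rules, per-hull movement-phase
    metrics (perimeter-area ratio, eccentricity of the minimum-volume
    enclosing ellipse) and time-use metrics (revisitation rate and visit
    duration from an inter-visit gap), density and metric-sorted isopleths
    built by cumulative hull union, parameter-selection diagnostics
    (space-time parity, proportion of time-selected hulls, minimum
    proportion inclusion bounds, isopleth area and edge-to-area curves),
    and a nine-patch movement simulator with ground-truth labels for
    validating the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'mvee.R'
    'trajectory.R'
    'tsd.R'
    'hullset.R'
    'behavior.R'
    'isopleths.R'
    'simulator.R'
    'tuning.R'
    'io.R'
    'plots.R'
    'lochull-package.R'
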