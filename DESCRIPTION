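Package: dctraj
Title: Drift-Corrected Velocities and Trajectories for Satellite-Tracked Marine Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates the swimming velocity of satellite-tracked marine animals
    (juvenile sea turtles in particular) from their drift velocity using gridded
    surface-current and Stokes-drift reanalysis fields. Implements daily velocity
    over ground from midnight-interpolated positions, a leeway model in which
    drift is the Eulerian surface current plus a fitted fraction of the surface
    Stokes drift, drift-corrected (DC) velocities and trajectories, two-segment
    breakpoint detection with drifting/homing classification, annual sine fitting
    of meridional DC-trajectories with circular phase statistics, von Bertalanffy
    size imputation, a size-conditional homing probability curve, and a seedable
    synthetic ocean and track generator for end-to-end validation without
    restricted tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
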