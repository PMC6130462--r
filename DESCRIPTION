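Package: stillsgeom
Title: Multi-Panel Detector Geometry Refinement for Serial Crystallography Stills
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint refinement of a hierarchical multi-panel detector model
    against ensembles of still-shot crystal models, as used to calibrate
    pixel-array detectors (CSPAD-like quadrant/sensor/ASIC hierarchies) at
    XFEL and synchrotron serial-crystallography beamlines.  Provides the
    frame-transform algebra for hierarchical detectors, Ewald-sphere spot
    prediction for stills with the delta-psi restraint, rotational
    autocorrelation alignment of detector quadrants from virtual powder
    patterns, sparse Levenberg-Marquardt and LBFGS refinement engines over
    the joint detector-plus-crystals parameter space, staged hierarchical
    and expanding refinement protocols with reindexing cycles, time-batched
    ensemble refinement, and intensity-uncertainty inflation models for
    integrated still data.  Seeded synthetic-experiment generators with
    known ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
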