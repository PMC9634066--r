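Package: navsim
Title: Fuzzy-Oscillatory Simulator of Hippocampus-Prefrontal Map-Based Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested simulator of map-based spatial navigation built on the
    interaction between a hippocampal cognitive map and a medial prefrontal
    retrieval controller. Landmark identity is carried by frequency codes and
    recognized by resonance in a bank of driven Van der Pol oscillators (the
    "what" stream); egocentric landmark coordinates are population-coded by a
    polar grid of radial-basis neurons (the "where" stream); retrieval of the
    next subgoal is performed by a fuzzy lookup-table controller with Gaussian
    and S/Z membership functions, product inference and center-average
    defuzzification. A closed-loop agent with short-term-memory buffers
    reproduces healthy navigation, attention-deficit wrong-path excursions, and
    Alzheimer-type failure modes (spectral slowing of the oscillator bank and
    weighted path competition after retrieval failure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
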