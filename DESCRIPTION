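Package: skytuner
Title: Angular Tuning Analysis of Spike Trains from Sky-Compass Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the angular tuning of neuronal spike
    trains recorded during rotating visual stimuli, as used in insect
    sky-compass neurophysiology. Maps spike times to presented stimulus
    angles under clockwise/counterclockwise rotation protocols, computes
    circular and axial descriptive statistics (preferred angle Phi_max,
    mean vector length r, circular standard deviation, 95% confidence
    arcs), tests tuning significance by linear-circular correlation,
    classifies opponency against background activity, and quantifies
    rotation-direction-dependent mismatch of the preferred angle. Includes
    an inhomogeneous-Poisson simulator of polarization-sensitive and
    azimuth-sensitive neuron responses (cosine tuning, onset transients,
    opponent inhibition, anticipatory shift) so every analysis stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
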