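Package: mupsim
Title: Motor Unit Pool Simulation of Muscle Force by Twitch Summation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of skeletal muscle force as the linear sum of
    motor unit (MU) contractions. Each MU twitch is described by a six-parameter
    analytical curve (lead time, half-contraction, contraction, half-relaxation
    and total times, peak force); the force of one MU is the superposition of
    identical twitches triggered by its stimulus train, and whole-muscle force
    is the sum over the pool of slow (S), fast-fatigue-resistant (FR) and
    fast-fatigable (FF) units. Includes generators for regular/irregular and
    synchronous/asynchronous stimulation trains, size-principle
    recruitment/derecruitment schedules, a synthetic MU pool generator with
    inverse-power force-contraction-time structure, force-frequency and tetanic
    fusion analyses, plain-text pool and stimulation file formats, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
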