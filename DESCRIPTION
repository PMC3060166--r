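Package: antnav
Title: Decentralized Insect Navigation Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of decentralized insect navigation built
    from independent procedural memories: a path integrator maintaining a
    home-referenced current vector, gated reference-vector memories for
    multiple food sources, route-landmark elements with local vectors and a
    stepwise salience decay, snapshot-style place landmarks at nest and food
    sites, a recurrent motivation network of mutually inhibitory unit pairs
    that gates every memory, and a biased random-turn generator whose
    blending with path integration yields emergent area-concentrated search.
    Procedure outputs compete through feedforward lateral inhibition and are
    combined by weighted vector summation into a single heading. Includes
    canonical foraging, shortcut, displacement and zero-vector release
    scenarios, a randomized scenario generator, trajectory logging, and
    search-path analysis (radial density profiles, distance series).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
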