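Package: trapscape
Title: Optimal Mosquito Trap Placement via Absorbing Markov Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models mosquito movement across a discrete landscape of resource
    sites as an absorbing Markov chain in which traps are absorbing states,
    scores a trap configuration by the expected number of days until a
    mosquito is trapped (the row sums of the fundamental matrix), and
    optimizes trap positions with a genetic algorithm in both discrete
    (node-restricted) and continuous (free-coordinate) modes. Supports
    exponential, long-tailed and zero-inflated exponential dispersal kernels,
    resource-type masking matrices, exponential and sigmoidal trap
    attractiveness kernels, immovable traps, a Monte-Carlo random-walk
    validation oracle, exhaustive enumeration for small discrete instances,
    and synthetic landscape generators for testing surveillance designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
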