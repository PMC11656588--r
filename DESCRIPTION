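Package: cowspace
Title: Bioeconomic Simulation of Living Space Provision for Housed Dairy Cows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic cow-lifetime simulation comparing two housing
    living-space scenarios (3 m2 vs 6.5 m2 of living space per cow) for
    housed dairy herds. Simulates paired cow lifetimes (lactation curves,
    time to conception, gestation, dry periods, herd exit and replacement),
    computes the partial-budget financial-return difference between the
    scenarios, amortizes the capital cost of providing the extra space
    (new build, indoor or outdoor loafing-area extension) across an
    interest-rate and loan-term sensitivity grid, and decomposes the
    simulated returns with a standardized linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
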