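Package: emergyes
Title: Emergy-Based Ecosystem-Service Accounting and Driver Attribution
Version: 0.1.0
Authors@R: person("emergyes", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Donor-side valuation of ecosystem services as emergy flows
    (solar equivalent joules per year) for nine ecosystem classes and eleven
    services, with double-counting-safe totals, and a first-order
    partial-differential attribution method that decomposes the change in
    total ecosystem services between two epochs into natural-driver,
    cognition-driver and human-driver (land-use) contributions plus a
    residual. Includes vegetation-fraction area correction from NDVI, a
    renewable-emergy maximum rule, DALY/PDF impact-factor services, regional
    aggregation with report tables, a seeded synthetic-fixture generator and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
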