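Package: sccapacity
Title: Hospital Capacity and Quality Impact of Subcutaneous Versus
    Intravenous Oncology Drug Administration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic resource-utilization model for onco-hematology
    day units converting rituximab and trastuzumab from intravenous (IV) to
    subcutaneous (SC) administration. Computes case-mix-weighted patient
    time in hospital per month by route, four capacity parameters (chair
    and laminar-flow-hood time freed, converted to additional treatments
    and percentage capacity gains) and three quality parameters
    (hospital-time reduction, labor-productivity valuation, venous-access
    device reduction), applies current-practice and maximal-conversion
    scenarios to hospital profiles and aggregates across hospitals. Ships
    a seeded synthetic-hospital generator and a minute-resolution chair
    occupancy simulator used as an independent oracle for the analytic
    capacity formulas.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
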