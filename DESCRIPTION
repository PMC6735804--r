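Package: bfcost
Title: Country-Level Human and Economic Costs of Not Breastfeeding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates, per country and in aggregate, the morbidity, mortality,
    health-system treatment costs, household formula costs and discounted future
    economic losses attributable to not breastfeeding according to WHO/UNICEF
    recommendations. Attributable burden uses multi-category Levin population
    attributable fractions against a universal-breastfeeding counterfactual;
    treatment costs follow a care-seeking cascade with facility-level unit
    costs; future losses use the human capital approach (discounted earnings
    streams over productive years) for child mortality, maternal mortality and
    cognitive deficit, with discount-rate/growth-rate sensitivity scenarios and
    strict no-extrapolation aggregation over countries with available data.
    Includes a seeded synthetic country-data generator and file-based
    long-format CSV ingestion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
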