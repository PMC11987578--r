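Package: effcascade
Title: Effective Coverage Cascades for Antenatal Care and Maternal
    Nutrition from Linked Household and Facility Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates effective coverage cascades for antenatal care (ANC)
    and maternal nutrition services by ecologically linking household-survey
    care-seeking records to health-facility readiness and provision/experience
    of care scores. Implements additive readiness and quality indices,
    stratum-level score aggregation with national fallbacks, survey-weighted
    cascade step estimation (service contact for 1/4+/8+ visits,
    intervention coverage, readiness- and quality-adjusted coverage), Taylor
    linearisation variance for household-survey estimators and a two-survey
    delete-one-group jackknife for linked estimators, plus a synthetic survey
    generator with closed-form expected cascade values for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
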