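Package: movemetrics
Title: Wearable-Sensor Movement Health Metrics and Validation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extraction of kinematic performance metrics from annotated
    full-body motion-capture time series for five movement-health assessment
    activities (single leg balance, forward lunge, overhead squat, overhead
    reach, feet-together squat), scoring of thirteen reference functional
    movement tests, and the normality-gated correlation, group-comparison and
    test-retest reliability statistics used to validate an overall movement
    health score. Includes a seeded synthetic motion-capture cohort generator
    with a latent impairment parameter, so the full pipeline is testable
    end-to-end without human-subject data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
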