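Package: ethopeak
Title: Objective Behavior Classification from Accelerometry via Histogram
    Interpeak Minima
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns coarse-scale behaviors (e.g. flight, on land, on water;
    sitting, walking, running) to tri-axial accelerometer recordings using
    individual-specific thresholds located objectively at interpeak frequency
    minima of metric histograms. Computes the standard per-second movement and
    posture metrics (moving means and standard deviations per axis, pitch,
    roll, ODBA, VeDBA), runs a declarative stepwise classification plan with
    an optional bout-averaging constraint that forbids land/water transitions
    without intervening flight, and validates assignments by accuracy sweeps
    over candidate thresholds against known labels or salt-water-immersion
    ground truth. Includes a labeled synthetic-accelerometry generator so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
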