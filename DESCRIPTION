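Package: swaysom
Title: Two-Level Self-Organizing Map Clustering of Postural Sway from
    Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts tri-axial lower-back accelerometer recordings made
    under the four conditions of the modified Clinical Test of Sensory
    Interaction and Balance (mCTSIB) into mediolateral and
    anterior-posterior sway features via an inverted-pendulum ground
    projection, screens collinear features with normality-gated
    correlation, clusters subjects with a two-level scheme (batch-trained
    Kohonen self-organizing map followed by K-means over the active
    prototypes, with Davies-Bouldin guided selection of the cluster
    count), and quantifies between-condition sway differences with
    external cluster-validity measures (purity, precision, recall,
    F-measure) over repeated randomized clusterings.  Includes a
    synthetic-cohort generator emulating the quantized sensor stream so
    the full pipeline is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
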