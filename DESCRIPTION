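Package: pcptiles
Title: Layout Engines for Parallel Coordinate and Tiled One-Dimensional
    Exploratory Graphics
Version: 0.1.0
Authors@R:
    person("pcptiles", "developers", email = "pcptiles@example.org",
           role = c("aut", "cre"))
Description: Two complementary layout engines for exploratory data analysis
    of rectangular cohort data. Builds parallel-coordinate-plot geometry with
    axis ordering by polyline crossing minimisation (exact for small axis
    counts, greedy plus 2-opt above) or by mutual information with a
    categorical feature, and tiled one-dimensional stacked graphics (bars for
    numeric features, colour tiles for categorical ones) that mark every
    missing cell with an explicit glyph so multivariate missingness patterns
    are visible. Layout geometry is a first-class, testable object; SVG and
    single-file interactive HTML renderers, a command-line interface, and
    seeded synthetic-data generators (including a birdwatcher fixture whose
    missingness depends jointly on observer and day of week) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
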