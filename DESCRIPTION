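Package: dvmtrack
Title: Diel Vertical Migration Rates from Chlorophyll Fluorescence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates diel vertical migration (DVM) rates of a bloom-dominant
    phytoplankton species from repeated vertical chlorophyll-a fluorescence
    casts in a shallow water column. Calibrates raw sonde fluorescence against
    discrete extracted chlorophyll samples, averages profiles into fixed-width
    depth bins, normalizes each profile by its depth-integrated chlorophyll to
    obtain a relative-chlorophyll distribution that is invariant to cast-to-cast
    biomass heterogeneity, screens vertically homogeneous profiles with a
    coefficient-of-variation filter, tracks the depth of the relative-chlorophyll
    maximum through time, and segments the track into dawn ascent and dusk
    descent events with pairwise, mean, and maximum migration rates. Includes
    dominance gating from cell counts, a Spearman rank validation of relative
    chlorophyll as a proxy for the focal species' vertical position, and a
    one-dimensional conservative advection-diffusion simulator of a migrating
    chlorophyll layer with a cast-sampling observation operator for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
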