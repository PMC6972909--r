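Package: vegprecip
Title: Spatiotemporal Analysis of Vegetation Response to Precipitation Anomalies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the lagged and cumulative response of
    vegetation greenness (NDVI) to precipitation anomalies on gridded monthly
    data. Implements second-order partial correlation between NDVI and
    lagged/accumulated precipitation anomalies with temperature and radiation
    anomalies as control variables, a 4 time-lag by 6 cumulation-period design
    with per-pixel best-window maps, seasonal correlation modes, precipitation
    characteristic indices (mean annual precipitation, fraction of
    precipitation days, precipitation concentration index) with
    Angstrom-formula radiation estimation, binned-gradient and ecological-zone
    attribution of the correlation pattern, and a synthetic gridded-data
    generator with known embedded response structure for end-to-end
    validation. Gridded stacks are read and written as CF-style NetCDF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
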