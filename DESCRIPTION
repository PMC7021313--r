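Package: spcmix
Title: Mixed EWMA-MA Control Charts and Run-Length Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Statistical process control with mixed memory-type control
    charts. Implements the Shewhart, moving average (MA), exponentially
    weighted moving average (EWMA), MA-EWMA and EWMA-MA charts for
    monitoring a process mean, a vectorised Monte-Carlo run-length engine
    (ARL, SDRL, MRL with standard errors), calibration of control-limit
    coefficients to a target in-control average run length by bisection
    with common random numbers, and Phase-II monitoring of observed time
    series with known in-control parameters. Six in-control sampling
    families (normal, Laplace, logistic, Student t, exponential, gamma)
    with a standardized location-shift model are provided for performance
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
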