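Package: pigdepth
Title: Pig Weight and Body Size Estimation from Overhead Depth Images
Version: 0.1.0
Authors@R:
    person("pigdepth", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for fully automatic estimation of pig body weight and five
    body-size traits (shoulder width, shoulder height, hip width, hip height,
    body length) from overhead depth images of the pig back. Provides a
    parametric depth-scene simulator with analytically known labels, the
    depth-to-gray preprocessing chain, a model factory that turns
    classification CNN backbones into multiple-output regression networks
    with six parallel linear heads, a CPU training loop with the summed
    per-target mean-squared-error loss, evaluation metrics (RMSE, MAE, MRE,
    R-squared, total MSE, mean estimation time), the weighing-scale capture
    trigger, 16-bit depth PNG input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: zlib
Config/testthat/edition: 3
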