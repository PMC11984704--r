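Package: fatract
Title: White-Matter Tract FA Statistics and Obesity Biomarker Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable obesity biomarkers from diffusion-MRI
    fractional anisotropy (FA) images. Per-tract descriptive statistics are
    computed over an integer label atlas (the 50-tract ICBM-DTI-81 white-matter
    parcellation ships with the package), candidate tract measurements are
    screened by a two-condition rule (between-group Wilcoxon rank-sum
    significance and FDR-corrected Spearman correlation with body-mass index),
    and a randomized add/exclude stepwise search builds two linear models: a
    BMI quantification model and a normal-weight versus overweight/obese
    classifier. Model coefficients are assembled into tract-by-statistic
    biomarker matrices that can be serialized and applied to new subjects.
    A synthetic cohort generator with planted effects supports end-to-end
    testing and parameter-recovery studies without access to real imaging data.
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
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
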