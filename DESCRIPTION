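Package: mcdropconnect
Title: Monte Carlo DropConnect Uncertainty Estimation for Classification
    and Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximate Bayesian inference in small neural networks by
    imposing Bernoulli distributions directly on the weights (DropConnect)
    or on unit activations (Dropout) and keeping the masks active at test
    time.  Monte Carlo averaging of stochastic forward passes yields the
    posterior predictive; the mutual information between predictions and
    weights provides a per-item epistemic uncertainty score.  Includes the
    full uncertainty-evaluation toolkit built on that score:
    correct-certain / incorrect-uncertain ratios and uncertainty accuracy
    over threshold sweeps with area-under-curve summaries,
    Kolmogorov-Smirnov separation of correct and incorrect predictions,
    uncertainty-informed referral curves with a random-rejection baseline,
    semantic-segmentation scores (pixel accuracy, mean accuracy, mean IoU),
    confidence-percentile accuracy, and correctness / confidence map
    rendering.  Ships synthetic classification and segmentation generators
    plus tiny reference networks and an SGD trainer so the whole pipeline
    runs end to end on one CPU.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
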