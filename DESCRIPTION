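Package: conceptbuild
Title: Function-Learning Concept-Building Task Simulation and Learning-Approach Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates and analyses a bilinear (V-shaped) function-learning
    task used to classify learners as abstraction or exemplar concept
    builders, and relates the classification to self-reported deep and
    surface approaches to learning.  Provides the task engine (training
    blocks with feedback, extrapolation/interpolation transfer trials), a
    synthetic-cohort generator with configurable learner mixtures and
    survey couplings, the two-step learner classifier (non-learner
    screening by final-block mean absolute error, then comparison of the
    extrapolation-error confidence interval against a flat exemplar-model
    baseline), Likert scale scoring for the M-ASSIST and R-SPQ-2F
    instruments, and the full statistics suite: point-biserial and Pearson
    correlations, 2x2 mixed-design ANOVA with partial eta squared,
    BIC-approximated posterior probabilities of the null, and power
    analysis for correlation and F tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite, car, withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
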