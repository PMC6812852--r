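Package: imadyn
Title: Insect Muscle Activation Dynamics: Simulation, Fitting and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates isometric muscle force from motoneuron spike trains with
    five activation dynamics models used for insect (locust extensor tibiae)
    muscle: the second-order Hatze-Zakotnik calcium-cascade model with
    frequency-dependent twitch potentiation, its Hatze-van-Zandwijk sigmoid
    variant, the non-linear Wilson model, and the linear Zajac, Bluemel and
    third-order Wilson models. Includes spike-train construction and pulse
    shaping, fixed-step Runge-Kutta and exact-discretisation solvers,
    peak-force and half-maximal rise/decay metrics, frequency-response curves,
    the staged potentiation-fitting workflow and simultaneous non-linear
    least-squares fitting with random restarts, a synthetic-data generator that
    emulates per-animal stimulation protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
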