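Package: slowfastpp
Title: Stability and Bifurcations of a Discrete Slow-Fast Ratio-Dependent
    Predator-Prey Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analytical toolkit for the discrete-time slow-fast
    predator-prey map with ratio-dependent (Michaelis-Menten-Holling)
    functional response obtained by semidiscretization of the fast time-scale
    planar system.  Provides the map, its Jacobian and closed-form fixed
    points; Jury/Schur-Cohn classification of quadratic characteristic roots;
    stability classification of all fixed points with the critical surfaces
    epsilon0 and delta-star; center-manifold verification of the transcritical
    bifurcation at the predator-free equilibrium; Neimark-Sacker normal-form
    analysis at the coexistence equilibrium (eigenvalue path, transversality,
    nondegeneracy, normal-form coefficients and the direction discriminant L);
    and numerical dynamics: orbit iteration, maximal Lyapunov exponents by
    tangent-frame renormalization, bifurcation sweeps, and phase-portrait
    sampling.  All Taylor coefficients are computed by exact symbolic
    differentiation of the map, never transcribed.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
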