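Package: normdyn
Title: Coupled Dynamics of Actions, Personal Norms and Beliefs in Social Dilemmas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Agent-based simulation and analytic toolkit for the joint dynamics
    of actions, personal norms (attitudes) and first- and second-order beliefs
    about others in repeated social-dilemma games. Agents choose myopic best
    responses to a quadratic utility combining material payoffs with normative
    terms (cognitive dissonance, peer disapproval, conformity with peers and
    with an external authority), and revise attitudes and beliefs through
    linear recurrences (cognitive dissonance, social projection, learning,
    conformity). Includes named games (coordination, public goods with
    quadratic costs, common pool resource), heterogeneous population sampling,
    evolutionary game theory baselines (Nash equilibria, social optima), an
    exact linear fixed-point solver for the deterministic dynamics, and
    ensemble summary statistics (equilibrium means and dispersions, Kendall
    rank correlations, convergence half-times, norm tightness metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
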