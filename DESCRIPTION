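Package: instevo
Title: Evolution of Punishment Institutions in a Public Goods Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of the joint dynamics of an economic game
    and a political game. Agents with fixed strategies (cooperator or
    free-rider) play a public goods game with obligate peer punishment; the
    fine level is itself an evolving institution, updated each generation by
    a proposed amendment and a majority vote in which every agent compares
    forecasts of its own long-run payoff under the incumbent and candidate
    rules. Payoff-proportional (Wright-Fisher) reproduction closes the loop,
    so institutionalised punishment can emerge from zero and carry
    cooperators from rarity to fixation. Includes a deterministic
    expected-dynamics engine (used both as the agents' forecasting machinery
    and as a validation oracle for the stochastic simulator), replicate
    batches with median summaries, sensitivity sweeps over the proposal
    distribution, CSV/JSON-lines trajectory output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
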