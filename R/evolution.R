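#' Convert round payoffs to reproductive fitness
#'
#' Fitness is the raw payoff floored at `fitness_floor` so that
#' reproduction probabilities remain well defined when fines push payoffs
#' to or below zero. The floor preserves the ranking of all payoffs above
#' it and guarantees a strictly positive total.
#'
#' @param ledger An `instevo_ledger` (after any punishment).
#' @param params An [model_params()] object.
#' @return Numeric vector of strictly positive fitnesses, length N.
#' @export
payoffs_to_fitness <- function(ledger, params) {
  pmax(ledger$payoff, params$fitness_floor)
}

#' Produce the next generation by payoff-proportional reproduction
#'
#' Wright-Fisher by default: each of the N offspring draws its parent
#' independently with probability proportional to fitness, and inherits the
#' parent's fixed strategy; group size never changes and no mutation
#' occurs, so a strategy lost from the population cannot reappear. The
#' punishment level (an institution, not a trait) carries over unchanged.
#' The `"moran"` alternative performs N sequential birth-death events
#' (fitness-proportional birth, uniform death) per generation.
#'
#' @param state The current `instevo_state`.
#' @param fitness Fitness vector from [payoffs_to_fitness()].
#' @param params An [model_params()] object.
#' @return The next generation's `instevo_state` (generation incremented).
#' @export
reproduce_population <- function(state, fitness, params) {
  n <- length(state$cooperator)
  stopifnot(length(fitness) == n, all(fitness > 0))
  if (params$reproduction == "wright-fisher") {
    parents <- sample.int(n, n, replace = TRUE, prob = fitness)
    coop <- state$cooperator[parents]
  } else {
    coop <- state$cooperator
    w <- fitness
    for (i in seq_len(n)) {
      parent <- sample.int(n, 1L, prob = w)
      dead <- sample.int(n, 1L)
      coop[dead] <- coop[parent]
      # the newborn inherits its parent's current fitness weight
      w[dead] <- w[parent]
    }
  }
  population_state(coop, punishment_level = state$punishment_level,
                   generation = state$generation + 1L)
}
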