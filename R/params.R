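#' Model parameters for an institutional public-goods simulation
#'
#' Bundles every fixed constant of a run: the economics of the public goods
#' (PG) game, the punishment institution, the political game's proposal
#' distribution, the forecasting rule agents use when voting, and the
#' reproduction scheme. Defaults are the baseline configuration: each agent
#' holds a budget of 10 units, cooperators contribute 10% of it, the pot is
#' doubled and shared equally by all agents, a punished free-rider pays twice
#' the punisher's cost, the run starts with 5% cooperators and a fine of 0,
#' and runs for 1000 generations over 100 replicates.
#'
#' @param group_size Number of agents N (fixed across generations). Default
#'   5000; see the methods vignette for why the default population is large
#'   enough that selection, not drift, governs the fate of the initial
#'   cooperator minority.
#' @param budget Per-agent endowment b (currency units) received every
#'   generation. Default 10.
#' @param contribution_fraction Fraction of the budget a cooperator pays into
#'   the public pot, in (0, 1]. Default 0.10.
#' @param pot_multiplier Multiplier m applied to the pot before equal
#'   redistribution to all N agents. Default 2.
#' @param fine_ratio Fine paid by a punished free-rider per punishment act,
#'   as a multiple of the punisher's own cost v. Default 2.
#' @param proposal_sd Standard deviation (currency units) of the normal
#'   distribution from which the political game draws one candidate fine per
#'   generation, centred on the incumbent fine. Default 0.5, roughly the
#'   critical fine of the baseline economy, so effective amendments are
#'   reachable within a few draws.
#' @param initial_cooperator_fraction Fraction of cooperators at generation
#'   0; the realised count is `round(fraction * N)`. Default 0.05.
#' @param n_generations Generations per replicate G. Default 1000.
#' @param n_replicates Replicates per batch R. Default 100.
#' @param forecast_horizon Horizon scale H (generations) of the voting
#'   agents' foresight: the averaging window in `"horizon"` mode and one
#'   tenth of the projection cap in `"steady"` mode. Default 50.
#' @param forecast_mode `"steady"` (the default): voters compare the
#'   projected steady-state per-generation payoff of their type
#'   (convergence tolerance 1e-6, iteration cap `10 * H`), the
#'   perfect-long-term-prediction reading. `"horizon"`: voters compare the
#'   mean projected payoff over the next H generations.
#' @param fitness_floor Small positive value substituted for non-positive
#'   payoffs so reproduction probabilities stay well defined. Default 0.01.
#' @param master_seed Integer master seed; per-replicate streams are derived
#'   from it (see [run_replicate()]). Default 1.
#' @param voting If `FALSE` the political game is switched off and the fine
#'   is held at `fixed_punishment` for the whole run (used to validate the
#'   simulator against the deterministic projection). Default `TRUE`.
#' @param fixed_punishment Fine level used when `voting = FALSE`. Default 0.
#' @param reproduction `"wright-fisher"` (non-overlapping generations,
#'   multinomial resampling; the default) or `"moran"` (N sequential
#'   birth-death events per generation).
#' @param vote_order `"vote-then-play"` (default): the political game runs
#'   before the economic game each generation, so an accepted fine applies
#'   immediately. `"play-then-vote"` reverses the order for robustness
#'   checks.
#'
#' @return An object of class `instevo_params` (a validated list).
#' @examples
#' p <- model_params(group_size = 100, n_generations = 50, n_replicates = 3)
#' p
#' @export
model_params <- function(group_size = 5000,
                         budget = 10,
                         contribution_fraction = 0.10,
                         pot_multiplier = 2,
                         fine_ratio = 2,
                         proposal_sd = 0.5,
                         initial_cooperator_fraction = 0.05,
                         n_generations = 1000,
                         n_replicates = 100,
                         forecast_horizon = 50,
                         forecast_mode = c("steady", "horizon"),
                         fitness_floor = 0.01,
                         master_seed = 1L,
                         voting = TRUE,
                         fixed_punishment = 0,
                         reproduction = c("wright-fisher", "moran"),
                         vote_order = c("vote-then-play", "play-then-vote")) {
  p <- list(
    group_size = as.integer(group_size),
    budget = as.numeric(budget),
    contribution_fraction = as.numeric(contribution_fraction),
    pot_multiplier = as.numeric(pot_multiplier),
    fine_ratio = as.numeric(fine_ratio),
    proposal_sd = as.numeric(proposal_sd),
    initial_cooperator_fraction = as.numeric(initial_cooperator_fraction),
    n_generations = as.integer(n_generations),
    n_replicates = as.integer(n_replicates),
    forecast_horizon = as.integer(forecast_horizon),
    forecast_mode = match.arg(forecast_mode),
    fitness_floor = as.numeric(fitness_floor),
    master_seed = as.integer(master_seed),
    voting = isTRUE(voting),
    fixed_punishment = as.numeric(fixed_punishment),
    reproduction = match.arg(reproduction),
    vote_order = match.arg(vote_order)
  )
  class(p) <- "instevo_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks every invariant of [model_params()] and fails with an error naming
#' the offending field. Called by all entry points that accept parameters.
#'
#' @param params An `instevo_params` object (or bare list with the same
#'   fields).
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  fail <- function(field, constraint, value) {
    stop(sprintf("invalid parameter `%s`: %s (got %s)",
                 field, constraint, deparse(value)), call. = FALSE)
  }
  chk <- function(field, ok, constraint) {
    v <- params[[field]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !ok(v)) {
      fail(field, constraint, params[[field]])
    }
  }
  chk("group_size", function(x) x >= 2, "must be an integer >= 2")
  chk("budget", function(x) x > 0, "must be > 0")
  chk("contribution_fraction", function(x) x > 0 && x <= 1,
      "must lie in (0, 1]")
  chk("pot_multiplier", function(x) x >= 1, "must be >= 1")
  chk("fine_ratio", function(x) x >= 0, "must be >= 0")
  chk("proposal_sd", function(x) x >= 0, "must be >= 0")
  chk("initial_cooperator_fraction", function(x) x >= 0 && x <= 1,
      "must lie in [0, 1]")
  chk("n_generations", function(x) x >= 1, "must be a positive integer")
  chk("n_replicates", function(x) x >= 1, "must be a positive integer")
  chk("forecast_horizon", function(x) x >= 1, "must be a positive integer")
  chk("fitness_floor", function(x) x > 0, "must be > 0")
  chk("fixed_punishment", function(x) x >= 0, "must be >= 0")
  chk("master_seed", function(x) is.finite(x), "must be a finite integer")
  invisible(params)
}

#' @export
print.instevo_params <- function(x, ...) {
  cat("Institutional public-goods model parameters\n")
  cat(sprintf("  group size N:        %d\n", x$group_size))
  cat(sprintf("  budget b:            %g   contribution: %g%% (a = %g)\n",
              x$budget, 100 * x$contribution_fraction,
              x$contribution_fraction * x$budget))
  cat(sprintf("  pot multiplier m:    %g   fine ratio: %g\n",
              x$pot_multiplier, x$fine_ratio))
  cat(sprintf("  proposal sd:         %g   voting: %s\n",
              x$proposal_sd,
              if (x$voting) x$vote_order else
                sprintf("disabled (fine fixed at %g)", x$fixed_punishment)))
  cat(sprintf("  forecast:            %s, horizon %d\n",
              x$forecast_mode, x$forecast_horizon))
  cat(sprintf("  initial cooperators: %g%%   generations: %d   replicates: %d\n",
              100 * x$initial_cooperator_fraction, x$n_generations,
              x$n_replicates))
  cat(sprintf("  reproduction:        %s   fitness floor: %g   seed: %d\n",
              x$reproduction, x$fitness_floor, x$master_seed))
  invisible(x)
}
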