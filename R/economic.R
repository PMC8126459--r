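#' Create a population state
#'
#' @param cooperator Logical vector of length N: `TRUE` for cooperators,
#'   `FALSE` for free-riders. Strategies are fixed for an agent's lifetime;
#'   composition changes only through reproduction.
#' @param punishment_level Current institutional fine parameter v (the cost
#'   paid by an obligate punisher per act; a punished free-rider pays
#'   `fine_ratio * v`). Must be >= 0.
#' @param generation Non-negative generation index.
#' @return An object of class `instevo_state`.
#' @export
population_state <- function(cooperator, punishment_level = 0,
                             generation = 0L) {
  stopifnot(is.logical(cooperator), length(cooperator) >= 2,
            !anyNA(cooperator), punishment_level >= 0, generation >= 0)
  structure(list(cooperator = cooperator,
                 punishment_level = as.numeric(punishment_level),
                 generation = as.integer(generation)),
            class = "instevo_state")
}

#' Initialise the generation-0 population
#'
#' Places exactly `round(initial_cooperator_fraction * N)` cooperators at
#' uniformly random positions (the count is deterministic so the stated
#' starting condition is exact; only placement is random) and sets the fine
#' to 0: the run begins with no punishment institution.
#'
#' @param params An [model_params()] object.
#' @return An `instevo_state` with `generation = 0` and
#'   `punishment_level = 0`.
#' @export
init_population <- function(params) {
  validate_params(params)
  n <- params$group_size
  n_coop <- as.integer(round(params$initial_cooperator_fraction * n))
  coop <- rep(FALSE, n)
  if (n_coop > 0) coop[sample.int(n, n_coop)] <- TRUE
  population_state(coop, punishment_level = 0, generation = 0L)
}

#' @export
print.instevo_state <- function(x, ...) {
  n <- length(x$cooperator)
  cat(sprintf(
    "Population state: generation %d, N = %d (%d cooperators, %d free-riders), fine v = %g\n",
    x$generation, n, sum(x$cooperator), n - sum(x$cooperator),
    x$punishment_level))
  invisible(x)
}

#' Play one round of the public goods game
#'
#' Each cooperator contributes `a = contribution_fraction * budget` to the
#' pot; the pot is multiplied by `pot_multiplier` and redistributed equally
#' to all N agents (contributors included). Base payoffs are therefore
#' `b - a + m C / N` for cooperators and `b + m C / N` for free-riders,
#' with `C = a * n_c`. No punishment is applied at this stage.
#'
#' @param state An `instevo_state`.
#' @param params An [model_params()] object.
#' @return An object of class `instevo_ledger`: list with `contribution`,
#'   `total_pot`, `share_per_agent`, `payoff` (length-N numeric),
#'   `n_cooperators`, `n_free_riders`, `punishment_level` (0 until
#'   [apply_punishment()] runs) and `assignments` (`NULL` until then).
#' @examples
#' p <- model_params(group_size = 4)
#' s <- population_state(c(TRUE, TRUE, FALSE, FALSE))
#' play_economic_game(s, p)$payoff
#' @export
play_economic_game <- function(state, params) {
  validate_params(params)
  coop <- state$cooperator
  n <- length(coop)
  if (n != params$group_size) {
    stop(sprintf("invalid parameter `group_size`: state has %d agents but params declare %d",
                 n, params$group_size), call. = FALSE)
  }
  a <- params$contribution_fraction * params$budget
  n_c <- sum(coop)
  pot <- a * n_c
  share <- params$pot_multiplier * pot / n
  payoff <- params$budget + share - a * as.numeric(coop)
  structure(list(contribution = a,
                 total_pot = pot,
                 share_per_agent = share,
                 payoff = payoff,
                 n_cooperators = as.integer(n_c),
                 n_free_riders = as.integer(n - n_c),
                 punishment_level = 0,
                 assignments = NULL),
            class = "instevo_ledger")
}

#' Select obligate punishers for every free-rider
#'
#' One punisher is drawn for each free-rider in the round, uniformly at
#' random over all other agents (self-punishment excluded; both cooperators
#' and free-riders are eligible, and the same agent may be selected to
#' punish several free-riders, paying the cost once per act).
#'
#' @param state An `instevo_state`.
#' @param ledger The `instevo_ledger` from [play_economic_game()].
#' @return A two-column integer matrix with one row per free-rider:
#'   `punisher` and `target`. Zero rows when there are no free-riders.
#' @export
select_punishers <- function(state, ledger) {
  n <- length(state$cooperator)
  if (n < 2) stop("punisher selection requires at least 2 agents", call. = FALSE)
  targets <- which(!state$cooperator)
  n_f <- length(targets)
  if (n_f == 0L) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("punisher", "target"))))
  }
  # draw uniformly over the n-1 non-target agents: draw an index in
  # 1..(n-1) and shift past the target's own position
  raw <- sample.int(n - 1L, n_f, replace = TRUE)
  punisher <- raw + (raw >= targets)
  cbind(punisher = as.integer(punisher), target = as.integer(targets))
}

#' Apply punishment costs and fines to a round ledger
#'
#' Every punisher pays `v` per act performed; every punished free-rider pays
#' `fine_ratio * v`. Payoffs may go negative; they are floored only later,
#' in reproduction, so that ledger accounting stays exact: the post-round
#' total is `N b + (m - 1) C - (1 + fine_ratio) v n_f`.
#'
#' @param ledger An `instevo_ledger` from [play_economic_game()].
#' @param assignments Punisher/target matrix from [select_punishers()].
#' @param v Punishment level (punisher cost per act), >= 0.
#' @param params An [model_params()] object.
#' @return The ledger with updated `payoff`, `punishment_level` and
#'   `assignments`.
#' @export
apply_punishment <- function(ledger, assignments, v, params) {
  stopifnot(v >= 0)
  if (v == 0 || nrow(assignments) == 0L) {
    ledger$punishment_level <- v
    ledger$assignments <- assignments
    return(ledger)
  }
  n <- length(ledger$payoff)
  acts <- tabulate(assignments[, "punisher"], nbins = n)
  payoff <- ledger$payoff - v * acts
  payoff[assignments[, "target"]] <-
    payoff[assignments[, "target"]] - params$fine_ratio * v
  ledger$payoff <- payoff
  ledger$punishment_level <- v
  ledger$assignments <- assignments
  ledger
}
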