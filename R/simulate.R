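#' Advance the simulation by one generation
#'
#' Executes the per-generation event loop. Under the default
#' `"vote-then-play"` order: (1) one candidate fine is proposed and voted
#' on, so an accepted amendment applies immediately; (2) the public goods
#' game is played; (3) if the fine is positive and free-riders are present,
#' punishers are selected and punishment applied; (4) payoffs become
#' fitness and the next generation is sampled. A single RNG stream drives
#' the stochastic steps in that fixed order (proposal draw, punisher
#' selection, reproduction).
#'
#' @param state Current `instevo_state`.
#' @param params An [model_params()] object.
#' @param cache Optional forecast-memoisation environment (see
#'   [vote_on_proposal()]).
#' @return A list with `state` (the next generation) and `record`, a named
#'   list holding this generation's trajectory row: `generation`,
#'   `cooperator_fraction`, `punishment_level`, `proposal_value`,
#'   `proposal_accepted`, `mean_payoff_cooperator`,
#'   `mean_payoff_free_rider` (type means are `NA` when the type is
#'   absent).
#' @export
run_generation <- function(state, params, cache = NULL) {
  coop <- state$cooperator
  n <- length(coop)
  n_c <- sum(coop)

  proposal_value <- NA_real_
  proposal_accepted <- NA

  do_vote <- function(state) {
    proposal <- propose_fine(state$punishment_level, params,
                             generation = state$generation)
    vote <- vote_on_proposal(state, proposal, params, cache)
    proposal_value <<- proposal$candidate_v
    proposal_accepted <<- vote$accepted
    if (vote$accepted) state$punishment_level <- proposal$candidate_v
    state
  }

  if (params$voting && params$vote_order == "vote-then-play") {
    state <- do_vote(state)
  }

  ledger <- play_economic_game(state, params)
  v <- state$punishment_level
  if (v > 0 && ledger$n_free_riders > 0L) {
    assignments <- select_punishers(state, ledger)
    ledger <- apply_punishment(ledger, assignments, v, params)
  }

  record <- list(
    generation = state$generation,
    cooperator_fraction = n_c / n,
    punishment_level = v,
    mean_payoff_cooperator =
      if (n_c > 0L) mean(ledger$payoff[coop]) else NA_real_,
    mean_payoff_free_rider =
      if (n_c < n) mean(ledger$payoff[!coop]) else NA_real_
  )

  if (params$voting && params$vote_order == "play-then-vote") {
    state <- do_vote(state)
  }
  record$proposal_value <- proposal_value
  record$proposal_accepted <- proposal_accepted

  fitness <- payoffs_to_fitness(ledger, params)
  next_state <- reproduce_population(state, fitness, params)
  list(state = next_state, record = record)
}

# counter-based derivation of one 32-bit seed per replicate, so changing
# the replicate count never perturbs earlier replicates
derive_seed <- function(master_seed, replicate_id) {
  s <- (as.numeric(master_seed) %% 2147483647 +
          2654435761 * as.numeric(replicate_id)) %% 2147483647
  as.integer(s)
}

#' Run one replicate of the full simulation
#'
#' Initialises the population with exactly
#' `round(initial_cooperator_fraction * N)` cooperators and a fine of 0
#' (or `fixed_punishment` when voting is disabled), then runs
#' `n_generations` generations. Each replicate uses its own RNG substream
#' derived from `(master_seed, replicate_id)` by a counter-based scheme, so
#' replicates are mutually independent and individually reproducible; the
#' caller's RNG state is restored on exit.
#'
#' @param params An [model_params()] object.
#' @param replicate_id Integer replicate label (>= 1).
#' @return A data frame with one row per generation and columns
#'   `replicate`, `generation`, `cooperator_fraction`, `punishment_level`,
#'   `proposal_value`, `proposal_accepted`, `mean_payoff_cooperator`,
#'   `mean_payoff_free_rider`.
#' @export
run_replicate <- function(params, replicate_id = 1L) {
  validate_params(params)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(derive_seed(params$master_seed, replicate_id))

  state <- init_population(params)
  if (!params$voting) state$punishment_level <- params$fixed_punishment
  cache <- new.env(parent = emptyenv())

  g <- params$n_generations
  cooperator_fraction <- numeric(g)
  punishment_level <- numeric(g)
  proposal_value <- numeric(g)
  proposal_accepted <- logical(g)
  mp_c <- numeric(g)
  mp_f <- numeric(g)
  for (t in seq_len(g)) {
    step <- run_generation(state, params, cache)
    r <- step$record
    cooperator_fraction[t] <- r$cooperator_fraction
    punishment_level[t] <- r$punishment_level
    proposal_value[t] <- r$proposal_value
    proposal_accepted[t] <- r$proposal_accepted
    mp_c[t] <- r$mean_payoff_cooperator
    mp_f[t] <- r$mean_payoff_free_rider
    state <- step$state
  }
  data.frame(replicate = as.integer(replicate_id),
             generation = 0:(g - 1L),
             cooperator_fraction = cooperator_fraction,
             punishment_level = punishment_level,
             proposal_value = proposal_value,
             proposal_accepted = proposal_accepted,
             mean_payoff_cooperator = mp_c,
             mean_payoff_free_rider = mp_f)
}

#' Run a batch of replicates and summarise it
#'
#' Runs `n_replicates` independent replicates (each on its own derived RNG
#' substream, so results do not depend on execution order) and computes
#' per-generation medians across replicates in the style of the headline
#' figure: median fine, median cooperator fraction, median type payoffs.
#'
#' @param params An [model_params()] object.
#' @return An object of class `instevo_sim`: list with `records` (all
#'   trajectory rows, sorted by replicate then generation), `summary` (an
#'   `instevo_summary`, see [summarize_trajectories()]) and `params`.
#' @examples
#' p <- model_params(group_size = 50, n_generations = 30, n_replicates = 2,
#'                   forecast_horizon = 100)
#' sim <- run_batch(p)
#' sim
#' @export
run_batch <- function(params) {
  validate_params(params)
  reps <- lapply(seq_len(params$n_replicates),
                 function(i) run_replicate(params, i))
  records <- do.call(rbind, reps)
  structure(list(records = records,
                 summary = summarize_trajectories(records),
                 params = params),
            class = "instevo_sim")
}

#' Median trajectory summary across replicates
#'
#' @param records Trajectory data frame as produced by [run_replicate()] /
#'   [run_batch()] (possibly re-read from disk).
#' @param probs Additional quantiles reported for the cooperator fraction
#'   and the fine. Default `c(0.25, 0.75)`.
#' @return An object of class `instevo_summary`: list with
#'   `by_generation` (per-generation medians and quantiles across
#'   replicates; type-payoff medians ignore replicates where the type is
#'   extinct) and `final` (per-replicate final state plus extinction
#'   tallies `n_freerider_extinct`, `n_cooperator_extinct`,
#'   `n_replicates`).
#' @export
summarize_trajectories <- function(records, probs = c(0.25, 0.75)) {
  stopifnot(nrow(records) > 0)
  gen <- sort(unique(records$generation))
  med_by_gen <- function(col) {
    unname(tapply(records[[col]], records$generation,
                  stats::median, na.rm = TRUE)[as.character(gen)])
  }
  q_by_gen <- function(col, q) {
    unname(tapply(records[[col]], records$generation, stats::quantile,
                  probs = q, na.rm = TRUE, names = FALSE)[as.character(gen)])
  }
  by_generation <- data.frame(
    generation = gen,
    med_cooperator_fraction = med_by_gen("cooperator_fraction"),
    med_punishment_level = med_by_gen("punishment_level"),
    med_payoff_cooperator = med_by_gen("mean_payoff_cooperator"),
    med_payoff_free_rider = med_by_gen("mean_payoff_free_rider")
  )
  for (q in probs) {
    by_generation[[sprintf("q%02d_cooperator_fraction", round(100 * q))]] <-
      q_by_gen("cooperator_fraction", q)
    by_generation[[sprintf("q%02d_punishment_level", round(100 * q))]] <-
      q_by_gen("punishment_level", q)
  }
  last <- records[records$generation == max(records$generation), ]
  last <- last[order(last$replicate), ]
  final <- data.frame(replicate = last$replicate,
                      cooperator_fraction = last$cooperator_fraction,
                      punishment_level = last$punishment_level)
  structure(list(by_generation = by_generation,
                 final = final,
                 n_replicates = nrow(final),
                 n_freerider_extinct = sum(final$cooperator_fraction == 1),
                 n_cooperator_extinct = sum(final$cooperator_fraction == 0),
                 probs = probs),
            class = "instevo_summary")
}

#' @export
print.instevo_summary <- function(x, ...) {
  bg <- x$by_generation
  fin <- bg[nrow(bg), ]
  cat(sprintf("Trajectory summary over %d replicates x %d generations\n",
              x$n_replicates, nrow(bg)))
  cat(sprintf("  final medians: cooperator fraction %.3f, fine %.3f\n",
              fin$med_cooperator_fraction, fin$med_punishment_level))
  cat(sprintf("  free-riders extinct in %d/%d replicates; cooperators extinct in %d/%d\n",
              x$n_freerider_extinct, x$n_replicates,
              x$n_cooperator_extinct, x$n_replicates))
  invisible(x)
}

#' @export
print.instevo_sim <- function(x, ...) {
  cat(sprintf("Institutional public-goods simulation (N = %d, sigma = %g, seed = %d)\n",
              x$params$group_size, x$params$proposal_sd,
              x$params$master_seed))
  print(x$summary)
  invisible(x)
}

#' @export
summary.instevo_sim <- function(object, ...) object$summary

#' Plot the median trajectories of a simulation batch
#'
#' Four base-graphics panels: median fine over generations (with one
#' example replicate in grey), median cooperator fraction, and median
#' per-type payoffs with the analytic critical fine era marked.
#'
#' @param x An `instevo_sim` object.
#' @param example_replicate Replicate whose raw fine trajectory is overlaid
#'   on the median fine panel. Default 1.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.instevo_sim <- function(x, example_replicate = 1L, ...) {
  bg <- x$summary$by_generation
  rec <- x$records
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ex <- rec[rec$replicate == example_replicate, ]
  graphics::plot(bg$generation, bg$med_punishment_level, type = "n",
                 xlab = "generation", ylab = "fine v",
                 main = "punishment level")
  graphics::lines(ex$generation, ex$punishment_level, col = "grey70")
  graphics::lines(bg$generation, bg$med_punishment_level, lwd = 2)
  graphics::abline(h = critical_fine(x$params), lty = 2, col = "red")
  graphics::plot(bg$generation, bg$med_cooperator_fraction, type = "l",
                 lwd = 2, col = "blue", ylim = c(0, 1),
                 xlab = "generation", ylab = "cooperator fraction",
                 main = "cooperation")
  graphics::plot(bg$generation, bg$med_payoff_cooperator, type = "l",
                 lwd = 2, col = "blue", xlab = "generation",
                 ylab = "mean payoff", main = "payoffs by type")
  graphics::lines(bg$generation, bg$med_payoff_free_rider, lwd = 2,
                  col = "red")
  graphics::legend("bottomright", legend = c("cooperator", "free-rider"),
                   col = c("blue", "red"), lwd = 2, bty = "n")
  graphics::plot(bg$generation,
                 bg$med_payoff_cooperator - bg$med_payoff_free_rider,
                 type = "l", lwd = 2, xlab = "generation",
                 ylab = "cooperator - free-rider payoff",
                 main = "payoff advantage")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Sensitivity sweep over the proposal standard deviation
#'
#' Re-runs [run_batch()] at each value of `sd_grid` with otherwise
#' identical parameters and the same master seed (common random numbers
#' across grid points), and tabulates how often free-riders are removed
#' from the population. The default grid spans proposal spreads too small
#' for any candidate to reach the critical fine up to spreads that exceed
#' it easily.
#'
#' @param params An [model_params()] object.
#' @param sd_grid Non-empty numeric vector of proposal standard deviations
#'   (>= 0).
#' @return An object of class `instevo_sweep`: data frame with one row per
#'   sigma and columns `proposal_sd`, `freerider_extinction_fraction`,
#'   `cooperator_extinction_fraction`,
#'   `median_final_cooperator_fraction`, `median_final_punishment_level`.
#' @export
sensitivity_sweep <- function(params,
                              sd_grid = c(0, 0.05, 0.1, 0.2, 0.5, 1)) {
  stopifnot(length(sd_grid) > 0, all(sd_grid >= 0))
  rows <- lapply(sd_grid, function(s) {
    p <- params
    p$proposal_sd <- as.numeric(s)
    sm <- run_batch(p)$summary
    data.frame(
      proposal_sd = as.numeric(s),
      freerider_extinction_fraction = sm$n_freerider_extinct / sm$n_replicates,
      cooperator_extinction_fraction = sm$n_cooperator_extinct / sm$n_replicates,
      median_final_cooperator_fraction =
        stats::median(sm$final$cooperator_fraction),
      median_final_punishment_level =
        stats::median(sm$final$punishment_level))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("instevo_sweep", "data.frame")
  out
}

#' Audit accepted proposals made under a free-rider majority
#'
#' The mechanism by which punishment first takes hold is that an amendment
#' passes while free-riders still hold the majority only when it gives
#' (i) an immediate expected payoff advantage to cooperators and (ii) a
#' better forecast long-run payoff to free-riders than the incumbent fine.
#' This audit recomputes both conditions (deterministically, from the
#' recorded composition and fine levels) for every accepted proposal in a
#' trajectory table where `0 < cooperator_fraction < 0.5`. All-free-rider
#' states are excluded: once cooperators are extinct the population
#' rationally repeals the fine step by step, and condition (i) is
#' meaningless with no cooperators present.
#'
#' @param x An `instevo_sim` object or its `records` data frame.
#' @param params Parameters of the run (taken from `x` when it is an
#'   `instevo_sim`).
#' @return Data frame with one row per audited acceptance: `replicate`,
#'   `generation`, `cooperator_fraction`, `incumbent_v`, `candidate_v`,
#'   `immediate_cooperator_advantage`, `freerider_forecast_gain` (both
#'   logical) and the underlying numeric gaps.
#' @export
audit_acceptances <- function(x, params = NULL) {
  if (inherits(x, "instevo_sim")) {
    params <- x$params
    records <- x$records
  } else {
    records <- x
    if (is.null(params)) stop("params required when auditing a raw table",
                              call. = FALSE)
  }
  recs <- records[order(records$replicate, records$generation), ]
  out <- list()
  for (rep_id in unique(recs$replicate)) {
    rr <- recs[recs$replicate == rep_id, ]
    hit <- which(!is.na(rr$proposal_accepted) & rr$proposal_accepted &
                   rr$cooperator_fraction > 0 & rr$cooperator_fraction < 0.5)
    for (i in hit) {
      cand <- rr$proposal_value[i]
      incumbent <- if (params$vote_order == "vote-then-play") {
        if (i == 1L) 0 else rr$punishment_level[i - 1L]
      } else {
        rr$punishment_level[i]
      }
      p <- rr$cooperator_fraction[i]
      ep <- expected_payoffs(p, cand, params)
      f_cand <- forecast_engine(p, cand, params, params$forecast_horizon,
                                params$forecast_mode)
      f_inc <- forecast_engine(p, incumbent, params, params$forecast_horizon,
                               params$forecast_mode)
      out[[length(out) + 1L]] <- data.frame(
        replicate = rep_id,
        generation = rr$generation[i],
        cooperator_fraction = p,
        incumbent_v = incumbent,
        candidate_v = cand,
        immediate_gap = ep$cooperator - ep$free_rider,
        forecast_gain = f_cand$free_rider - f_inc$free_rider,
        immediate_cooperator_advantage = ep$cooperator > ep$free_rider,
        freerider_forecast_gain = f_cand$free_rider > f_inc$free_rider)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(replicate = integer(0), generation = integer(0),
                      cooperator_fraction = numeric(0),
                      incumbent_v = numeric(0), candidate_v = numeric(0),
                      immediate_gap = numeric(0), forecast_gain = numeric(0),
                      immediate_cooperator_advantage = logical(0),
                      freerider_forecast_gain = logical(0)))
  }
  do.call(rbind, out)
}
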