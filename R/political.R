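#' Propose a candidate punishment level
#'
#' One amendment per generation: the candidate fine is drawn from a normal
#' distribution centred on the incumbent level with standard deviation
#' `proposal_sd` (a local, mutation-like search of the rule space), then
#' clamped at 0 since fines cannot be negative. Proposals are exogenous
#' draws — no agent authors them.
#'
#' @param incumbent_v Current punishment level, >= 0.
#' @param params An [model_params()] object.
#' @param generation Generation index recorded on the proposal.
#' @return An object of class `instevo_proposal`: list with `candidate_v`
#'   (clamped), `raw_draw` and `generation`.
#' @export
propose_fine <- function(incumbent_v, params, generation = NA_integer_) {
  stopifnot(incumbent_v >= 0)
  raw <- stats::rnorm(1, mean = incumbent_v, sd = params$proposal_sd)
  structure(list(candidate_v = max(raw, 0),
                 raw_draw = raw,
                 generation = as.integer(generation)),
            class = "instevo_proposal")
}

#' @export
print.instevo_proposal <- function(x, ...) {
  cat(sprintf("Proposal: candidate fine %g (raw draw %g)\n",
              x$candidate_v, x$raw_draw))
  invisible(x)
}

#' Vote on a proposed punishment level
#'
#' Every agent compares the forecast long-run payoff of its own strategy
#' type under the incumbent and candidate fines (via [forecast_payoff()])
#' and votes to accept iff the candidate forecast is strictly higher;
#' indifference counts as a vote for the status quo. The amendment passes
#' on a strict majority (> N/2). Because agents of the same type share the
#' same forecast, the outcome is a pure function of the cooperator
#' fraction, the two fine levels and the parameters.
#'
#' @param state An `instevo_state`.
#' @param proposal An `instevo_proposal`.
#' @param params An [model_params()] object.
#' @param cache Optional environment used to memoise forecasts keyed by
#'   (cooperator count, fine); [run_replicate()] passes one so incumbent
#'   forecasts are not recomputed every generation.
#' @return An object of class `instevo_vote`: list with `votes_accept`,
#'   `votes_reject`, `accepted`, `incumbent_v`, `candidate_v` and
#'   `forecasts` (2 x 2 numeric matrix, types x \{incumbent, candidate\}).
#' @export
vote_on_proposal <- function(state, proposal, params, cache = NULL) {
  n <- length(state$cooperator)
  n_c <- sum(state$cooperator)
  n_f <- n - n_c
  inc <- state$punishment_level
  cand <- proposal$candidate_v
  p <- n_c / n

  if (cand == inc) {
    # degenerate amendment: everyone indifferent, status quo retained
    fc <- cached_forecast(p, n_c, inc, params, cache)
    forecasts <- matrix(c(fc$cooperator, fc$free_rider,
                          fc$cooperator, fc$free_rider), nrow = 2,
                        dimnames = list(c("cooperator", "free_rider"),
                                        c("incumbent", "candidate")))
    return(structure(list(votes_accept = 0L, votes_reject = as.integer(n),
                          accepted = FALSE, incumbent_v = inc,
                          candidate_v = cand, forecasts = forecasts),
                     class = "instevo_vote"))
  }

  f_inc <- cached_forecast(p, n_c, inc, params, cache)
  f_cand <- cached_forecast(p, n_c, cand, params, cache)
  coop_accepts <- f_cand$cooperator > f_inc$cooperator
  free_accepts <- f_cand$free_rider > f_inc$free_rider
  votes_accept <- n_c * coop_accepts + n_f * free_accepts
  forecasts <- matrix(c(f_inc$cooperator, f_inc$free_rider,
                        f_cand$cooperator, f_cand$free_rider), nrow = 2,
                      dimnames = list(c("cooperator", "free_rider"),
                                      c("incumbent", "candidate")))
  structure(list(votes_accept = as.integer(votes_accept),
                 votes_reject = as.integer(n - votes_accept),
                 accepted = votes_accept > n / 2,
                 incumbent_v = inc,
                 candidate_v = cand,
                 forecasts = forecasts),
            class = "instevo_vote")
}

cached_forecast <- function(p, n_c, v, params, cache) {
  if (is.null(cache)) {
    return(forecast_engine(p, v, params, params$forecast_horizon,
                           params$forecast_mode))
  }
  key <- sprintf("%d|%.15g", n_c, v)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- forecast_engine(p, v, params, params$forecast_horizon,
                         params$forecast_mode)
  cache[[key]] <- res
  res
}

#' @export
print.instevo_vote <- function(x, ...) {
  cat(sprintf("Vote on fine %g vs incumbent %g: %d accept / %d reject -> %s\n",
              x$candidate_v, x$incumbent_v, x$votes_accept, x$votes_reject,
              if (x$accepted) "ACCEPTED" else "rejected"))
  invisible(x)
}
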