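#' Expected per-generation payoffs by strategy type
#'
#' Closed-form focal-agent expectations: the focal agent's own type is held
#' fixed while the other N - 1 agents are cooperators with probability `p`.
#' A focal cooperator earns `b - a + m a ((N-1) p + 1) / N`; a focal
#' free-rider earns `b + m a (N-1) p / N` and, whenever the fine is active,
#' pays `fine_ratio * v` once per round (every free-rider is punished
#' exactly once). Under the uniform punisher-selection convention the
#' expected obligate-punisher cost is `v (1 - p)` for both types: a focal
#' cooperator is eligible for all `(N-1)(1-p)` punishment slots with
#' probability `1/(N-1)` each, a focal free-rider for all slots but its own.
#' The self-exclusion asymmetry cancels exactly at finite N.
#'
#' @param p Cooperator fraction among the other agents, in \[0, 1\].
#'   Vectorised.
#' @param v Punishment level (punisher cost per act), >= 0.
#' @param params An [model_params()] object.
#' @return A list with numeric components `cooperator` and `free_rider`
#'   (same length as `p`).
#' @examples
#' p <- model_params(group_size = 100)
#' expected_payoffs(1, 0.5, p)$cooperator  # 11: full pot, no free-riders
#' @export
expected_payoffs <- function(p, v, params) {
  stopifnot(all(p >= 0 & p <= 1), all(v >= 0))
  n <- params$group_size
  a <- params$contribution_fraction * params$budget
  m <- params$pot_multiplier
  b <- params$budget
  cost <- v * (1 - p)                      # expected punisher duty, both types
  coop <- b - a + m * a * ((n - 1) * p + 1) / n - cost
  free <- b + m * a * (n - 1) * p / n - params$fine_ratio * v - cost
  list(cooperator = coop, free_rider = free)
}

#' Critical fine: the punishment level equalising expected payoffs
#'
#' The expected payoff gap (free-rider minus cooperator) is affine in v:
#' `a (1 - m/N) - fine_ratio * v`, independent of the cooperator fraction.
#' Its root `v* = a (1 - m/N) / fine_ratio` is the threshold above which
#' cooperators out-earn free-riders in expectation; at the baseline
#' (a = 1, m = 2, N = 100, fine_ratio = 2) it is 0.49.
#'
#' @param params An [model_params()] object.
#' @param p Cooperator fraction (accepted for interface symmetry; the
#'   threshold does not depend on it). Default 0.5.
#' @return The critical fine (currency units); `Inf` when `fine_ratio = 0`
#'   and the gap is positive, 0 when the gap is already non-positive.
#' @export
critical_fine <- function(params, p = 0.5) {
  a <- params$contribution_fraction * params$budget
  gap0 <- a * (1 - params$pot_multiplier / params$group_size)
  if (gap0 <= 0) return(0)
  if (params$fine_ratio == 0) return(Inf)
  gap0 / params$fine_ratio
}

#' Deterministic projection of the cooperator fraction
#'
#' Mean-field companion of the stochastic simulator: iterates the
#' discrete-time selection map
#' `p' = p f_c / (p f_c + (1 - p) f_f)` with `f_x = max(payoff_x, eps)`
#' under a fixed punishment level. The boundaries p = 0 and p = 1 are
#' absorbing. This is both the agents' forecasting machinery in the
#' political game and the oracle against which the simulator is validated.
#'
#' @param p0 Initial cooperator fraction in \[0, 1\].
#' @param v Punishment level held fixed throughout.
#' @param params An [model_params()] object.
#' @param horizon Number of steps to iterate (>= 1).
#' @return Numeric vector of length `horizon + 1`: the trajectory
#'   `p_0, ..., p_horizon`.
#' @export
project_dynamics <- function(p0, v, params, horizon) {
  stopifnot(p0 >= 0, p0 <= 1, horizon >= 1)
  traj <- numeric(horizon + 1)
  traj[1] <- p <- p0
  eps <- params$fitness_floor
  n <- params$group_size
  a <- params$contribution_fraction * params$budget
  m <- params$pot_multiplier
  b <- params$budget
  fr <- params$fine_ratio
  for (t in seq_len(horizon)) {
    if (p > 0 && p < 1) {
      cost <- v * (1 - p)
      fc <- max(b - a + m * a * ((n - 1) * p + 1) / n - cost, eps)
      ff <- max(b + m * a * (n - 1) * p / n - fr * v - cost, eps)
      p <- p * fc / (p * fc + (1 - p) * ff)
    }
    traj[t + 1] <- p
  }
  traj
}

# Shared projection core returning the per-step expected payoffs of both
# persisting types along the trajectory. mode "horizon": exactly `horizon`
# states (t = 0 .. horizon-1). mode "steady": iterate until |dp| < tol or
# 10 * horizon steps, return only the final state's payoffs.
forecast_engine <- function(p0, v, params, horizon, mode, tol = 1e-6) {
  eps <- params$fitness_floor
  n <- params$group_size
  a <- params$contribution_fraction * params$budget
  m <- params$pot_multiplier
  b <- params$budget
  fr <- params$fine_ratio
  base_c <- b - a + m * a / n
  slope <- m * a * (n - 1) / n
  fine <- fr * v
  p <- p0
  if (mode == "horizon") {
    sum_c <- 0
    sum_f <- 0
    for (t in seq_len(horizon)) {
      cost <- v * (1 - p)
      pic <- base_c + slope * p - cost
      pif <- b + slope * p - fine - cost
      sum_c <- sum_c + pic
      sum_f <- sum_f + pif
      if (p > 0 && p < 1) {
        fc <- max(pic, eps)
        ff <- max(pif, eps)
        p <- p * fc / (p * fc + (1 - p) * ff)
      }
    }
    list(cooperator = sum_c / horizon, free_rider = sum_f / horizon,
         horizon_used = as.integer(horizon))
  } else {
    cap <- 10L * horizon
    used <- 0L
    for (t in seq_len(cap)) {
      if (p <= 0 || p >= 1) break
      cost <- v * (1 - p)
      fc <- max(base_c + slope * p - cost, eps)
      ff <- max(b + slope * p - fine - cost, eps)
      pn <- p * fc / (p * fc + (1 - p) * ff)
      used <- t
      if (abs(pn - p) < tol) {
        p <- pn
        break
      }
      p <- pn
    }
    cost <- v * (1 - p)
    list(cooperator = base_c + slope * p - cost,
         free_rider = b + slope * p - fine - cost,
         horizon_used = used)
  }
}

#' Forecast an agent type's long-run payoff under a punishment level
#'
#' Projects the population forward from cooperator fraction `p` with the
#' fine held at `v` and summarises the named type's expected per-generation
#' payoff: the mean over `forecast_horizon` generations
#' (`forecast_mode = "horizon"`, so a horizon of 1 reduces to
#' [expected_payoffs()]) or the payoff at the projected steady state
#' (`"steady"`). The type is treated as persisting even where its projected
#' frequency reaches 0, so a forecast is always defined for both types.
#' Deterministic: this is the perfect-foresight assessment agents use when
#' voting.
#'
#' @param strategy `"cooperator"` or `"free_rider"`.
#' @param v Candidate punishment level, >= 0.
#' @param p Current cooperator fraction.
#' @param params An [model_params()] object.
#' @return An object of class `instevo_forecast`: list with `strategy`,
#'   `punishment_level`, `predicted_payoff`, `horizon_used`.
#' @export
forecast_payoff <- function(strategy = c("cooperator", "free_rider"),
                            v, p, params) {
  strategy <- match.arg(strategy)
  stopifnot(v >= 0, p >= 0, p <= 1)
  res <- forecast_engine(p, v, params, params$forecast_horizon,
                         params$forecast_mode)
  structure(list(strategy = strategy,
                 punishment_level = v,
                 predicted_payoff = res[[strategy]],
                 horizon_used = res$horizon_used),
            class = "instevo_forecast")
}

#' @export
print.instevo_forecast <- function(x, ...) {
  cat(sprintf("Forecast for %s under fine v = %g: %.4f per generation (%d projected generations)\n",
              x$strategy, x$punishment_level, x$predicted_payoff,
              x$horizon_used))
  invisible(x)
}
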