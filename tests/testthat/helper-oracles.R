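# Independent oracles used across tests. Written straight-line on purpose:
# plain arithmetic, no calls into the package's cycle code.

# Closed-form OLS via the two-parameter normal equations.
ols_oracle <- function(x, y, intercept = TRUE) {
  if (intercept) {
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    b1 <- sxy / sxx
    b0 <- mean(y) - b1 * mean(x)
    list(intercept = b0, slope = b1,
         r_squared = sxy^2 / (sxx * sum((y - mean(y))^2)))
  } else {
    list(intercept = 0, slope = sum(x * y) / sum(x^2))
  }
}

# Annual probability by numerical integration of the hazard over [t, t+1].
hazard_integral_prob <- function(hazard, t) {
  H <- stats::integrate(hazard, t, t + 1, rel.tol = 1e-12)$value
  1 - exp(-H)
}

# Hand-rolled annual-cycle loop for a deliberately simple scenario: one
# two-state track (no biomarker modifier), constant-covariate trajectory,
# Weibull events with no history at baseline, one logistic mortality cause.
simple_cycle_oracle <- function(profile, event_lambdas, event_rhos,
                                mort_prob, track_p, horizon) {
  alive <- 1
  occ <- c(1, 0)
  hist <- setNames(rep(0, length(event_lambdas)), names(event_lambdas))
  cum <- setNames(rep(0, length(event_lambdas) + 3),
                  c(names(event_lambdas), "sick", "mort_cause",
                    "all_cause_death"))
  d0 <- profile$diabetes_duration
  out <- matrix(NA_real_, horizon, length(cum),
                dimnames = list(as.character(seq_len(horizon)), names(cum)))
  for (y in seq_len(horizon)) {
    t <- d0 + y - 1
    occ1 <- c(occ[1] * (1 - track_p), occ[2] + occ[1] * track_p)
    cum["sick"] <- cum["sick"] + alive * (occ1[2] - occ[2])
    occ <- occ1
    for (ev in names(event_lambdas)) {
      rho <- event_rhos[[ev]]
      p <- 1 - exp(-event_lambdas[[ev]] * ((t + 1)^rho - t^rho))
      cum[ev] <- cum[ev] + alive * (1 - hist[[ev]]) * p
      hist[[ev]] <- hist[[ev]] + (1 - hist[[ev]]) * p
    }
    cum["mort_cause"] <- cum["mort_cause"] + alive * mort_prob
    alive <- alive * (1 - mort_prob)
    cum["all_cause_death"] <- 1 - alive
    out[y, ] <- cum
  }
  out
}

# A fixed profile used in many unit tests.
test_profile <- function(...) {
  risk_profile(age = 62, sex = "male", smoker = TRUE,
               diabetes_duration = 9, hba1c = 8.2, sbp = 148,
               lipid_ratio = 5.1, bmi = 30.5, ...)
}

# Minimal valid bundle where every equation is a constant annual
# probability (logistic with intercept qlogis(p)).
constant_bundle <- function(p_event = 0.05, p_death = 0.1) {
  const_spec <- function(ev, p) {
    equation_spec(ev, "logistic_annual",
                  c(intercept = if (p == 0) -745 else stats::qlogis(p)))
  }
  specs <- lapply(macrovascular_events(), function(ev) const_spec(ev, p_event))
  names(specs) <- macrovascular_events()
  equation_bundle("toy", specs,
                  list(all_cause_death = const_spec("all_cause_death",
                                                    p_death)))
}

# Two-state track with a fixed transition probability and no modifier.
two_state_track <- function(p = 0.3, organ = "neuropathy") {
  mv_track(organ, c("none", "sick"),
           list(list(from = "none", to = "sick",
                     spec = transition_spec(p, "none"))))
}
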