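#' Biomarker trajectory over the simulation horizon
#'
#' Builds per-covariate annual value paths. Year 0 holds the baseline value;
#' treatment effects reach full effect during the first year, so years
#' `1..horizon` hold `baseline + delta` (flat), unless an explicit per-year
#' path is supplied, which is returned verbatim.
#'
#' @param baseline A [risk_profile()] giving year-0 values.
#' @param effects Named list/vector of additive treatment effects (deltas)
#'   on trajectory covariates (`hba1c`, `sbp`, `lipid_ratio`, `bmi`, `ldl`,
#'   `egfr`).
#' @param horizon Simulation horizon in years, `>= 1`.
#' @param paths Named list of explicit per-year paths (length
#'   `horizon + 1`, year 0 first); overrides `effects` for that covariate.
#' @return Named list of numeric vectors of length `horizon + 1`, class
#'   `biomarker_trajectory`.
#' @export
build_trajectory <- function(baseline, effects = list(), horizon,
                             paths = list()) {
  if (horizon < 1) stop("horizon must be at least 1")
  covs <- c("hba1c", "sbp", "lipid_ratio", "bmi", "ldl", "egfr")
  bad <- setdiff(c(names(effects), names(paths)), covs)
  if (length(bad)) {
    stop("unknown trajectory covariate(s): ", paste(bad, collapse = ", "))
  }
  traj <- lapply(covs, function(cv) {
    if (!is.null(paths[[cv]])) {
      p <- paths[[cv]]
      if (length(p) != horizon + 1) {
        stop("explicit path for '", cv, "' must have length horizon + 1")
      }
      return(as.numeric(p))
    }
    base <- baseline[[cv]]
    delta <- if (is.null(effects[[cv]])) 0 else effects[[cv]]
    c(base, rep(base + delta, horizon))
  })
  names(traj) <- covs
  structure(traj, class = "biomarker_trajectory")
}

#' One cohort subgroup: baseline profile, weight and trajectory
#'
#' The model is loaded separately for subgroups with distinct cardiovascular
#' risk (by default the four gender-by-smoking cells) and outcomes are
#' pooled as the weighted average.
#'
#' @param baseline A [risk_profile()] (carries sex and smoking status).
#' @param weight Subgroup weight; weights across a study's subgroups must
#'   sum to 1.
#' @param trajectory A [build_trajectory()] result, or `NULL` for a constant
#'   baseline path (filled in at simulation time).
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(baseline, weight, trajectory = NULL) {
  stopifnot(inherits(baseline, "risk_profile"),
            weight >= 0, weight <= 1)
  structure(list(sex = baseline$sex, smoker = baseline$smoker,
                 weight = weight, baseline = baseline,
                 trajectory = trajectory),
            class = "subgroup_spec")
}

# Endpoint ids a track contributes: every state after the first.
track_endpoints <- function(tracks) {
  unlist(lapply(tracks, function(tr) tr$states[-1]), use.names = FALSE)
}

# Full endpoint vector for a bundle + tracks combination.
engine_endpoints <- function(bundle, tracks) {
  mort <- names(bundle$mortality_specs)
  ids <- c(macrovascular_events(), track_endpoints(tracks), mort)
  if (!"all_cause_death" %in% ids) ids <- c(ids, "all_cause_death")
  unique(ids)
}

#' Initialise the cohort state for a subgroup
#'
#' All microvascular occupancy starts in each track's first state unless
#' `init_occupancy` supplies vectors; prior macrovascular events come from
#' the baseline profile's `event_history`.
#'
#' @param subgroup A [subgroup_spec()].
#' @param bundle An [equation_bundle()].
#' @param tracks Named list of [mv_track()].
#' @param init_occupancy Optional named list of initial occupancy vectors.
#' @return An object of class `cohort_state`.
#' @export
init_cohort_state <- function(subgroup, bundle, tracks,
                              init_occupancy = NULL) {
  occ <- lapply(tracks, function(tr) {
    v <- stats::setNames(rep(0, length(tr$states)), tr$states)
    v[1] <- 1
    v
  })
  if (!is.null(init_occupancy)) {
    for (nm in names(init_occupancy)) {
      v <- init_occupancy[[nm]]
      if (abs(sum(v) - 1) > 1e-9) stop("initial occupancy must sum to 1")
      occ[[nm]][] <- v
    }
  }
  cum <- stats::setNames(rep(0, length(engine_endpoints(bundle, tracks))),
                         engine_endpoints(bundle, tracks))
  structure(
    list(year_index = 0L, alive_fraction = 1, track_occupancy = occ,
         cum_incidence = cum, profile = subgroup$baseline),
    class = "cohort_state"
  )
}

#' Advance the cohort one annual cycle
#'
#' The within-cycle order is fixed: (1) microvascular Markov steps, with new
#' entries into each downstream state accrued to cumulative incidence among
#' survivors; (2) macrovascular annual event probabilities accrue among
#' survivors not yet affected; (3) mortality causes combine by
#' complement-product and reduce the alive fraction; (4) event-history
#' prevalences, age and diabetes duration advance. Cumulative incidences are
#' on the of-initial-cohort scale. No half-cycle correction is applied.
#'
#' @param state A `cohort_state`.
#' @param bundle An [equation_bundle()].
#' @param tracks Named list of [mv_track()].
#' @return The updated `cohort_state`.
#' @export
advance_one_year <- function(state, bundle, tracks) {
  prof <- state$profile
  alive <- state$alive_fraction
  cum <- state$cum_incidence

  # (1) microvascular progression
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    m <- build_transition_matrix(tr, prof)
    occ0 <- state$track_occupancy[[nm]]
    occ1 <- step_track(occ0, m)
    n <- length(occ0)
    if (n > 1) {
      for (j in 2:n) {
        delta <- sum(occ1[j:n]) - sum(occ0[j:n])  # >= 0: forward-only chain
        cum[tr$states[j]] <- cum[tr$states[j]] + alive * delta
      }
    }
    state$track_occupancy[[nm]] <- occ1
  }

  # (2) macrovascular events among survivors not yet affected
  ev_probs <- evaluate_bundle(bundle, prof, which = "events")
  hist <- prof$event_history
  for (ev in names(ev_probs)) {
    at_risk <- 1 - hist[[ev]]
    cum[ev] <- cum[ev] + alive * at_risk * ev_probs[[ev]]
    hist[[ev]] <- hist[[ev]] + at_risk * ev_probs[[ev]]
  }

  # (3) mortality: competing causes, complement-product
  mort_probs <- evaluate_bundle(bundle, prof, which = "mortality")
  q <- combine_competing(mort_probs)
  if (q > 0) {
    haz <- -log1p(-pmin(mort_probs, 1 - 1e-15))
    share <- if (sum(haz) > 0) haz / sum(haz) else
      rep(1 / length(haz), length(haz))
    for (i in seq_along(mort_probs)) {
      cause <- names(mort_probs)[i]
      cum[cause] <- cum[cause] + alive * q * share[i]
    }
  }
  alive <- alive * (1 - q)
  cum["all_cause_death"] <- 1 - alive

  # (4) history/ageing updates
  for (st in c("blindness", "esrd", "amputation")) {
    for (nm in names(tracks)) {
      k <- match(st, tracks[[nm]]$states)
      if (!is.na(k)) {
        hist[[st]] <- sum(state$track_occupancy[[nm]][
          k:length(tracks[[nm]]$states)])
      }
    }
  }
  prof$event_history <- hist
  prof$age <- prof$age + 1
  prof$diabetes_duration <- prof$diabetes_duration + 1

  state$profile <- prof
  state$alive_fraction <- alive
  state$cum_incidence <- cum
  state$year_index <- state$year_index + 1L
  state
}

#' Run the deterministic annual-cycle simulation for one subgroup
#'
#' Advances the cohort year by year for `horizon` years (capped at 40),
#' reading each year's biomarker values from the subgroup trajectory before
#' the cycle is evaluated, and records the cumulative incidence of every
#' endpoint at the end of each year.
#'
#' @param subgroup A [subgroup_spec()].
#' @param bundle An [equation_bundle()].
#' @param tracks Named list of [mv_track()]; defaults to [default_tracks()].
#' @param horizon Integer years, `1 <= horizon <= 40`.
#' @param init_occupancy Optional initial occupancy (see
#'   [init_cohort_state()]).
#' @return Matrix of cumulative incidences (rows: years `1..horizon`,
#'   columns: endpoint ids), class `simulation_result`, with the final
#'   `cohort_state` attached as attribute `final_state`.
#' @export
run_simulation <- function(subgroup, bundle, tracks = default_tracks(),
                           horizon, init_occupancy = NULL) {
  if (horizon < 1) stop("horizon must be at least 1 year")
  if (horizon > 40) stop("horizon exceeds the 40-year maximum")
  horizon <- as.integer(horizon)
  traj <- subgroup$trajectory
  if (is.null(traj)) {
    traj <- build_trajectory(subgroup$baseline, list(), horizon)
  }
  if (length(traj[[1]]) < horizon + 1) {
    stop("trajectory shorter than horizon")
  }
  state <- init_cohort_state(subgroup, bundle, tracks, init_occupancy)
  eps <- engine_endpoints(bundle, tracks)
  out <- matrix(NA_real_, nrow = horizon, ncol = length(eps),
                dimnames = list(as.character(seq_len(horizon)), eps))
  for (y in seq_len(horizon)) {
    for (cv in names(traj)) {
      val <- traj[[cv]][y + 1]  # post-treatment value applies from year 1
      if (is.finite(val)) state$profile[[cv]] <- val
    }
    state <- advance_one_year(state, bundle, tracks)
    out[y, ] <- state$cum_incidence[eps]
  }
  structure(out, class = c("simulation_result", "matrix", "array"),
            final_state = state)
}

#' Pool subgroup simulation results by weights
#'
#' Elementwise weighted average of per-year endpoint maps, mirroring the
#' weighted pooling of the gender-by-smoking subgroup runs.
#'
#' @param results List of `simulation_result` matrices with identical
#'   dimnames.
#' @param weights Numeric weights summing to 1 (within 1e-9).
#' @return Pooled matrix with the same dimnames.
#' @export
pool_subgroups <- function(results, weights) {
  if (length(results) != length(weights)) {
    stop("results and weights lengths differ")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("subgroup weights must sum to 1 (got ", sum(weights), ")")
  }
  ref <- dimnames(results[[1]])
  for (r in results[-1]) {
    if (!identical(dimnames(r), ref)) {
      stop("subgroup results have mismatched years or endpoints")
    }
  }
  pooled <- Reduce(`+`, Map(function(r, w) unclass(r) * w, results, weights))
  structure(pooled, class = c("simulation_result", "matrix", "array"))
}
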