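# Run code with a local, restorable RNG state so fixtures are
# bit-reproducible without disturbing the caller's stream.
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy equation bundle with known small hazards
#'
#' Builds a complete bundle (all five macrovascular events plus cvd/other
#' mortality) mixing the three hazard families, with coefficients drawn so
#' that annual probabilities stay below 0.2 for physiologically plausible
#' profiles. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param zero_hazard If `TRUE`, all linear predictors are `-Inf`-like
#'   (coefficients give probability 0): useful for engine book-keeping
#'   tests.
#' @return An [equation_bundle()] named `"toy"`.
#' @export
make_toy_bundle <- function(seed = 1, zero_hazard = FALSE) {
  with_fixture_seed(seed, {
    base_int <- function(lo, hi) stats::runif(1, lo, hi)
    mk <- function(ev, family) {
      if (zero_hazard) {
        return(equation_spec(ev, "logistic_annual",
                             c(intercept = -745)))  # plogis(-745) == 0
      }
      switch(family,
        weibull = equation_spec(
          ev, "weibull",
          c(intercept = base_int(-6.5, -5.5),
            hba1c_c = stats::runif(1, 0.05, 0.15),
            sbp_c = stats::runif(1, 0.002, 0.01),
            male = stats::runif(1, 0.1, 0.3)),
          transforms = list(hba1c_c = list(covariate = "hba1c", offset = 7),
                            sbp_c = list(covariate = "sbp", offset = 135)),
          shape = stats::runif(1, 1.1, 1.6)),
        gompertz = equation_spec(
          ev, "gompertz",
          c(intercept = base_int(-6.5, -5.5),
            hba1c_c = stats::runif(1, 0.05, 0.15),
            smoker = stats::runif(1, 0.1, 0.4)),
          transforms = list(hba1c_c = list(covariate = "hba1c", offset = 7)),
          shape = stats::runif(1, 0.02, 0.08)),
        fiveyear = equation_spec(
          ev, "fiveyear_risk",
          c(intercept = base_int(-4.0, -3.0),
            hba1c_c = stats::runif(1, 0.1, 0.2),
            lipid_ratio = stats::runif(1, 0.02, 0.08)),
          transforms = list(hba1c_c = list(covariate = "hba1c", offset = 7))),
        logistic = equation_spec(
          ev, "logistic_annual",
          c(intercept = base_int(-5.5, -4.5),
            age_c = stats::runif(1, 0.01, 0.03)),
          transforms = list(age_c = list(covariate = "age", offset = 60))))
    }
    fams <- c(mi = "weibull", ihd = "gompertz", chf = "fiveyear",
              stroke = "weibull", pvd = "logistic")
    specs <- Map(mk, names(fams), fams)
    mort <- list(
      cvd_death = mk("cvd_death", "gompertz"),
      other_death = mk("other_death", "logistic")
    )
    equation_bundle("toy", specs, mort,
                    provenance = "synthetic toy coefficients (seeded)")
  })
}

#' Generate a toy validation study with known ground truth
#'
#' Builds a four-subgroup (female/male x smoker/non-smoker) study with
#' plausible type-2-diabetes baselines, simulates it with the toy bundle,
#' and fills the observed endpoint values from the model's own predictions
#' perturbed by a known multiplicative bias and seeded noise — so the true
#' concordance of the resulting validation points is known by construction
#' (`observed = predicted * bias * exp(noise)`, hence the no-intercept
#' regression of predicted on observed has slope close to `1/bias`).
#'
#' @param seed Integer seed.
#' @param horizon Follow-up years, `1..40`.
#' @param bias Multiplicative bias applied to observed values (1 = none).
#' @param noise_sd Standard deviation of lognormal perturbation (0 = exact
#'   closed loop).
#' @param bundle Bundle used to generate truth; defaults to
#'   `make_toy_bundle(seed)`.
#' @param weights Subgroup weights (female-smoker, female-non-smoker,
#'   male-smoker, male-non-smoker); must sum to 1.
#' @return A [study_config()] with attribute `truth` recording bundle,
#'   bias and the unperturbed predictions.
#' @export
make_toy_study <- function(seed = 1, horizon = 5, bias = 1, noise_sd = 0,
                           bundle = NULL, weights = c(0.2, 0.3, 0.2, 0.3)) {
  if (horizon < 1 || horizon > 40) stop("horizon must lie in 1..40")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (is.null(bundle)) bundle <- make_toy_bundle(seed)
  with_fixture_seed(seed + 1000L, {
    cells <- expand.grid(sex = c("female", "male"),
                         smoker = c(TRUE, FALSE),
                         stringsAsFactors = FALSE)
    cells <- cells[order(cells$sex, !cells$smoker), ]
    subgroups <- Map(function(sex, smoker, w) {
      base <- risk_profile(
        age = stats::runif(1, 55, 65), sex = sex, smoker = smoker,
        diabetes_duration = stats::runif(1, 5, 12),
        hba1c = stats::runif(1, 6.5, 9.5),
        sbp = stats::runif(1, 125, 160),
        lipid_ratio = stats::runif(1, 3.5, 5.5),
        bmi = stats::runif(1, 26, 33))
      subgroup_spec(base, w,
                    build_trajectory(base, list(hba1c = -0.5), horizon))
    }, cells$sex, cells$smoker, weights)

    tracks <- default_tracks()
    sims <- lapply(subgroups, run_simulation, bundle = bundle,
                   tracks = tracks, horizon = horizon)
    pooled <- pool_subgroups(sims, weights)

    ep_ids <- c("mi", "stroke", "chf", "blindness", "esrd", "amputation",
                "all_cause_death")
    pred <- pooled[as.character(horizon), ep_ids]
    noise <- stats::rnorm(length(pred), 0, noise_sd)
    obs <- pmin(pmax(pred * bias * exp(noise), 0), 1)
    endpoints <- data.frame(endpoint_id = ep_ids, observed = unname(obs),
                            horizon = horizon,
                            stringsAsFactors = FALSE)
    cfg <- study_config(
      study_id = paste0("TOY-", seed), subgroups = subgroups,
      endpoints = endpoints, follow_up = horizon,
      description = "synthetic validation study (seeded fixture)",
      dependency_class = "always_independent")
    attr(cfg, "truth") <- list(bundle = bundle, bias = bias,
                               noise_sd = noise_sd,
                               predicted = unname(pred))
    cfg
  })
}

#' Generate synthetic validation points with known regression truth
#'
#' Draws observed values `X` uniformly on `x_range`, sets
#' `Y = intercept + slope * X + noise` and truncates `Y` to \[0, 1\]
#' (truncation is flagged per point so exact-recovery tests can drop those
#' rows). Study labels are assigned round-robin for cluster testing.
#'
#' @param seed Integer seed.
#' @param n Number of points.
#' @param true_intercept,true_slope Generating line.
#' @param noise_sd Gaussian noise SD (0 for exact recovery).
#' @param n_studies Number of round-robin study labels (clusters).
#' @param x_range Range of observed values.
#' @return A `validation_points` data.frame with extra logical column
#'   `truncated`.
#' @export
make_synthetic_points <- function(seed = 1, n = 167, true_intercept = 0,
                                  true_slope = 1, noise_sd = 0.02,
                                  n_studies = 12,
                                  x_range = c(0.01, 0.8)) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.finite(true_slope)) stop("true slope must be finite")
  with_fixture_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    y_raw <- true_intercept + true_slope * x + stats::rnorm(n, 0, noise_sd)
    y <- pmin(pmax(y_raw, 0), 1)
    cats <- rep(c("macrovascular", "microvascular", "mortality"),
                length.out = n)
    deps <- rep(c("dependent", "independent"), length.out = n)
    out <- data.frame(
      study_id = paste0("S", rep_len(seq_len(n_studies), n)),
      stratum_id = "default",
      endpoint_id = paste0("ep", seq_len(n)),
      category = cats, dependency = deps,
      horizon = 5, observed = x, predicted = y,
      truncated = y != y_raw,
      stringsAsFactors = FALSE
    )
    class(out) <- c("validation_points", "data.frame")
    out
  })
}
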