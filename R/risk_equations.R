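#' Cohort-mean risk-factor profile
#'
#' Holds the current-year cohort-mean covariates that drive the risk
#' equations: demographics, glycaemic and cardiovascular biomarkers, and the
#' prevalence of prior complications. Values are cohort means (not individual
#' patients); event histories are prevalence fractions in \[0, 1\] and enter
#' linear predictors as expected values.
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param smoker Logical, current smoker.
#' @param diabetes_duration Years since diagnosis.
#' @param hba1c Glycated haemoglobin, percent (DCCT scale).
#' @param sbp Systolic blood pressure, mmHg.
#' @param lipid_ratio Total:HDL cholesterol ratio (dimensionless).
#' @param bmi Body-mass index, kg/m^2.
#' @param ldl LDL cholesterol, mmol/L (optional, `NA` if unknown).
#' @param egfr Estimated GFR, mL/min/1.73m^2 (optional).
#' @param albuminuria_stage `"none"`, `"micro"` or `"macro"`.
#' @param event_history Named numeric vector of prior-event prevalence
#'   fractions; recognised names are `mi`, `ihd`, `chf`, `stroke`, `pvd`,
#'   `blindness`, `esrd`, `amputation`. Missing names default to 0.
#'
#' @return An object of class `risk_profile`.
#' @export
risk_profile <- function(age = 60, sex = c("female", "male"), smoker = FALSE,
                         diabetes_duration = 8, hba1c = 7.5, sbp = 140,
                         lipid_ratio = 4.5, bmi = 29, ldl = NA_real_,
                         egfr = NA_real_,
                         albuminuria_stage = c("none", "micro", "macro"),
                         event_history = numeric()) {
  sex <- match.arg(sex)
  albuminuria_stage <- match.arg(albuminuria_stage)
  hist <- stats::setNames(rep(0, length(event_ids())), event_ids())
  if (length(event_history)) {
    bad <- setdiff(names(event_history), event_ids())
    if (length(bad)) {
      stop("unknown event_history names: ", paste(bad, collapse = ", "))
    }
    if (any(event_history < 0 | event_history > 1)) {
      stop("event_history fractions must lie in [0, 1]")
    }
    hist[names(event_history)] <- event_history
  }
  num <- c(age = age, diabetes_duration = diabetes_duration, hba1c = hba1c,
           sbp = sbp, lipid_ratio = lipid_ratio, bmi = bmi)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("continuous risk factors must be finite and positive; got: ",
         paste(names(num)[!is.finite(num) | num <= 0], collapse = ", "))
  }
  structure(
    list(age = age, sex = sex, smoker = isTRUE(smoker),
         diabetes_duration = diabetes_duration, hba1c = hba1c, sbp = sbp,
         lipid_ratio = lipid_ratio, bmi = bmi, ldl = ldl, egfr = egfr,
         albuminuria_stage = albuminuria_stage, event_history = hist),
    class = "risk_profile"
  )
}

#' Macrovascular event identifiers tracked by the engine
#'
#' @return Character vector of event ids with a prior-event history slot.
#' @export
event_ids <- function() {
  c("mi", "ihd", "chf", "stroke", "pvd",
    "blindness", "esrd", "amputation")
}

#' Macrovascular events simulated from risk equations
#' @return Character vector of the five macrovascular event ids.
#' @export
macrovascular_events <- function() c("mi", "ihd", "chf", "stroke", "pvd")

#' Parametric risk-equation specification
#'
#' One event's hazard/risk equation. Supported families:
#' \describe{
#'   \item{`weibull`}{Cumulative hazard `H(t) = exp(b'x) * t^shape`
#'     (UKPDS-OM1 lineage); `shape` must be positive.}
#'   \item{`gompertz`}{`H(t) = exp(b'x)/shape * (exp(shape*t) - 1)`
#'     (UKPDS-OM2 lineage).}
#'   \item{`logistic_annual`}{Annual probability `plogis(b'x)` directly.}
#'   \item{`fiveyear_risk`}{Five-year risk `plogis(b'x)` converted to an
#'     annual probability (NDR lineage, which publishes 5-year CVD risks).}
#' }
#'
#' @param event_id Event identifier the equation predicts.
#' @param family One of `"weibull"`, `"gompertz"`, `"logistic_annual"`,
#'   `"fiveyear_risk"`.
#' @param coefficients Named numeric vector of betas. The name `intercept`
#'   maps to a constant 1; other names must resolve to a `risk_profile`
#'   field (`age`, `diabetes_duration`, `hba1c`, `sbp`, `lipid_ratio`,
#'   `bmi`, `ldl`, `egfr`), an indicator (`male`, `female`, `smoker`,
#'   `micro_albuminuria`, `macro_albuminuria`), an event-history id, or a
#'   declared transform.
#' @param transforms Named list of covariate transforms. Each element is a
#'   list with `covariate` plus optional `offset` (centering), `scale`
#'   (divisor) and `log` (logical): the transformed value is
#'   `(x - offset)/scale`, or `log(x/offset)` when `log = TRUE`.
#' @param shape Shape parameter: Weibull `rho > 0` or Gompertz `theta != 0`.
#' @param time_scale `"diabetes_duration"` (UKPDS convention, default) or
#'   `"age"`: the clock the cumulative hazard runs on.
#'
#' @return An object of class `equation_spec`.
#' @export
equation_spec <- function(event_id, family, coefficients, transforms = list(),
                          shape = NULL,
                          time_scale = c("diabetes_duration", "age")) {
  family <- match.arg(family,
                      c("weibull", "gompertz", "logistic_annual",
                        "fiveyear_risk"))
  time_scale <- match.arg(time_scale)
  coefficients <- unlist(coefficients)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("coefficients must be a named numeric vector")
  }
  if (family == "weibull") {
    if (is.null(shape) || shape <= 0) {
      stop("weibull family requires shape (rho) > 0 for '", event_id, "'")
    }
  }
  if (family == "gompertz") {
    if (is.null(shape) || shape == 0) {
      stop("gompertz family requires nonzero shape (theta) for '",
           event_id, "'")
    }
  }
  structure(
    list(event_id = event_id, family = family,
         coefficients = coefficients, transforms = transforms,
         shape = shape, time_scale = time_scale),
    class = "equation_spec"
  )
}

# Resolve one covariate name to its numeric value for a profile.
resolve_covariate <- function(name, profile, transforms, event_id = "?") {
  if (name == "intercept") return(1)
  if (!is.null(transforms[[name]])) {
    tr <- transforms[[name]]
    x <- resolve_covariate(tr$covariate, profile, list(), event_id)
    off <- if (is.null(tr$offset)) 0 else tr$offset
    if (isTRUE(tr$log)) {
      if (off <= 0) off <- 1
      return(log(x / off))
    }
    sc <- if (is.null(tr$scale)) 1 else tr$scale
    return((x - off) / sc)
  }
  val <- switch(name,
    male = as.numeric(profile$sex == "male"),
    female = as.numeric(profile$sex == "female"),
    smoker = as.numeric(profile$smoker),
    micro_albuminuria = as.numeric(profile$albuminuria_stage == "micro"),
    macro_albuminuria = as.numeric(profile$albuminuria_stage == "macro"),
    if (name %in% names(profile$event_history)) {
      profile$event_history[[name]]
    } else if (name %in% c("age", "diabetes_duration", "hba1c", "sbp",
                           "lipid_ratio", "bmi", "ldl", "egfr")) {
      profile[[name]]
    } else {
      stop("covariate '", name, "' in equation '", event_id,
           "' matches no risk_profile field or declared transform")
    })
  if (!is.finite(val)) {
    stop("covariate '", name, "' is non-finite in equation '", event_id, "'")
  }
  val
}

#' Linear predictor of a risk equation
#'
#' Assembles `sum(beta_j * x_j)` from an equation's coefficients and the
#' current profile, applying declared covariate transforms.
#'
#' @param spec An [equation_spec()].
#' @param profile A [risk_profile()].
#' @return The linear predictor (numeric scalar).
#' @export
linear_predictor <- function(spec, profile) {
  stopifnot(inherits(spec, "equation_spec"), inherits(profile, "risk_profile"))
  if (!length(spec$coefficients)) return(0)
  x <- vapply(names(spec$coefficients), resolve_covariate,
              numeric(1), profile = profile, transforms = spec$transforms,
              event_id = spec$event_id)
  sum(spec$coefficients * x)
}

#' Annual event probability under a Weibull hazard
#'
#' The probability of a first event in cycle year `(t, t + 1]` given
#' event-free survival to `t`, from the cumulative hazard
#' `H(t) = exp(b'x) * t^rho`:
#' `p = 1 - exp(-(H(t + 1) - H(t)))`.
#'
#' @param spec An [equation_spec()] with `family = "weibull"`.
#' @param profile A [risk_profile()].
#' @param t Elapsed time on the equation's time scale, years, `>= 0`.
#' @return Annual probability in \[0, 1\].
#' @export
weibull_annual_prob <- function(spec, profile, t) {
  if (t < 0) stop("t must be non-negative")
  rho <- spec$shape
  if (is.null(rho) || rho <= 0) stop("weibull shape (rho) must be positive")
  lambda <- exp(linear_predictor(spec, profile))
  dH <- lambda * ((t + 1)^rho - t^rho)
  -expm1(-dH)
}

#' Annual event probability under a Gompertz hazard
#'
#' Uses `H(t) = exp(b'x)/theta * (exp(theta * t) - 1)`; as `theta -> 0` this
#' tends to the constant-hazard form `H(t) = exp(b'x) * t` (computed through
#' `expm1` so small `theta` is numerically safe).
#'
#' @inheritParams weibull_annual_prob
#' @param spec An [equation_spec()] with `family = "gompertz"`.
#' @return Annual probability in \[0, 1\].
#' @export
gompertz_annual_prob <- function(spec, profile, t) {
  if (t < 0) stop("t must be non-negative")
  theta <- spec$shape
  if (is.null(theta) || theta == 0) stop("gompertz shape (theta) must be nonzero")
  lambda <- exp(linear_predictor(spec, profile))
  # H(t+1) - H(t) = lambda * exp(theta t) * expm1(theta) / theta
  dH <- lambda * exp(theta * t) * expm1(theta) / theta
  -expm1(-dH)
}

#' Convert a five-year risk to an annual probability
#'
#' Assumes a constant annual probability within the five-year window:
#' `p1 = 1 - (1 - p5)^(1/5)`. Used for NDR-style equations, which publish
#' five-year cardiovascular risks.
#'
#' @param p5 Five-year cumulative risk in \[0, 1\].
#' @return Annual probability; `1 - (1 - p1)^5` recovers `p5`.
#' @export
fiveyear_to_annual <- function(p5) {
  if (any(p5 < 0 | p5 > 1)) stop("five-year risk must lie in [0, 1]")
  1 - (1 - p5)^(1 / 5)
}

#' Combine competing within-cycle event probabilities
#'
#' Complement-product combination of independent competing causes:
#' `1 - prod(1 - p_i)`. An empty list yields 0.
#'
#' @param probs Numeric vector of probabilities in \[0, 1\].
#' @return Combined probability, at least `max(probs)`.
#' @export
combine_competing <- function(probs) {
  if (!length(probs)) return(0)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  -expm1(sum(log1p(-probs)))
}

# Annual probability for one spec, dispatching on family.
annual_prob <- function(spec, profile, t = NULL) {
  if (is.null(t)) t <- profile[[spec$time_scale]]
  switch(spec$family,
    weibull = weibull_annual_prob(spec, profile, t),
    gompertz = gompertz_annual_prob(spec, profile, t),
    logistic_annual = stats::plogis(linear_predictor(spec, profile)),
    fiveyear_risk = fiveyear_to_annual(
      stats::plogis(linear_predictor(spec, profile))),
    stop("unknown equation family: ", spec$family))
}

#' Named set of risk equations covering all engine events
#'
#' A bundle provides one [equation_spec()] per macrovascular event and per
#' mortality cause. An NDR-style bundle can borrow specs for events it does
#' not cover natively (notably mortality, for which no complete Swedish NDR
#' equations exist); borrowed event ids are recorded in `fallback`.
#'
#' @param name Bundle name, e.g. `"ukpds_om1"`, `"ukpds_om2"`, `"ndr"`,
#'   `"toy"`.
#' @param specs Named list of [equation_spec()], one per event id.
#' @param mortality_specs Named list of [equation_spec()], one per mortality
#'   cause (e.g. `cvd_death`, `other_death`, or a single `all_cause_death`).
#' @param provenance Free-text citation for the coefficient source.
#' @param fallback Character vector of event/cause ids whose specs were
#'   borrowed from another bundle.
#' @return An object of class `equation_bundle`.
#' @export
equation_bundle <- function(name, specs, mortality_specs,
                            provenance = "", fallback = character()) {
  stopifnot(is.list(specs), is.list(mortality_specs))
  missing_ev <- setdiff(macrovascular_events(), names(specs))
  if (length(missing_ev)) {
    stop("bundle '", name, "' lacks specs for: ",
         paste(missing_ev, collapse = ", "))
  }
  if (!length(mortality_specs)) {
    stop("bundle '", name, "' must include at least one mortality spec")
  }
  structure(
    list(name = name, specs = specs, mortality_specs = mortality_specs,
         provenance = provenance, fallback = fallback),
    class = "equation_bundle"
  )
}

#' Evaluate every equation of a bundle for the current profile
#'
#' @param bundle An [equation_bundle()].
#' @param profile A [risk_profile()].
#' @param t Optional elapsed time; defaults to each equation's own
#'   `time_scale` field read from the profile.
#' @param which `"events"`, `"mortality"` or `"both"`.
#' @return Named numeric vector of annual probabilities in \[0, 1\].
#' @export
evaluate_bundle <- function(bundle, profile, t = NULL,
                            which = c("events", "mortality", "both")) {
  which <- match.arg(which)
  specs <- switch(which,
    events = bundle$specs,
    mortality = bundle$mortality_specs,
    both = c(bundle$specs, bundle$mortality_specs))
  vapply(specs, annual_prob, numeric(1), profile = profile, t = t)
}

#' @export
print.equation_bundle <- function(x, ...) {
  cat("<equation_bundle>", x$name, "\n",
      " events:   ", paste(names(x$specs), collapse = ", "), "\n",
      " mortality:", paste(names(x$mortality_specs), collapse = ", "), "\n")
  if (length(x$fallback)) {
    cat("  fallback (borrowed specs):", paste(x$fallback, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write / read an equation bundle as a YAML file
#'
#' The on-disk dialect is versioned plain text: top-level `schema`, `name`,
#' `provenance`, `fallback`, and `equations` / `mortality` lists whose
#' entries carry `event_id`, `family`, `coefficients`, `transforms`,
#' `shape`, `time_scale`. Unknown families are rejected at load.
#'
#' @param bundle An [equation_bundle()].
#' @param path File path.
#' @return `read_bundle()` returns an [equation_bundle()];
#'   `write_bundle()` returns `path` invisibly.
#' @export
write_bundle <- function(bundle, path) {
  ser <- function(s) {
    list(event_id = s$event_id, family = s$family,
         coefficients = as.list(s$coefficients),
         transforms = s$transforms, shape = s$shape,
         time_scale = s$time_scale)
  }
  out <- list(schema = "t2dcohort-bundle/1", name = bundle$name,
              provenance = bundle$provenance,
              fallback = as.list(bundle$fallback),
              equations = lapply(bundle$specs, ser),
              mortality = lapply(bundle$mortality_specs, ser))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "t2dcohort-bundle/1")) {
    stop("unrecognised bundle schema: ", raw$schema)
  }
  de <- function(s) {
    equation_spec(s$event_id, s$family, unlist(s$coefficients),
                  transforms = if (is.null(s$transforms)) list() else s$transforms,
                  shape = s$shape,
                  time_scale = s$time_scale)
  }
  equation_bundle(raw$name,
                  specs = lapply(raw$equations, de),
                  mortality_specs = lapply(raw$mortality, de),
                  provenance = if (is.null(raw$provenance)) "" else raw$provenance,
                  fallback = unlist(raw$fallback) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
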