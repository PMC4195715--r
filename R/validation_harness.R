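#' Registry of the 12 external-validation studies
#'
#' Study-level metadata for the validation exercise: design, follow-up,
#' participants at baseline, number of cumulative-incidence endpoints
#' contributed, and the dependency class that determines whether each study
#' counts as "dependent" or "independent" under a given risk-equation
#' bundle. Dependency classes:
#' \describe{
#'   \item{`always_dependent`}{Data used in model construction (WESDR,
#'     Rochester microvascular sources) or in the UKPDS risk/mortality
#'     equations (UKPDS 33, UKPDS 80 — dependent even under NDR equations,
#'     because UKPDS mortality equations are used there).}
#'   \item{`ndr_dependent`}{Swedish NDR cohorts: dependent only when the NDR
#'     macrovascular equations are simulated, independent under either UKPDS
#'     set.}
#'   \item{`always_independent`}{The six studies not used in construction.}
#' }
#'
#' @return A data.frame with one row per study.
#' @export
study_registry <- function() {
  data.frame(
    study_id = c("NDR (I)", "NDR (II)", "UKPDS 33", "UKPDS 80", "WESDR",
                 "Rochester", "ACCORD", "ADOPT", "ADVANCE", "ASPEN",
                 "CARDS", "Osaka"),
    design = c("observational", "observational", "trial", "trial",
               "observational", "observational", "trial", "trial", "trial",
               "trial", "trial", "observational"),
    duration = c("5", "5.6", "11", "5-25", "5-30", "1-30", "3.5", "4", "5",
                 "4", "4", "5-20"),
    participants = c(29034L, 18334L, 3867L, 3867L, 1780L, 1470L, 10251L,
                     2895L, 11140L, 1905L, 2838L, 1939L),
    n_endpoints = c(32L, 3L, 12L, 14L, 14L, 16L, 8L, 10L, 10L, 6L, 10L,
                    32L),
    dependency_class = c("ndr_dependent", "ndr_dependent",
                         "always_dependent", "always_dependent",
                         "always_dependent", "always_dependent",
                         "always_independent", "always_independent",
                         "always_independent", "always_independent",
                         "always_independent", "always_independent"),
    stringsAsFactors = FALSE
  )
}

#' Endpoint category lookup
#'
#' Fixed mapping from model endpoint ids to outcome category.
#'
#' @param endpoint_id Character vector of endpoint ids.
#' @return Character vector: `"macrovascular"`, `"microvascular"` or
#'   `"mortality"` (`NA` for ids the model cannot match).
#' @export
endpoint_category <- function(endpoint_id) {
  micro <- c("background_retinopathy", "proliferative_retinopathy",
             "blindness", "microalbuminuria", "macroalbuminuria", "esrd",
             "symptomatic_neuropathy", "amputation")
  mort <- c("all_cause_death", "cvd_death", "other_death")
  out <- rep(NA_character_, length(endpoint_id))
  out[endpoint_id %in% macrovascular_events()] <- "macrovascular"
  out[endpoint_id %in% micro] <- "microvascular"
  out[endpoint_id %in% mort] <- "mortality"
  out
}

#' Classify a study as a dependent or independent validation source
#'
#' A study is "dependent" when its data contributed to the model or to the
#' risk equations being simulated, "independent" otherwise. The rule table
#' follows the packaged registry; studies not in the registry must declare
#' `dependency_class` in their configuration.
#'
#' @param study_id Study identifier.
#' @param bundle_name `"ukpds_om1"`, `"ukpds_om2"`, `"ndr"`, or any other
#'   bundle name (treated as UKPDS-like for NDR-dependent studies only when
#'   it equals `"ndr"`).
#' @param dependency_class Optional declared class for studies outside the
#'   registry (`"always_dependent"`, `"ndr_dependent"`,
#'   `"always_independent"`).
#' @return `"dependent"` or `"independent"`.
#' @export
classify_dependency <- function(study_id, bundle_name,
                                dependency_class = NULL) {
  reg <- study_registry()
  cls <- if (study_id %in% reg$study_id) {
    reg$dependency_class[reg$study_id == study_id]
  } else if (!is.null(dependency_class)) {
    match.arg(dependency_class,
              c("always_dependent", "ndr_dependent", "always_independent"))
  } else {
    stop("study '", study_id,
         "' is not in the registry and declares no dependency_class")
  }
  switch(cls,
    always_dependent = "dependent",
    always_independent = "independent",
    ndr_dependent = if (identical(bundle_name, "ndr")) "dependent"
                    else "independent")
}

#' Filter raw study endpoints to the model-matchable cumulative incidences
#'
#' Keeps endpoints that (a) match a single model outcome (no composites) and
#' (b) are reported as a cumulative incidence. Every exclusion is logged
#' with its reason.
#'
#' @param raw A data.frame with at least `endpoint_id` and `measure`
#'   (`"cumulative_incidence"`, `"prevalence"`, ...); other columns are
#'   carried through.
#' @return A list with `included` (rows kept, with a `category` column) and
#'   `excluded` (rows dropped, with a `reason` column:
#'   `"no-model-match"` or `"not-cumulative-incidence"`).
#' @export
filter_endpoints <- function(raw) {
  stopifnot(is.data.frame(raw),
            all(c("endpoint_id", "measure") %in% names(raw)))
  cat_ <- endpoint_category(raw$endpoint_id)
  no_match <- is.na(cat_)
  not_ci <- !no_match & raw$measure != "cumulative_incidence"
  keep <- !no_match & !not_ci
  excluded <- raw[!keep, , drop = FALSE]
  excluded$reason <- ifelse(no_match[!keep], "no-model-match",
                            "not-cumulative-incidence")
  included <- raw[keep, , drop = FALSE]
  included$category <- cat_[keep]
  list(included = included, excluded = excluded)
}

#' Study configuration for one validation exercise
#'
#' @param study_id Study identifier (registry name, or any id with a
#'   declared `dependency_class`).
#' @param subgroups List of [subgroup_spec()]; weights must sum to 1.
#' @param endpoints data.frame with columns `endpoint_id`, `observed`
#'   (cumulative incidence in \[0, 1\]), `horizon` (years), and optionally
#'   `stratum_id`.
#' @param follow_up Follow-up horizon in years (scalar or vector when the
#'   study reports several time points); must cover every endpoint horizon.
#' @param strata Optional named list of strata, each itself a list with a
#'   `subgroups` element: age/sex strata are simulated as separate
#'   sub-cohorts and treated as separate units of analysis. Endpoints
#'   reference them through `stratum_id`.
#' @param description Free text.
#' @param dependency_class Declared class for non-registry studies.
#' @return An object of class `study_config`.
#' @export
study_config <- function(study_id, subgroups, endpoints, follow_up,
                         strata = NULL, description = "",
                         dependency_class = NULL) {
  if (max(follow_up) < 1) stop("follow_up must be at least 1 year")
  if (!length(subgroups) && is.null(strata)) {
    stop("at least one subgroup is required")
  }
  if (length(subgroups)) {
    w <- vapply(subgroups, function(s) s$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-9) stop("subgroup weights must sum to 1")
  }
  stopifnot(is.data.frame(endpoints),
            all(c("endpoint_id", "observed", "horizon") %in%
                  names(endpoints)))
  if (any(endpoints$observed < 0 | endpoints$observed > 1)) {
    stop("observed cumulative incidences must lie in [0, 1]")
  }
  if (is.null(endpoints$stratum_id)) endpoints$stratum_id <- NA_character_
  structure(
    list(study_id = study_id, description = description,
         subgroups = subgroups, follow_up = follow_up,
         endpoints = endpoints, strata = strata,
         dependency_class = dependency_class),
    class = "study_config"
  )
}

#' Run the external-validation pipeline for one study
#'
#' For each stratum, simulates every subgroup under the chosen equation
#' bundle to the maximum endpoint horizon, pools by the subgroup weights,
#' and reads the predicted cumulative incidence of each endpoint at its
#' horizon, pairing it with the observed value. Each stratum and each
#' reported time point yields a separate validation point.
#'
#' @param config A [study_config()].
#' @param bundle An [equation_bundle()].
#' @param tracks Named list of [mv_track()]; defaults to [default_tracks()].
#' @return data.frame of class `validation_points` with columns `study_id`,
#'   `stratum_id`, `endpoint_id`, `category`, `dependency`, `horizon`,
#'   `observed`, `predicted`.
#' @export
run_validation <- function(config, bundle, tracks = default_tracks()) {
  dep <- classify_dependency(config$study_id, bundle$name,
                             config$dependency_class)
  max_h <- max(config$endpoints$horizon)
  if (max_h > max(config$follow_up)) {
    stop("endpoint horizon ", max_h, " exceeds study follow-up ",
         max(config$follow_up))
  }
  stratum_sets <- if (is.null(config$strata)) {
    list(default = list(subgroups = config$subgroups))
  } else {
    config$strata
  }
  pooled <- lapply(stratum_sets, function(st) {
    res <- lapply(st$subgroups, run_simulation, bundle = bundle,
                  tracks = tracks, horizon = max_h)
    w <- vapply(st$subgroups, function(s) s$weight, numeric(1))
    pool_subgroups(res, w)
  })
  ep <- config$endpoints
  pred <- numeric(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    sid <- ep$stratum_id[i]
    if (is.na(sid)) sid <- names(stratum_sets)[1]
    mat <- pooled[[sid]]
    if (is.null(mat)) stop("endpoint references unknown stratum '", sid, "'")
    if (!ep$endpoint_id[i] %in% colnames(mat)) {
      stop("endpoint '", ep$endpoint_id[i],
           "' has no matching model outcome")
    }
    pred[i] <- mat[as.character(ep$horizon[i]), ep$endpoint_id[i]]
  }
  out <- data.frame(
    study_id = config$study_id,
    stratum_id = ifelse(is.na(ep$stratum_id), names(stratum_sets)[1],
                        ep$stratum_id),
    endpoint_id = ep$endpoint_id,
    category = endpoint_category(ep$endpoint_id),
    dependency = dep,
    horizon = ep$horizon,
    observed = ep$observed,
    predicted = pred,
    stringsAsFactors = FALSE
  )
  class(out) <- c("validation_points", "data.frame")
  out
}

#' Count endpoints across study configurations
#'
#' @param configs List of [study_config()] objects (or the registry
#'   data.frame, in which case the tally uses the recorded per-study counts
#'   without categories).
#' @return List with `total` and `by_category` tally.
#' @export
count_endpoints <- function(configs) {
  if (is.data.frame(configs)) {
    return(list(total = sum(configs$n_endpoints), by_category = NULL))
  }
  if (!length(configs)) {
    return(list(total = 0L,
                by_category = c(macrovascular = 0L, microvascular = 0L,
                                mortality = 0L)))
  }
  cats <- unlist(lapply(configs, function(cf) {
    endpoint_category(cf$endpoints$endpoint_id)
  }))
  tab <- table(factor(cats, levels = c("macrovascular", "microvascular",
                                       "mortality")))
  list(total = length(cats), by_category = c(tab))
}

#' Read / write validation points as CSV
#'
#' The delimited interchange format for predicted/observed pairs: columns
#' `study_id`, `stratum_id`, `endpoint_id`, `category`, `dependency`,
#' `horizon`, `observed`, `predicted` (extra columns are preserved).
#'
#' @param path File path.
#' @param points A `validation_points` data.frame.
#' @return `read_validation_points()` returns a `validation_points`
#'   data.frame.
#' @export
read_validation_points <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "endpoint_id", "observed", "predicted")
  miss <- setdiff(need, names(pts))
  if (length(miss)) {
    stop("points file lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(pts$observed < 0 | pts$observed > 1 |
            pts$predicted < 0 | pts$predicted > 1)) {
    stop("observed/predicted cumulative incidences must lie in [0, 1]")
  }
  class(pts) <- c("validation_points", "data.frame")
  pts
}

#' @rdname read_validation_points
#' @export
write_validation_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a study configuration as a YAML file
#'
#' The same structured-text dialect as equation bundles: top-level
#' `schema`, `study_id`, `description`, `follow_up`, `dependency_class`,
#' `subgroups` (baseline profile fields, `weight`, optional trajectory
#' paths), `endpoints`, and optional `strata`.
#'
#' @param config A [study_config()].
#' @param path File path.
#' @return `read_study_config()` returns a [study_config()];
#'   `write_study_config()` returns `path` invisibly.
#' @export
write_study_config <- function(config, path) {
  ser_prof <- function(p) {
    list(age = p$age, sex = p$sex, smoker = p$smoker,
         diabetes_duration = p$diabetes_duration, hba1c = p$hba1c,
         sbp = p$sbp, lipid_ratio = p$lipid_ratio, bmi = p$bmi,
         ldl = if (is.na(p$ldl)) NULL else p$ldl,
         egfr = if (is.na(p$egfr)) NULL else p$egfr,
         albuminuria_stage = p$albuminuria_stage,
         event_history = as.list(p$event_history[p$event_history > 0]))
  }
  ser_sub <- function(s) {
    out <- list(baseline = ser_prof(s$baseline), weight = s$weight)
    if (!is.null(s$trajectory)) {
      out$trajectory <- lapply(unclass(s$trajectory), as.numeric)
    }
    out
  }
  out <- list(
    schema = "t2dcohort-study/1",
    study_id = config$study_id, description = config$description,
    follow_up = config$follow_up,
    dependency_class = config$dependency_class,
    subgroups = unname(lapply(config$subgroups, ser_sub)),
    endpoints = lapply(seq_len(nrow(config$endpoints)), function(i) {
      e <- config$endpoints[i, ]
      list(endpoint_id = e$endpoint_id, observed = e$observed,
           horizon = e$horizon,
           stratum_id = if (is.na(e$stratum_id)) NULL else e$stratum_id)
    }),
    strata = if (is.null(config$strata)) NULL else {
      lapply(config$strata, function(st) {
        list(subgroups = unname(lapply(st$subgroups, ser_sub)))
      })
    })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "t2dcohort-study/1")) {
    stop("unrecognised study schema: ", raw$schema)
  }
  de_prof <- function(p) {
    risk_profile(age = p$age, sex = p$sex, smoker = isTRUE(p$smoker),
                 diabetes_duration = p$diabetes_duration, hba1c = p$hba1c,
                 sbp = p$sbp, lipid_ratio = p$lipid_ratio, bmi = p$bmi,
                 ldl = p$ldl %||% NA_real_, egfr = p$egfr %||% NA_real_,
                 albuminuria_stage = p$albuminuria_stage %||% "none",
                 event_history = unlist(p$event_history) %||% numeric())
  }
  de_sub <- function(s) {
    sg <- subgroup_spec(de_prof(s$baseline), s$weight)
    if (!is.null(s$trajectory)) {
      tr <- lapply(s$trajectory, as.numeric)
      class(tr) <- "biomarker_trajectory"
      sg$trajectory <- tr
    }
    sg
  }
  ep <- do.call(rbind, lapply(raw$endpoints, function(e) {
    data.frame(endpoint_id = e$endpoint_id, observed = e$observed,
               horizon = e$horizon,
               stratum_id = e$stratum_id %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  study_config(
    study_id = raw$study_id,
    subgroups = lapply(raw$subgroups, de_sub),
    endpoints = ep, follow_up = unlist(raw$follow_up),
    strata = if (is.null(raw$strata)) NULL else {
      lapply(raw$strata, function(st) {
        list(subgroups = lapply(st$subgroups, de_sub))
      })
    },
    description = raw$description %||% "",
    dependency_class = raw$dependency_class)
}
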