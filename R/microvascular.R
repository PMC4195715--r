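#' Transition specification for a progressive microvascular chain
#'
#' A baseline annual transition probability, optionally rescaled by a
#' power-law biomarker modifier in the NIH-model lineage: the applied
#' probability is `baseline * (x / reference)^exponent`, where `x` is the
#' current cohort-mean value of `covariate`.
#'
#' @param baseline_annual_prob Baseline annual transition probability.
#' @param modifier `"none"` or `"power"`.
#' @param covariate Profile field driving the power modifier (default
#'   `"hba1c"`; `"sbp"` is the usual choice for nephropathy).
#' @param reference Reference covariate value at which the multiplier is 1.
#' @param exponent Power-law exponent.
#' @return An object of class `transition_spec`.
#' @export
transition_spec <- function(baseline_annual_prob,
                            modifier = c("none", "power"),
                            covariate = "hba1c", reference = 10,
                            exponent = 1) {
  modifier <- match.arg(modifier)
  if (baseline_annual_prob < 0 || baseline_annual_prob > 1) {
    stop("baseline_annual_prob must lie in [0, 1]")
  }
  if (modifier == "power" && reference <= 0) {
    stop("power modifier reference must be positive")
  }
  structure(
    list(baseline_annual_prob = baseline_annual_prob, modifier = modifier,
         covariate = covariate, reference = reference, exponent = exponent),
    class = "transition_spec"
  )
}

#' Progressive microvascular disease track
#'
#' An ordered chain of health states from `none` to the end stage, with
#' forward-only transitions. Default state ladders:
#' retinopathy `none -> background -> proliferative -> blindness`;
#' nephropathy `none -> microalbuminuria -> macroalbuminuria -> esrd`;
#' neuropathy `none -> symptomatic -> amputation`.
#'
#' @param organ `"retinopathy"`, `"nephropathy"` or `"neuropathy"`.
#' @param states Ordered character vector of state names (mild to severe).
#' @param transitions List of transitions, each a list with `from`, `to`
#'   (state names, `to` strictly later than `from`) and `spec`
#'   (a [transition_spec()]).
#' @return An object of class `mv_track`.
#' @export
mv_track <- function(organ, states, transitions) {
  organ <- match.arg(organ, c("retinopathy", "nephropathy", "neuropathy"))
  if (anyDuplicated(states)) stop("track states must be distinct")
  for (tr in transitions) {
    i <- match(tr$from, states)
    j <- match(tr$to, states)
    if (is.na(i) || is.na(j)) {
      stop("transition references unknown state: ", tr$from, " -> ", tr$to)
    }
    if (j <= i) {
      stop("backward or self transition not allowed: ", tr$from, " -> ", tr$to)
    }
    if (!inherits(tr$spec, "transition_spec")) {
      stop("each transition needs a transition_spec")
    }
  }
  structure(list(organ = organ, states = states, transitions = transitions),
            class = "mv_track")
}

#' Biomarker risk multiplier for one transition
#'
#' @param spec A [transition_spec()].
#' @param profile A [risk_profile()].
#' @return Non-negative multiplier; 1 for `modifier = "none"` or when the
#'   covariate sits at its reference value.
#' @export
risk_multiplier <- function(spec, profile) {
  if (spec$modifier == "none") return(1)
  x <- profile[[spec$covariate]]
  if (is.null(x) || !is.finite(x)) {
    stop("modifier covariate '", spec$covariate, "' missing from profile")
  }
  if (x <= 0 && spec$exponent != round(spec$exponent)) {
    stop("non-positive covariate with fractional exponent")
  }
  (x / spec$reference)^spec$exponent
}

#' Annual transition matrix for a track at the current profile
#'
#' Off-diagonal entries are baseline probabilities scaled by
#' [risk_multiplier()]; each diagonal is the residual so rows sum to 1.
#' A row whose scaled off-diagonal sum exceeds 1 is an error (the modifier
#' has pushed probabilities out of range), naming the offending state.
#'
#' @param track An [mv_track()].
#' @param profile A [risk_profile()].
#' @return Row-stochastic matrix with `track$states` as dimnames; zero mass
#'   below the diagonal.
#' @export
build_transition_matrix <- function(track, profile) {
  n <- length(track$states)
  m <- matrix(0, n, n, dimnames = list(track$states, track$states))
  for (tr in track$transitions) {
    p <- tr$spec$baseline_annual_prob * risk_multiplier(tr$spec, profile)
    m[tr$from, tr$to] <- m[tr$from, tr$to] + p
  }
  off <- rowSums(m)
  if (any(off > 1 + 1e-12)) {
    bad <- track$states[which(off > 1 + 1e-12)[1]]
    stop("transition row for state '", bad, "' in ", track$organ,
         " exceeds 1 after risk scaling (sum = ",
         format(max(off), digits = 6), ")")
  }
  diag(m) <- diag(m) + (1 - off)
  m
}

#' Advance a track occupancy vector one annual cycle
#'
#' @param occupancy Probability vector over the track's states (sums to 1).
#' @param matrix Row-stochastic transition matrix from
#'   [build_transition_matrix()].
#' @return Updated occupancy vector.
#' @export
step_track <- function(occupancy, matrix) {
  if (length(occupancy) != nrow(matrix)) {
    stop("occupancy length does not match transition matrix dimension")
  }
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy must sum to 1")
  }
  out <- as.vector(occupancy %*% matrix)
  names(out) <- rownames(matrix)
  out
}

#' Default microvascular tracks (synthetic placeholder probabilities)
#'
#' State ladders follow the NIH/DiDACT lineage; the baseline annual
#' transition probabilities shipped here are synthetic placeholders of
#' plausible magnitude, intended for testing and demonstration until a
#' transcription of the published values is supplied (see the methods
#' vignette for the transcription workflow). HbA1c modifies all organs;
#' nephropathy progression is additionally SBP-sensitive.
#'
#' @param hba1c_ref Reference HbA1c (percent) at which multipliers are 1.
#' @param sbp_ref Reference SBP (mmHg) for the nephropathy modifier.
#' @return Named list of three [mv_track()] objects.
#' @export
default_tracks <- function(hba1c_ref = 10, sbp_ref = 140) {
  pw <- function(p, k, cov = "hba1c", ref = hba1c_ref) {
    transition_spec(p, "power", covariate = cov, reference = ref, exponent = k)
  }
  list(
    retinopathy = mv_track(
      "retinopathy",
      c("none", "background_retinopathy", "proliferative_retinopathy",
        "blindness"),
      list(
        list(from = "none", to = "background_retinopathy",
             spec = pw(0.060, 2)),
        list(from = "background_retinopathy", to = "proliferative_retinopathy",
             spec = pw(0.025, 2)),
        list(from = "proliferative_retinopathy", to = "blindness",
             spec = pw(0.030, 1))
      )),
    nephropathy = mv_track(
      "nephropathy",
      c("none", "microalbuminuria", "macroalbuminuria", "esrd"),
      list(
        list(from = "none", to = "microalbuminuria", spec = pw(0.040, 2)),
        list(from = "microalbuminuria", to = "macroalbuminuria",
             spec = pw(0.030, 1, cov = "sbp", ref = sbp_ref)),
        list(from = "macroalbuminuria", to = "esrd", spec = pw(0.020, 1))
      )),
    neuropathy = mv_track(
      "neuropathy",
      c("none", "symptomatic_neuropathy", "amputation"),
      list(
        list(from = "none", to = "symptomatic_neuropathy",
             spec = pw(0.035, 2)),
        list(from = "symptomatic_neuropathy", to = "amputation",
             spec = pw(0.010, 1))
      ))
  )
}
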