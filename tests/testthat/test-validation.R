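test_that("registry totals match the published study table", {
  reg <- study_registry()
  expect_equal(nrow(reg), 12)
  expect_equal(sum(reg$n_endpoints), 167)
  expect_lte(sum(reg$participants), 90000)
})

test_that("dependency classification follows the rule table", {
  for (b in c("ukpds_om1", "ukpds_om2", "ndr")) {
    expect_equal(classify_dependency("WESDR", b), "dependent")
    expect_equal(classify_dependency("Rochester", b), "dependent")
    expect_equal(classify_dependency("UKPDS 33", b), "dependent")
    expect_equal(classify_dependency("UKPDS 80", b), "dependent")
    for (s in c("ACCORD", "ADOPT", "ADVANCE", "ASPEN", "CARDS", "Osaka")) {
      expect_equal(classify_dependency(s, b), "independent")
    }
  }
  expect_equal(classify_dependency("NDR (I)", "ndr"), "dependent")
  expect_equal(classify_dependency("NDR (II)", "ndr"), "dependent")
  expect_equal(classify_dependency("NDR (I)", "ukpds_om1"), "independent")
  expect_equal(classify_dependency("NDR (I)", "ukpds_om2"), "independent")
  expect_equal(classify_dependency("NDR (II)", "ukpds_om2"), "independent")

  expect_error(classify_dependency("Unknown Study", "ndr"), "registry")
  expect_equal(
    classify_dependency("Unknown Study", "ndr",
                        dependency_class = "always_independent"),
    "independent")
})

test_that("endpoint filtering keeps matchable cumulative incidences only", {
  raw <- data.frame(
    endpoint_id = c("major_microvascular_events", "macroalbuminuria",
                    "all_cause_death", "mi", "blindness"),
    measure = c("cumulative_incidence", "prevalence",
                "cumulative_incidence", "cumulative_incidence",
                "cumulative_incidence"),
    stringsAsFactors = FALSE
  )
  out <- filter_endpoints(raw)
  expect_setequal(out$included$endpoint_id,
                  c("all_cause_death", "mi", "blindness"))
  expect_equal(out$included$category[out$included$endpoint_id == "mi"],
               "macrovascular")
  ex <- out$excluded
  expect_equal(ex$reason[ex$endpoint_id == "major_microvascular_events"],
               "no-model-match")
  expect_equal(ex$reason[ex$endpoint_id == "macroalbuminuria"],
               "not-cumulative-incidence")
})

test_that("run_validation emits one point per endpoint, stratum and horizon", {
  cfg <- make_toy_study(21, horizon = 5)
  bundle <- attr(cfg, "truth")$bundle
  pts <- run_validation(cfg, bundle)
  expect_s3_class(pts, "validation_points")
  expect_equal(nrow(pts), nrow(cfg$endpoints))
  expect_true(all(pts$observed >= 0 & pts$observed <= 1))
  expect_true(all(pts$predicted >= 0 & pts$predicted <= 1))
  expect_true(all(pts$dependency == "independent"))
  expect_false(any(is.na(pts$category)))

  # bit-identical re-run: deterministic pipeline
  expect_identical(run_validation(cfg, bundle), pts)

  # endpoint horizons beyond follow-up are contract errors
  cfg_bad <- cfg
  cfg_bad$endpoints$horizon[1] <- 10
  expect_error(run_validation(cfg_bad, bundle), "follow-up")
})

test_that("strata and time points multiply the unit of analysis", {
  bundle <- make_toy_bundle(31)
  base_sub <- function(seedoff) {
    prof <- risk_profile(age = 55 + seedoff, sex = "male",
                         diabetes_duration = 6 + seedoff)
    list(subgroups = list(subgroup_spec(prof, 1)))
  }
  strata <- list(a1 = base_sub(0), a2 = base_sub(4),
                 a3 = base_sub(8), a4 = base_sub(12))
  ep <- expand.grid(endpoint_id = c("mi", "stroke", "all_cause_death",
                                    "blindness"),
                    stratum_id = names(strata),
                    stringsAsFactors = FALSE)
  ep$observed <- 0.1
  ep$horizon <- rep(c(3, 5), length.out = nrow(ep))
  cfg <- study_config("STRAT-TOY", subgroups = list(), endpoints = ep,
                      follow_up = 5, strata = strata,
                      dependency_class = "always_dependent")
  pts <- run_validation(cfg, bundle)
  expect_equal(nrow(pts), 16)  # 4 strata x 4 endpoints
  expect_equal(length(unique(pts$stratum_id)), 4)
  # predictions at longer horizons dominate same-stratum shorter ones
  for (s in names(strata)) {
    p3 <- pts$predicted[pts$stratum_id == s & pts$horizon == 3 &
                          pts$endpoint_id == "mi"]
    p5 <- pts$predicted[pts$stratum_id == s & pts$horizon == 5 &
                          pts$endpoint_id == "mi"]
    if (length(p3) && length(p5)) expect_gte(p5, p3)
  }
})

test_that("point counts are invariant to the bundle choice", {
  cfg <- make_toy_study(41, horizon = 4)
  b1 <- attr(cfg, "truth")$bundle
  b2 <- make_toy_bundle(99)
  p1 <- run_validation(cfg, b1)
  p2 <- run_validation(cfg, b2)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$observed, p2$observed)
  expect_false(isTRUE(all.equal(p1$predicted, p2$predicted)))
})

test_that("endpoint counting sums and partitions across configs", {
  expect_equal(count_endpoints(list())$total, 0L)
  cfg <- make_toy_study(51, horizon = 3)
  one <- count_endpoints(list(cfg))
  expect_equal(one$total, nrow(cfg$endpoints))
  expect_equal(sum(one$by_category), one$total)
  two <- count_endpoints(list(cfg, cfg))
  expect_equal(two$total, 2 * nrow(cfg$endpoints))
  expect_equal(count_endpoints(study_registry())$total, 167)
})

test_that("validation points round-trip through CSV", {
  pts <- make_synthetic_points(seed = 8, n = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_points(pts, path)
  back <- read_validation_points(path)
  expect_equal(back$observed, pts$observed, tolerance = 1e-12)
  expect_equal(back$predicted, pts$predicted, tolerance = 1e-12)
  expect_s3_class(back, "validation_points")

  bad <- pts; bad$predicted <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_validation_points(path2), "predicted")
})

test_that("study configurations round-trip through YAML", {
  cfg <- make_toy_study(61, horizon = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$study_id, cfg$study_id)
  expect_equal(back$endpoints$observed, cfg$endpoints$observed,
               tolerance = 1e-12)
  bundle <- attr(cfg, "truth")$bundle
  p1 <- run_validation(cfg, bundle)
  p2 <- run_validation(back, bundle)
  expect_equal(p2$predicted, p1$predicted, tolerance = 1e-10)
  expect_equal(p2$dependency, p1$dependency)
})
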