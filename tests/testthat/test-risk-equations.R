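test_that("linear predictor assembles beta'x with transforms", {
  prof <- test_profile()

  empty <- equation_spec("mi", "weibull", c(intercept = 0), shape = 1)
  empty$coefficients <- numeric(0)
  expect_identical(linear_predictor(empty, prof), 0)

  centred <- equation_spec(
    "mi", "logistic_annual", c(h = 0.5),
    transforms = list(h = list(covariate = "hba1c", offset = 7.0)))
  prof9 <- test_profile(); prof9$hba1c <- 9.0
  expect_equal(linear_predictor(centred, prof9), 0.5 * (9 - 7))

  mixed <- equation_spec(
    "mi", "logistic_annual",
    c(intercept = -2, male = 0.3, smoker = 0.2, sbp = 0.01, mi = 1.5))
  prof$event_history[["mi"]] <- 0.25
  expect_equal(linear_predictor(mixed, prof),
               -2 + 0.3 + 0.2 + 0.01 * 148 + 1.5 * 0.25)

  bad <- equation_spec("mi", "logistic_annual", c(xyz = 1))
  expect_error(linear_predictor(bad, prof), "xyz")
})

test_that("Weibull annual probability matches the hazard-integral oracle", {
  prof <- test_profile()
  # constant-hazard limit: rho = 1, exp(b'x) = 0.05
  s1 <- equation_spec("mi", "weibull", c(intercept = log(0.05)), shape = 1)
  for (t in c(0, 3, 17)) {
    expect_equal(weibull_annual_prob(s1, prof, t), 1 - exp(-0.05),
                 tolerance = 1e-12)
  }
  # rho = 2, lambda = 0.01, t = 3: oracle integrates lambda*rho*t^(rho-1)
  s2 <- equation_spec("mi", "weibull", c(intercept = log(0.01)), shape = 2)
  oracle <- hazard_integral_prob(function(u) 0.01 * 2 * u, 3)
  expect_equal(weibull_annual_prob(s2, prof, 3), oracle, tolerance = 1e-9)
  expect_equal(weibull_annual_prob(s2, prof, 3), 1 - exp(-(0.16 - 0.09)),
               tolerance = 1e-12)
  # zero hazard
  s3 <- equation_spec("mi", "weibull", c(intercept = -Inf), shape = 2)
  expect_equal(weibull_annual_prob(s3, prof, 5), 0)
  # contract errors
  expect_error(weibull_annual_prob(s2, prof, -1), "non-negative")
  expect_error(equation_spec("mi", "weibull", c(intercept = 0), shape = 0),
               "shape")
})

test_that("Gompertz annual probability matches oracle and theta->0 limit", {
  prof <- test_profile()
  s <- equation_spec("ihd", "gompertz", c(intercept = log(0.002)),
                     shape = 0.1)
  oracle <- hazard_integral_prob(function(u) 0.002 * exp(0.1 * u), 10)
  expect_equal(gompertz_annual_prob(s, prof, 10), oracle, tolerance = 1e-9)
  expect_equal(gompertz_annual_prob(s, prof, 10), 0.005701,
               tolerance = 1e-4)

  # theta -> 0 reduces to the constant hazard 1 - exp(-exp(b'x))
  s0 <- equation_spec("ihd", "gompertz", c(intercept = log(0.03)),
                      shape = 1e-8)
  expect_equal(gompertz_annual_prob(s0, prof, 7), 1 - exp(-0.03),
               tolerance = 1e-6)

  szero <- equation_spec("ihd", "gompertz", c(intercept = -Inf), shape = 0.1)
  expect_equal(gompertz_annual_prob(szero, prof, 3), 0)
  expect_error(equation_spec("ihd", "gompertz", c(intercept = 0), shape = 0),
               "nonzero")
})

test_that("constant-hazard equivalence: Weibull rho=1 vs Gompertz theta->0", {
  prof <- test_profile()
  for (lambda in c(0.001, 0.02, 0.15)) {
    sw <- equation_spec("mi", "weibull", c(intercept = log(lambda)),
                        shape = 1)
    sg <- equation_spec("mi", "gompertz", c(intercept = log(lambda)),
                        shape = 1e-8)
    const <- 1 - exp(-lambda)
    for (t in c(0, 5, 20)) {
      expect_equal(weibull_annual_prob(sw, prof, t), const,
                   tolerance = 1e-6)
      expect_equal(gompertz_annual_prob(sg, prof, t), const,
                   tolerance = 1e-6)
    }
  }
})

test_that("five-year risks convert to annual and round-trip", {
  expect_equal(fiveyear_to_annual(0), 0)
  expect_equal(fiveyear_to_annual(1), 1)
  expect_equal(fiveyear_to_annual(0.4), 1 - (1 - 0.4)^(1 / 5),
               tolerance = 1e-12)
  expect_equal(fiveyear_to_annual(0.4), 0.09712, tolerance = 1e-4)
  for (p5 in c(0.001, 0.123, 0.4, 0.87, 0.999)) {
    p1 <- fiveyear_to_annual(p5)
    expect_lt(abs((1 - (1 - p1)^5) - p5), 1e-12)
  }
  expect_error(fiveyear_to_annual(1.2), "\\[0, 1\\]")
})

test_that("competing probabilities combine by complement-product", {
  expect_identical(combine_competing(numeric(0)), 0)
  expect_equal(combine_competing(c(0.1, 0.2)), 0.28, tolerance = 1e-12)
  expect_equal(combine_competing(0.37), 0.37, tolerance = 1e-12)
  expect_gte(combine_competing(c(0.3, 0.5, 0.01)), 0.5)
  expect_error(combine_competing(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("all annual probabilities lie in [0,1] for random inputs", {
  set.seed(42)
  prof_pool <- replicate(20, risk_profile(
    age = runif(1, 35, 85), sex = sample(c("female", "male"), 1),
    smoker = runif(1) < 0.5, diabetes_duration = runif(1, 1, 30),
    hba1c = runif(1, 6, 11), sbp = runif(1, 110, 180),
    lipid_ratio = runif(1, 2.5, 7), bmi = runif(1, 20, 40)),
    simplify = FALSE)
  for (i in 1:40) {
    fam <- sample(c("weibull", "gompertz", "logistic_annual",
                    "fiveyear_risk"), 1)
    spec <- equation_spec(
      "mi", fam,
      c(intercept = runif(1, -8, 1), hba1c = runif(1, -0.3, 0.3),
        male = runif(1, -1, 1)),
      shape = switch(fam, weibull = runif(1, 0.3, 3),
                     gompertz = runif(1, -0.2, 0.2) + 0.01, NULL))
    prof <- prof_pool[[sample(20, 1)]]
    p <- t2dcohort:::annual_prob(spec, prof, t = runif(1, 0, 39))
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("annual probability is monotone in a positive-beta covariate", {
  mk <- function(h) {
    p <- test_profile(); p$hba1c <- h; p
  }
  for (fam in c("weibull", "gompertz", "logistic_annual", "fiveyear_risk")) {
    spec <- equation_spec(
      "mi", fam, c(intercept = -5, hba1c = 0.12),
      shape = switch(fam, weibull = 1.4, gompertz = 0.05, NULL))
    probs <- vapply(seq(6, 11, by = 0.5), function(h) {
      t2dcohort:::annual_prob(spec, mk(h), t = 8)
    }, numeric(1))
    expect_true(all(diff(probs) > 0))
  }
})

test_that("bundles validate coverage and round-trip through YAML", {
  b <- make_toy_bundle(3)
  expect_error(
    equation_bundle("bad", b$specs[c("mi", "ihd")], b$mortality_specs),
    "lacks specs")
  expect_error(equation_bundle("bad", b$specs, list()), "mortality")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_bundle(b, path)
  b2 <- read_bundle(path)
  prof <- test_profile()
  expect_equal(evaluate_bundle(b2, prof, which = "both"),
               evaluate_bundle(b, prof, which = "both"), tolerance = 1e-12)
  expect_identical(b2$name, b$name)

  # unknown schema rejected
  raw <- yaml::read_yaml(path)
  raw$schema <- "other/9"
  yaml::write_yaml(raw, path)
  expect_error(read_bundle(path), "schema")
})

test_that("evaluate_bundle reports every event and flags uncovered ids", {
  b <- make_toy_bundle(4)
  prof <- test_profile()
  p <- evaluate_bundle(b, prof, which = "both")
  expect_setequal(names(p),
                  c(macrovascular_events(), "cvd_death", "other_death"))
  expect_true(all(p >= 0 & p <= 1))
})
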