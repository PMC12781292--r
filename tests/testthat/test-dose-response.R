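test_that("default knots sit at the (.05, .35, .65, .95) quantiles", {
  expect_equal(default_knots(1:100), c(5.95, 35.65, 65.35, 95.05))
  expect_error(default_knots(c(1, 1, 2, 2)), "distinct")
  expect_error(default_knots(c(rep(1, 96), 2, 3, 4, 5)), "ties")
  # translation equivariance
  x <- runif(80)
  expect_equal(default_knots(x + 10), default_knots(x) + 10)
})

test_that("the restricted cubic basis matches its closed form", {
  kn <- c(0, 1, 2, 3)
  b <- rcs_basis(1.5, kn)
  expect_equal(ncol(b), 3)
  # hand evaluation of the truncated-power formula, /(t4-t1)^2 scaling;
  # at x = 1.5 the (x - t3)+ and (x - t4)+ pieces truncate to zero
  expect_equal(unname(b[1, "x1"]), 1.5^3 / 9)
  expect_equal(unname(b[1, "x2"]), 0.5^3 / 9)
  # nonlinear terms vanish at and below the first knot
  expect_equal(unname(rcs_basis(c(-2, 0), kn)[, c("x1", "x2")]), matrix(0, 2, 2))
})

test_that("the fitted spline is linear in the tails and twice differentiable", {
  set.seed(31)
  for (rep in 1:3) {
    kn <- sort(runif(4, 0, 10))
    while (min(diff(kn)) < 0.5) kn <- sort(runif(4, 0, 10))
    f <- function(x) rcs_basis(x, kn) %*% c(1, 2, -3)
    h <- 1e-3
    second <- function(x) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
    # second derivative ~ 0 outside [t1, t4], nonzero inside
    expect_lt(max(abs(second(c(kn[1] - 1, kn[4] + 1)))), 1e-4)
    expect_gt(max(abs(second(seq(kn[2], kn[3], length.out = 5)))), 1e-3)
    # continuity across each knot
    for (k in kn) expect_lt(abs(f(k + 1e-8) - f(k - 1e-8)), 1e-6)
  }
})

test_that("RCS regression reproduces an exactly linear truth", {
  set.seed(5)
  d <- tibble::tibble(cf_total = runif(200, 30, 150))
  d$md_total <- 3 + 0.5 * d$cf_total
  fit <- fit_rcs_model(d, "md_total", "cf_total")
  co <- coef(fit$lm)
  expect_lt(max(abs(co[3:4])), 1e-8)
  suppressWarnings({ # noiseless fixture: "essentially perfect fit"
    expect_equal(summary(fit$lm)$r.squared, 1)
    # linear contrast: effect = slope * (q75 - q25)
    te <- total_effect(fit)
    expect_equal(te$estimate, 0.5 * (te$x_high - te$x_low), tolerance = 1e-8)
    expect_equal(total_effect(fit, 0.5, 0.5)$estimate, 0)
    expect_equal(total_effect(fit, 0.5, 0.5)$se, 0)
  })
  expect_error(total_effect(fit, 0.8, 0.2), "q_low")
})

test_that("model fitting rejects degenerate designs", {
  d <- tibble::tibble(cf_total = c(1, 5, 9, 20), md_total = 1:4)
  expect_error(fit_rcs_model(d, "md_total", "cf_total", knots = c(1, 5, 9, 20)), "parameters")
  d2 <- tibble::tibble(cf_total = runif(50, 0, 100))
  d2$md_total <- d2$cf_total
  d2$dup <- factor(rep(c("a", "b"), 25))
  d2$dup2 <- d2$dup
  expect_error(
    fit_rcs_model(d2, "md_total", "cf_total", covariates = c("dup", "dup2")),
    "collinear"
  )
})

test_that("the saturating cohort fit is monotone and steepest mid-range", {
  co <- simulate_dose_response_cohort(cohort_spec(), seed = 77)
  fit <- fit_rcs_model(co, "md_total", "cf_total")
  grid <- seq(min(co$cf_total), max(co$cf_total), length.out = 120)
  curve <- predict_curve(fit, grid)
  slope <- diff(curve$fitted) / diff(curve$exposure)
  # monotone up to estimation noise in the sparse tails: any local decrease
  # is negligible against the overall rise
  expect_gt(min(slope), -0.05 * max(slope))
  expect_gt(curve$fitted[120] - curve$fitted[1], 50)
  mid <- grid[-1] >= 60 & grid[-1] <= 90
  low <- grid[-1] < 50
  high <- grid[-1] > 110
  expect_gt(max(slope[mid]), max(slope[low | high]))
})

test_that("nonlinearity F-test is exact-zero for a linearized response", {
  set.seed(11)
  d <- tibble::tibble(cf_total = runif(150, 0, 100), md_total = rnorm(150))
  fit <- fit_rcs_model(d, "md_total", "cf_total")
  # subtract the nonlinear components' fitted contribution: the refit has
  # exactly zero nonlinear coefficients but nonzero residuals
  X <- rcs_basis(d$cf_total, fit$knots)
  beta_nl <- coef(fit$lm)[3:4]
  d$md_total <- d$md_total - as.vector(X[, 2:3] %*% beta_nl)
  refit <- fit_rcs_model(d, "md_total", "cf_total", knots = fit$knots)
  expect_lt(max(abs(coef(refit$lm)[3:4])), 1e-10)
  expect_gt(sum(residuals(refit$lm)^2), 0)
  expect_lt(nonlinearity_test(refit)$statistic, 1e-12)
})

test_that("nonlinearity test has power against the saturating truth", {
  rej <- vapply(1:200, function(i) {
    co <- simulate_dose_response_cohort(cohort_spec(), seed = 1000 + i)
    nonlinearity_test(fit_rcs_model(co, "md_total", "cf_total"))$p.value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.9)
})

test_that("standardized fits are scale invariant with near-zero intercept", {
  set.seed(13)
  d <- tibble::tibble(cf_total = rnorm(400))
  d$md_total <- d$cf_total + rnorm(400, 0, 0.5)
  s1 <- standardized_fit(d, "md_total", "cf_total")
  d10 <- dplyr::mutate(d, cf_total = cf_total * 10)
  s2 <- standardized_fit(d10, "md_total", "cf_total")
  expect_equal(coef(s1$lm), coef(s2$lm), tolerance = 1e-10)
  expect_lt(abs(coef(s1$lm)[1]), 0.1)
  # pure linear noiseless truth: standardized slope is the correlation, 1
  d$md_total <- 2 * d$cf_total + 7
  s3 <- standardized_fit(d, "md_total", "cf_total")
  expect_equal(unname(coef(s3$lm)[2]), 1, tolerance = 1e-8)
  expect_error(standardized_fit(dplyr::mutate(d, cf_total = 1), "md_total", "cf_total"), "variance")
})

test_that("prediction bands are narrowest in the data bulk and vanish without noise", {
  set.seed(17)
  d <- tibble::tibble(cf_total = rnorm(500, 50, 10))
  d$md_total <- 20 + d$cf_total + rnorm(500, 0, 5)
  fit <- fit_rcs_model(d, "md_total", "cf_total")
  curve <- predict_curve(fit, c(mean(d$cf_total), max(d$cf_total)))
  expect_lt(curve$se[1], curve$se[2])
  expect_error(predict_curve(fit, numeric(0)), "empty")
  # identical data -> identical curves
  fit2 <- fit_rcs_model(d, "md_total", "cf_total")
  expect_identical(predict_curve(fit, 40:60), predict_curve(fit2, 40:60))
  # noiseless linear truth -> zero-width band
  d$md_total <- 1 + 2 * d$cf_total
  fit0 <- fit_rcs_model(d, "md_total", "cf_total")
  expect_lt(suppressWarnings(max(predict_curve(fit0)$se)), 1e-6)
})

test_that("spline fits equal an independently coded truncated-power fit", {
  set.seed(19)
  for (rep in 1:3) {
    x <- runif(120, 0, 100)
    y <- rnorm(120)
    kn <- default_knots(x)
    fit <- fit_rcs_model(tibble::tibble(cf_total = x, md_total = y), "md_total", "cf_total")
    # unnormalized truncated-power basis, coded from the formula directly
    pp3 <- function(u) pmax(u, 0)^3
    tp <- function(tj) {
      pp3(x - tj) - pp3(x - kn[3]) * (kn[4] - tj) / (kn[4] - kn[3]) +
        pp3(x - kn[4]) * (kn[3] - tj) / (kn[4] - kn[3])
    }
    ref <- lm(y ~ x + tp(kn[1]) + tp(kn[2]))
    expect_equal(unname(fitted(fit$lm)), unname(fitted(ref)), tolerance = 1e-8)
  }
})

test_that("adding covariates never lowers R-squared (model nesting)", {
  set.seed(23)
  for (rep in 1:3) {
    co <- simulate_dose_response_cohort(cohort_spec(n = 300), seed = 500 + rep)
    f1 <- fit_rcs_model(co, "md_total", "cf_total")
    f2 <- fit_rcs_model(co, "md_total", "cf_total",
      covariates = c("gender", "age_band", "education")
    )
    expect_gte(glance(f2)$r.squared, glance(f1)$r.squared)
  }
})
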