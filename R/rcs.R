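#' Default knot placement for a 4-knot restricted cubic spline
#'
#' Knots at the empirical (0.05, 0.35, 0.65, 0.95) quantiles of the
#' predictor — Harrell's default positions for four knots.
#'
#' @param x Numeric predictor sample with at least 20 distinct values for a
#'   stable placement (hard minimum: enough distinct values that the knots
#'   are strictly increasing).
#' @param k Number of knots; only 4 is supported.
#' @return Numeric vector of 4 strictly increasing knots.
#' @examples
#' default_knots(1:100)
#' @export
default_knots <- function(x, k = 4) {
  if (k != 4) abort("only 4-knot splines are supported")
  x <- x[is.finite(x)]
  if (length(unique(x)) < k) abort("fewer than 4 distinct predictor values")
  kn <- unname(quantile(x, c(0.05, 0.35, 0.65, 0.95), type = 7))
  if (any(diff(kn) <= 0)) {
    abort("ties collapse the default knots; supply knots manually")
  }
  kn
}

#' Restricted cubic spline basis (4 knots)
#'
#' Truncated-power construction: with knots `t1 < t2 < t3 < t4` the basis
#' has the linear term `x` plus two nonlinear terms
#' \deqn{S_j(x) = \frac{(x-t_j)_+^3 - (x-t_3)_+^3 \frac{t_4-t_j}{t_4-t_3}
#'   + (x-t_4)_+^3 \frac{t_3-t_j}{t_4-t_3}}{(t_4-t_1)^2}, \quad j = 1, 2,}
#' which vanish for `x <= t1` and make the function linear beyond `t4`
#' (continuous with continuous first and second derivatives everywhere).
#' The `(t4 - t1)^2` scaling keeps the nonlinear coefficients on a scale
#' comparable with the linear one.
#'
#' @param x Numeric vector (finite).
#' @param knots 4 strictly increasing knots.
#' @return Numeric matrix with columns `x`, `x1`, `x2`.
#' @export
rcs_basis <- function(x, knots) {
  if (!all(is.finite(x))) abort("x must be finite")
  if (length(knots) != 4 || any(diff(knots) <= 0)) {
    abort("knots must be 4 strictly increasing values")
  }
  t1 <- knots[1]; t3 <- knots[3]; t4 <- knots[4]
  norm <- (t4 - t1)^2
  pp3 <- function(u) pmax(u, 0)^3
  nl <- function(tj) {
    (pp3(x - tj) - pp3(x - t3) * (t4 - tj) / (t4 - t3) +
      pp3(x - t4) * (t3 - tj) / (t4 - t3)) / norm
  }
  cbind(x = x, x1 = nl(knots[1]), x2 = nl(knots[2]))
}

#' Fit a restricted-cubic-spline dose-response model
#'
#' Ordinary least squares of the outcome on the 4-knot RCS basis of the
#' exposure, optionally adjusted for categorical covariates (dummy-coded
#' against their first level). An unadjusted fit is the conventional
#' "Model 1" of dose-response reports; adding covariates gives "Model 2".
#'
#' @param data Data frame holding the variables.
#' @param outcome,exposure Column names (strings) of the outcome (e.g.
#'   `md_total`) and exposure (e.g. `cf_total`).
#' @param covariates Optional character vector of covariate column names.
#' @param knots Optional 4 knots; defaults to [default_knots()] of the
#'   exposure.
#' @return An object of class `rcs_fit` wrapping the `lm` fit, with methods
#'   for [tidy()], [glance()], [nonlinearity_test()], [total_effect()],
#'   [predict_curve()] and [autoplot()].
#' @export
fit_rcs_model <- function(data, outcome, exposure, covariates = NULL,
                          knots = NULL) {
  stopifnot(is.data.frame(data))
  for (v in c(outcome, exposure, covariates)) {
    if (!v %in% names(data)) abort(paste0("unknown column: ", v))
  }
  y <- data[[outcome]]
  x <- data[[exposure]]
  if (!is.numeric(y) || !is.numeric(x)) abort("outcome and exposure must be numeric")
  knots <- knots %||% default_knots(x)
  basis <- rcs_basis(x, knots)
  colnames(basis) <- paste0(exposure, c("", "'", "''"))
  X <- basis
  if (length(covariates) > 0) {
    cov_df <- data[covariates]
    cov_df[] <- lapply(cov_df, function(c) {
      if (is.character(c)) c <- factor(c)
      if (is.factor(c)) droplevels(c) else c
    })
    mm <- model.matrix(~., data = cov_df)[, -1, drop = FALSE]
    X <- cbind(basis, mm)
  }
  if (nrow(X) <= ncol(X) + 1) abort("more parameters than observations")
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    abort(paste0(
      "rank-deficient design; collinear column(s): ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  structure(
    list(
      lm = fit, knots = knots, outcome = outcome, exposure = exposure,
      covariates = covariates, n = length(y),
      spline_terms = colnames(basis), x = x
    ),
    class = "rcs_fit"
  )
}

#' @export
print.rcs_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<rcs_fit> %s ~ rcs(%s, 4 knots)%s, n = %d\n  R2 = %.3f (adj %.3f), nonlinearity F(2, %d) = %.2f, p = %.3g\n",
    x$outcome, x$exposure,
    if (length(x$covariates)) paste0(" + ", length(x$covariates), " covariates") else "",
    x$n, g$r.squared, g$adj.r.squared, g$df.residual, g$f.nonlinear, g$p.nonlinear
  ))
  invisible(x)
}

#' @export
tidy.rcs_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4],
    spline = rownames(s) %in% paste0("`", x$spline_terms, "`") |
      rownames(s) %in% x$spline_terms
  )
}

#' @export
glance.rcs_fit <- function(x, ...) {
  s <- summary(x$lm)
  nl <- nonlinearity_test(x)
  tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, df.residual = x$lm$df.residual,
    f.nonlinear = nl$statistic, p.nonlinear = nl$p.value,
    nobs = x$n
  )
}

spline_coef_idx <- function(fit) {
  cn <- names(coef(fit$lm))
  idx <- match(c(fit$spline_terms, paste0("`", fit$spline_terms, "`")), cn)
  idx <- idx[!is.na(idx)]
  if (length(idx) != 3) abort("internal: spline terms not found in fit")
  idx
}

#' Joint F-test of the spline's nonlinear terms
#'
#' Compares the full model against the nested model with the two nonlinear
#' basis terms removed (covariates retained); under the null of a purely
#' linear exposure effect the statistic is F(2, residual df).
#'
#' @param fit An [fit_rcs_model()] result.
#' @return A tibble with `statistic`, `df1`, `df2`, `p.value`.
#' @export
nonlinearity_test <- function(fit) {
  if (!inherits(fit, "rcs_fit")) abort("fit must be an rcs_fit")
  full <- fit$lm
  dat <- full$model
  nl_cols <- fit$spline_terms[2:3]
  reduced <- lm(.y ~ ., data = dat[, !(names(dat) %in% nl_cols), drop = FALSE])
  a <- anova(reduced, full)
  tibble(
    statistic = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
    p.value = a$`Pr(>F)`[2]
  )
}

#' Total (interquartile) effect of the exposure
#'
#' The difference in model-predicted outcome between the exposure's
#' `q_high` and `q_low` sample quantiles, covariates held at reference.
#' The standard error follows from the coefficient covariance by the delta
#' method (the contrast is linear in the coefficients), and the interval is
#' the z-based Wald interval `estimate +/- 1.96 se`.
#'
#' @param fit An [fit_rcs_model()] result.
#' @param q_low,q_high Exposure quantiles contrasted; default interquartile
#'   (0.25, 0.75).
#' @return A tibble with `x_low`, `x_high`, `estimate`, `se`, `conf.low`,
#'   `conf.high`.
#' @export
total_effect <- function(fit, q_low = 0.25, q_high = 0.75) {
  if (!inherits(fit, "rcs_fit")) abort("fit must be an rcs_fit")
  if (q_low > q_high) abort("q_low must be <= q_high")
  xs <- unname(quantile(fit$x, c(q_low, q_high), type = 7))
  contrast <- rcs_basis(xs[2], fit$knots) - rcs_basis(xs[1], fit$knots)
  idx <- spline_coef_idx(fit)
  beta <- coef(fit$lm)[idx]
  V <- vcov(fit$lm)[idx, idx]
  est <- sum(contrast * beta)
  se <- sqrt(as.numeric(contrast %*% V %*% t(contrast)))
  ci <- wald_ci(est, se)
  tibble(
    x_low = xs[1], x_high = xs[2],
    estimate = est, se = se,
    conf.low = ci$conf.low, conf.high = ci$conf.high
  )
}

#' Standardized RCS fit
#'
#' Z-scores both the outcome and the exposure before building the spline
#' basis and fitting, so coefficients are comparable across scales.
#'
#' @param data Data frame.
#' @param outcome,exposure Column names.
#' @return An `rcs_fit` on the standardized variables.
#' @export
standardized_fit <- function(data, outcome, exposure) {
  y <- data[[outcome]]
  x <- data[[exposure]]
  if (sd(y) == 0 || sd(x) == 0) abort("zero-variance outcome or exposure")
  z <- tibble(
    !!outcome := as.vector(scale(y)),
    !!exposure := as.vector(scale(x))
  )
  fit_rcs_model(z, outcome, exposure)
}

#' Prediction curve with pointwise 95% confidence band
#'
#' Model-predicted mean outcome over a grid of exposure values, covariates
#' at reference, with the pointwise Wald band from the coefficient
#' covariance. The band narrows where the data are dense and widens toward
#' the exposure extremes.
#'
#' @param fit An [fit_rcs_model()] result.
#' @param grid Exposure values; defaults to 200 points over the observed
#'   range.
#' @param level Band coverage, default 0.95.
#' @return A tibble with `exposure`, `fitted`, `se`, `conf.low`, `conf.high`.
#' @export
predict_curve <- function(fit, grid = NULL, level = 0.95) {
  if (!inherits(fit, "rcs_fit")) abort("fit must be an rcs_fit")
  grid <- grid %||% seq(min(fit$x), max(fit$x), length.out = 200)
  if (length(grid) == 0) abort("empty prediction grid")
  basis <- rcs_basis(grid, fit$knots)
  cn <- names(coef(fit$lm))
  X <- matrix(0, length(grid), length(cn))
  X[, 1] <- 1 # intercept; covariates stay at reference (all dummies 0)
  X[, spline_coef_idx(fit)] <- basis
  beta <- coef(fit$lm)
  V <- vcov(fit$lm)
  fitted <- as.vector(X %*% beta)
  se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    exposure = grid, fitted = fitted, se = se,
    conf.low = fitted - z * se, conf.high = fitted + z * se
  )
}
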