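#' Estimation settings for the Ising network
#'
#' @param gamma EBIC hyperparameter (>= 0); larger values select sparser
#'   per-node models. Default 0.25.
#' @param rule Symmetrization rule: `"AND"` (edge kept only when both
#'   directed nodewise coefficients are nonzero; the conservative default)
#'   or `"OR"` (kept when either is).
#' @param n_lambda Length of the penalty path, log-spaced from the
#'   max-penalty null model down to `lambda_min_ratio` times it.
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest.
#' @param method `"elasso"` (L1 path + EBIC, default) or `"pseudo"` (plain
#'   maximum pseudo-likelihood via unpenalised logistic regressions, for
#'   small dense problems).
#' @return A list of class `ising_config`.
#' @export
ising_config <- function(gamma = 0.25, rule = c("AND", "OR"),
                         n_lambda = 100, lambda_min_ratio = 0.01,
                         method = c("elasso", "pseudo")) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  if (gamma < 0) abort("gamma must be >= 0")
  if (n_lambda < 2 || lambda_min_ratio <= 0 || lambda_min_ratio >= 1) {
    abort("need n_lambda >= 2 and 0 < lambda_min_ratio < 1")
  }
  structure(
    list(
      gamma = gamma, rule = rule, n_lambda = n_lambda,
      lambda_min_ratio = lambda_min_ratio, method = method
    ),
    class = "ising_config"
  )
}

# Nodewise fit for one node: returns intercept + coefficient vector over the
# other nodes, selected by EBIC along a glmnet L1 path.
fit_node_elasso <- function(y, x, config) {
  n <- length(y)
  p <- ncol(x)
  # glmnet needs >= 2 predictors; pad 2-node problems with a null column
  padded <- p == 1
  if (padded) x <- cbind(x, 0)
  # lambda_max: smallest penalty with an all-zero slope solution
  lam_max <- max(abs(crossprod(x, y - mean(y)))) / n
  lam_max <- max(lam_max, 1e-4)
  lambda <- exp(seq(log(lam_max), log(lam_max * config$lambda_min_ratio),
    length.out = config$n_lambda
  ))
  fit <- glmnet::glmnet(x, y,
    family = "binomial", lambda = lambda,
    standardize = FALSE
  )
  # binomial deviance = -2 loglik for 0/1 outcomes (saturated loglik 0)
  dev <- (1 - fit$dev.ratio) * fit$nulldev
  k <- fit$df
  ebic <- dev + k * log(n) + 2 * config$gamma * k * log(p)
  best <- which.min(ebic)
  beta <- as.vector(fit$beta[, best])
  if (padded) beta <- beta[1]
  list(
    intercept = fit$a0[[best]], beta = beta,
    ebic = ebic, n_edges = k[best]
  )
}

fit_node_pseudo <- function(y, x) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
    family = stats::binomial()
  ))
  list(intercept = fit$coefficients[1], beta = fit$coefficients[-1])
}

#' Estimate an Ising network from binary symptom data
#'
#' Nodewise regularized logistic regression (the eLasso approach): each node
#' is regressed on all others along an L1 path, the per-node penalty is
#' chosen by the extended BIC, and directed coefficient pairs are
#' symmetrized into undirected couplings (AND rule by default: both
#' directions must be selected, and the edge weight is the mean of the two
#' directed estimates). Thresholds are the selected per-node intercepts.
#'
#' @param data A 0/1 matrix or data frame (respondents x nodes), e.g. a
#'   [assemble_network_matrix()] result; column names become node labels.
#' @param config An [ising_config()].
#' @param partition Optional community labels per node; defaults to the
#'   input's `partition` attribute, if present.
#' @return An [ising_model()].
#' @export
estimate_ising <- function(data, config = ising_config(), partition = NULL) {
  partition <- partition %||% attr(data, "partition")
  x <- unclass(as.matrix(data))
  attr(x, "partition") <- NULL
  storage.mode(x) <- "double"
  if (!all(x %in% c(0, 1))) abort("data must be binary 0/1")
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2 || nrow(unique(x)) < 2) abort("need at least 2 distinct observations")
  labels <- colnames(x) %||% paste0("V", seq_len(p))
  colnames(x) <- labels
  cm <- colMeans(x)
  if (any(cm == 0 | cm == 1)) {
    abort(paste0(
      "zero-variance node(s): ",
      paste(labels[cm == 0 | cm == 1], collapse = ", ")
    ))
  }
  tau <- numeric(p)
  directed <- matrix(0, p, p, dimnames = list(labels, labels))
  for (j in seq_len(p)) {
    fit <- if (config$method == "elasso") {
      fit_node_elasso(x[, j], x[, -j, drop = FALSE], config)
    } else {
      fit_node_pseudo(x[, j], x[, -j, drop = FALSE])
    }
    tau[j] <- fit$intercept
    directed[j, -j] <- fit$beta
  }
  both <- (directed != 0) & (t(directed) != 0)
  either <- (directed != 0) | (t(directed) != 0)
  keep <- if (config$method == "pseudo") either else {
    if (config$rule == "AND") both else either
  }
  omega <- ifelse(keep, (directed + t(directed)) / 2, 0)
  diag(omega) <- 0
  ising_model(tau = tau, omega = omega, labels = labels, partition = partition)
}
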