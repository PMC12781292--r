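#' Default covariate category probabilities for a synthetic ICU-nurse cohort
#'
#' Marginal distributions of the demographic covariates typical of a
#' national tertiary-ICU nursing sample (female-dominated, young, mostly
#' undergraduate-educated). Each element is a named probability vector;
#' probabilities are normalized to sum to one. Covariates are sampled
#' independently (joint structure is not modelled).
#'
#' @return Named list of named numeric vectors.
#' @export
default_covariate_marginals <- function() {
  norm <- function(x) x / sum(x)
  lapply(list(
    gender = c(male = 0.116, female = 0.884),
    age_band = c(`18-29` = 0.465, `30-39` = 0.457, `40-49` = 0.071, `50-59` = 0.006),
    marital_status = c(married = 0.608, unmarried = 0.381, divorced = 0.009, other = 0.002),
    icu_tenure = c(
      `<=5y` = 0.510, `6-10y` = 0.276, `11-15y` = 0.161,
      `16-20y` = 0.034, `>=21y` = 0.019
    ),
    education = c(
      college = 0.208, undergraduate = 0.764,
      postgraduate = 0.025, doctorate = 0.003
    ),
    title = c(
      nurse = 0.202, nurse_practitioner = 0.448, nurse_in_charge = 0.319,
      associate_chief = 0.026, chief = 0.005
    ),
    income_band = c(
      `<=4000` = 0.141, `4001-8000` = 0.524, `8001-12000` = 0.284,
      `12001-16000` = 0.042, `16001-20000` = 0.008, `>=20001` = 0.002
    ),
    income_satisfaction = c(satisfied = 0.440, unsatisfied = 0.560)
  ), norm)
}

#' Specification of a synthetic dose-response cohort
#'
#' Defines the generative conditions for [simulate_dose_response_cohort()]:
#' cohort size, covariate marginals, the CF distribution (truncated normal
#' matched to a typical cohort: median 82, IQR 24, range 35-139), the
#' CF-to-MD curve, residual noise and additive covariate effects on MD.
#'
#' The default curve is a 4-parameter logistic
#' `MD(CF) = lower + (upper - lower) / (1 + exp(-(CF - midpoint)/scale))`
#' with lower plateau 25, upper plateau 110, midpoint 75 and scale 8 —
#' a saturating shape rising sharply for CF between roughly 60 and 90 and
#' flattening at both extremes. `curve = "linear"` substitutes
#' `MD(CF) = linear_intercept + linear_slope * CF`, the null of the
#' nonlinearity test.
#'
#' @param n Cohort size; default 645.
#' @param covariate_marginals See [default_covariate_marginals()].
#' @param curve `"logistic4"` or `"linear"`.
#' @param lower,upper,midpoint,scale 4PL curve parameters (MD points; CF
#'   points for `midpoint`/`scale`).
#' @param linear_intercept,linear_slope Parameters of the linear curve.
#' @param noise_sd Residual SD of MD given CF, in MD points; default 15.
#' @param covariate_effects Named list of named numeric vectors: additive MD
#'   shifts per category. Default: males shifted by −8 MD points, all other
#'   covariates null (gender is the one covariate with a real effect).
#' @param cf_median,cf_iqr,cf_min,cf_max CF distribution parameters.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 645,
                        covariate_marginals = default_covariate_marginals(),
                        curve = c("logistic4", "linear"),
                        lower = 25, upper = 110, midpoint = 75, scale = 8,
                        linear_intercept = 0, linear_slope = 0.6,
                        noise_sd = 15,
                        covariate_effects = list(gender = c(male = -8)),
                        cf_median = 82, cf_iqr = 24, cf_min = 35, cf_max = 139) {
  curve <- match.arg(curve)
  if (n < 1) abort("n must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  for (nm in names(covariate_marginals)) {
    p <- covariate_marginals[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      abort(paste0("covariate marginal '", nm, "' must be probabilities summing to 1"))
    }
  }
  if (!all(names(covariate_effects) %in% names(covariate_marginals))) {
    abort("covariate_effects name a covariate absent from the marginals")
  }
  structure(
    list(
      n = n, covariate_marginals = covariate_marginals, curve = curve,
      lower = lower, upper = upper, midpoint = midpoint, scale = scale,
      linear_intercept = linear_intercept, linear_slope = linear_slope,
      noise_sd = noise_sd, covariate_effects = covariate_effects,
      cf_median = cf_median, cf_iqr = cf_iqr, cf_min = cf_min, cf_max = cf_max
    ),
    class = "cohort_spec"
  )
}

dose_curve <- function(cf, spec) {
  if (spec$curve == "linear") {
    spec$linear_intercept + spec$linear_slope * cf
  } else {
    spec$lower + (spec$upper - spec$lower) /
      (1 + exp(-(cf - spec$midpoint) / spec$scale))
  }
}

# inverse-CDF draw from a normal truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Simulate a dose-response cohort
#'
#' Draws CF totals from a truncated normal (SD backed out of the IQR),
#' passes them through the spec's CF-to-MD curve, adds covariate shifts and
#' Gaussian noise, and truncates MD to its 0-352 scale range. Covariates are
#' drawn independently from the spec's marginals.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with `cf_total`, `md_total` and one column per
#'   covariate.
#' @export
simulate_dose_response_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec")
  with_seed_if(seed, {
    cf <- rtruncnorm(
      spec$n, spec$cf_median, spec$cf_iqr / (2 * qnorm(0.75)),
      spec$cf_min, spec$cf_max
    )
    covs <- purrr::map(spec$covariate_marginals, function(p) {
      factor(
        sample(names(p), spec$n, replace = TRUE, prob = p),
        levels = names(p)
      )
    })
    shift <- numeric(spec$n)
    for (nm in names(spec$covariate_effects)) {
      eff <- spec$covariate_effects[[nm]]
      s <- unname(eff[as.character(covs[[nm]])])
      shift <- shift + ifelse(is.na(s), 0, s)
    }
    md_raw <- dose_curve(cf, spec) + shift + rnorm(spec$n, 0, spec$noise_sd)
    n_out <- sum(md_raw < 0 | md_raw > 352)
    if (n_out > 0.1 * spec$n) {
      warn(sprintf(
        "%d of %d raw MD values fell outside [0, 352] before truncation",
        n_out, spec$n
      ))
    }
    dplyr::bind_cols(
      tibble(cf_total = cf, md_total = pmin(pmax(md_raw, 0), 352)),
      tibble::as_tibble(covs)
    )
  })
}

#' Specification of a ground-truth two-community Ising network
#'
#' Describes a planted 52-node (by default) MD/CF network: random positive
#' couplings within each community at a given density, explicitly planted
#' cross-community "bridge" couplings, and thresholds drawn uniformly from
#' `threshold_range`.
#'
#' @param n_md,n_cf Community sizes; defaults 22 and 30.
#' @param intra_density Probability of an edge within a community.
#' @param intra_weight_range Range of intra-community edge weights.
#' @param bridge_edges Data frame (or tibble) with columns `cf`, `md`,
#'   `weight`: the planted cross-community couplings, e.g.
#'   `tibble(cf = "CF26", md = "MD10", weight = 0.8)`.
#' @param threshold_range Interval thresholds are drawn from; default
#'   `c(-2, -1)` (symptoms inactive by default, as in sparse symptom data).
#' @return A list of class `network_truth_spec`.
#' @export
network_truth_spec <- function(n_md = 22, n_cf = 30,
                               intra_density = 0.15,
                               intra_weight_range = c(0.3, 0.9),
                               bridge_edges = tibble(
                                 cf = character(), md = character(),
                                 weight = numeric()
                               ),
                               threshold_range = c(-2, -1)) {
  if (n_md < 1 || n_cf < 1) abort("both communities need at least one node")
  if (intra_density < 0 || intra_density > 1) abort("intra_density must be in [0, 1]")
  bridge_edges <- as_tibble(bridge_edges)
  if (!all(c("cf", "md", "weight") %in% names(bridge_edges))) {
    abort("bridge_edges needs columns cf, md, weight")
  }
  if (!all(is.finite(bridge_edges$weight))) abort("bridge weights must be finite")
  structure(
    list(
      n_md = n_md, n_cf = n_cf, intra_density = intra_density,
      intra_weight_range = intra_weight_range,
      bridge_edges = bridge_edges, threshold_range = threshold_range
    ),
    class = "network_truth_spec"
  )
}

#' Build a ground-truth Ising model from a network spec
#'
#' Cross-community couplings are exactly the planted bridge list (all other
#' cross entries zero), so bridge-centrality and intervention-target
#' recovery can be checked against a known answer.
#'
#' @param spec A [network_truth_spec()].
#' @param seed Integer seed for the random intra-community structure.
#' @return An [ising_model()] with an "MD"/"CF" partition.
#' @export
make_ground_truth_ising <- function(spec = network_truth_spec(), seed = NULL) {
  if (!inherits(spec, "network_truth_spec")) abort("spec must be a network_truth_spec")
  labels <- c(paste0("MD", seq_len(spec$n_md)), paste0("CF", seq_len(spec$n_cf)))
  n <- length(labels)
  bad <- setdiff(c(spec$bridge_edges$cf, spec$bridge_edges$md), labels)
  if (length(bad) > 0) {
    abort(paste0("bridge edge references unknown node(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(grepl("^CF", spec$bridge_edges$cf)) ||
    !all(grepl("^MD", spec$bridge_edges$md))) {
    abort("bridge edges must join a CF node to an MD node")
  }
  with_seed_if(seed, {
    omega <- matrix(0, n, n, dimnames = list(labels, labels))
    for (block in list(seq_len(spec$n_md), spec$n_md + seq_len(spec$n_cf))) {
      for (i in block) {
        for (j in block) {
          if (j > i && runif(1) < spec$intra_density) {
            w <- runif(1, spec$intra_weight_range[1], spec$intra_weight_range[2])
            omega[i, j] <- omega[j, i] <- w
          }
        }
      }
    }
    for (r in seq_len(nrow(spec$bridge_edges))) {
      i <- match(spec$bridge_edges$cf[r], labels)
      j <- match(spec$bridge_edges$md[r], labels)
      omega[i, j] <- omega[j, i] <- spec$bridge_edges$weight[r]
    }
    tau <- runif(n, spec$threshold_range[1], spec$threshold_range[2])
    ising_model(tau, omega,
      labels = labels,
      partition = setNames(
        c(rep("MD", spec$n_md), rep("CF", spec$n_cf)), labels
      )
    )
  })
}

#' Simulate a binary symptom cohort from an Ising model
#'
#' Thin wrapper over [sample_ising()] named for its role in the synthetic
#' pipeline.
#'
#' @param model An [ising_model()].
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param sweeps Gibbs sweeps per respondent.
#' @return A `symptom_matrix`.
#' @export
simulate_binary_cohort <- function(model, n, seed = NULL, sweeps = 100) {
  if (n <= 0) abort("n must be positive")
  sample_ising(model, n, sweeps = sweeps, seed = seed)
}

#' Synthesize item-level responses consistent with a binary symptom matrix
#'
#' Inverts the dichotomization rules: a CF node value of 0 becomes the raw
#' response 1 and a 1 becomes a uniform draw from 2..5; an MD node value of
#' 0 zeroes the frequency, the intensity, or both (at random, the other
#' drawn uniformly from 0..4) and a 1 draws frequency and intensity each
#' uniformly from 1..4. Dichotomizing the synthesized table reproduces the
#' input matrix exactly, so the full scoring pipeline can be exercised end
#' to end.
#'
#' @param binary A `symptom_matrix` with 22 MD and 30 CF columns (MD first).
#' @param seed Integer seed.
#' @param map ProQOL subscale map giving each CF node's item number.
#' @return An item-level tibble with `respondent_id`, `proqol_*`,
#'   `mdsr_freq_*`, `mdsr_intensity_*` columns.
#' @export
synthesize_item_responses <- function(binary, seed = NULL,
                                      map = proqol_subscale_map()) {
  validate_subscale_map(map)
  x <- unclass(as.matrix(binary))
  if (ncol(x) != 52) abort("expected a 52-column (22 MD + 30 CF) binary matrix")
  if (!all(x %in% c(0, 1))) abort("matrix must be binary 0/1")
  n <- nrow(x)
  md <- x[, 1:22, drop = FALSE]
  cf <- x[, 23:52, drop = FALSE]
  with_seed_if(seed, {
    freq <- matrix(0L, n, 22)
    intens <- matrix(0L, n, 22)
    on <- md == 1
    freq[on] <- sample(1:4, sum(on), replace = TRUE)
    intens[on] <- sample(1:4, sum(on), replace = TRUE)
    # off items: zero the frequency, the intensity, or both
    off <- which(!on)
    which_zero <- sample(1:3, length(off), replace = TRUE)
    other <- sample(0:4, length(off), replace = TRUE)
    freq[off] <- ifelse(which_zero == 2, other, 0L)
    intens[off] <- ifelse(which_zero == 1, other, 0L)

    pro_nodes <- matrix(1L, n, 30)
    on_cf <- cf == 1
    pro_nodes[on_cf] <- sample(2:5, sum(on_cf), replace = TRUE)
    # node order -> administered item order
    item_of_node <- map$item[order(map$cf_node)]
    pro <- matrix(1L, n, 30)
    pro[, item_of_node] <- pro_nodes

    out <- tibble(respondent_id = seq_len(n))
    for (j in 1:30) out[[paste0("proqol_", j)]] <- pro[, j]
    for (j in 1:22) out[[paste0("mdsr_freq_", j)]] <- freq[, j]
    for (j in 1:22) out[[paste0("mdsr_intensity_", j)]] <- intens[, j]
    out
  })
}
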