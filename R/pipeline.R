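#' Assemble a pipeline configuration
#'
#' Validates a nested configuration list (typically read from YAML via
#' [read_pipeline_config()]) for [run_pipeline()]. Stages toggle
#' independently; every enabled stochastic stage must carry an explicit
#' seed, and unknown keys are rejected so silent typos cannot change an
#' analysis.
#'
#' @param config Named list; see Details.
#' @details Recognized top-level keys: `input` (path to an item-level CSV,
#'   or NULL to use the synthetic cohort), `out_dir`, `stages` (named list
#'   of logicals: `synthetic`, `scoring`, `dose_response`, `network`,
#'   `bridges`, `stability`, `nira`), `seeds` (named list: `synthetic`,
#'   `stability`, `nira`), and parameter blocks `synthetic` (`n`,
#'   `n_network`), `dose_response` (`covariates`, `knots`), `network`
#'   (`gamma`, `rule`), `stability` (`n_boot`, `drop_fractions`), `nira`
#'   (`n_sim`, `k`, `direction`).
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    input = NULL,
    out_dir = tempfile("moralnet_run_"),
    stages = list(
      synthetic = TRUE, scoring = TRUE, dose_response = TRUE,
      network = TRUE, bridges = TRUE, stability = FALSE, nira = TRUE
    ),
    seeds = list(synthetic = NULL, stability = NULL, nira = NULL),
    synthetic = list(n = 645, n_network = 645),
    dose_response = list(covariates = NULL, knots = NULL),
    network = list(gamma = 0.25, rule = "AND"),
    stability = list(n_boot = 100, drop_fractions = seq(0.1, 0.7, by = 0.1)),
    nira = list(n_sim = 5000, k = 2, direction = "both")
  )
  check_keys <- function(user, def, path) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0) {
      abort(paste0("unknown config key(s): ", paste0(path, unknown, collapse = ", ")))
    }
  }
  check_keys(config, defaults, "")
  merged <- defaults
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      check_keys(config[[k]], defaults[[k]], paste0(k, "$"))
      merged[[k]] <- utils::modifyList(defaults[[k]], config[[k]])
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  random_stages <- c(
    synthetic = isTRUE(merged$stages$synthetic),
    stability = isTRUE(merged$stages$stability),
    nira = isTRUE(merged$stages$nira)
  )
  for (st in names(random_stages)[random_stages]) {
    if (is.null(merged$seeds[[st]])) {
      abort(paste0("enabled random stage '", st, "' has no seed in seeds$", st))
    }
  }
  structure(merged, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — synthetic-cohort generation (or
#' CSV input), instrument scoring, dose-response spline modelling, Ising
#' network estimation, bridge centrality, centrality stability, and
#' threshold-intervention simulation — writing one artifact per stage under
#' `out_dir` plus a `run.json` log of parameters and seeds.
#'
#' @param config A [pipeline_config()], a plain list, or a YAML path.
#' @return Invisibly, a named list of in-memory stage results plus
#'   `artifacts` (paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  artifacts <- list()
  stage <- function(name, enabled, code) {
    if (!enabled) return(invisible(NULL))
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  stage("input", TRUE, {
    if (!is.null(config$input)) {
      results$items <- as_tibble(utils::read.csv(config$input, check.names = FALSE))
    } else if (isTRUE(config$stages$synthetic)) {
      seed <- config$seeds$synthetic
      results$cohort <- simulate_dose_response_cohort(
        cohort_spec(n = config$synthetic$n), seed = seed
      )
      truth <- make_ground_truth_ising(
        network_truth_spec(bridge_edges = tibble(
          cf = c("CF26", "CF28"), md = c("MD10", "MD14"), weight = c(0.9, 0.7)
        )),
        seed = derive_seed(seed, 1)
      )
      results$truth <- truth
      binary <- simulate_binary_cohort(truth, config$synthetic$n_network,
        seed = derive_seed(seed, 2)
      )
      results$items <- synthesize_item_responses(binary, seed = derive_seed(seed, 3))
    } else {
      abort("no input file and synthetic stage disabled")
    }
  })

  stage("scoring", isTRUE(config$stages$scoring) && !is.null(results$items), {
    results$scored <- score_responses(results$items)
    artifacts$scored <- write_stage_csv(results$scored, config$out_dir, "scored")
    results$binary <- assemble_network_matrix(results$items)
    artifacts$binary <- write_stage_csv(
      as_tibble(results$binary), config$out_dir, "binary_matrix"
    )
  })

  stage("dose_response", isTRUE(config$stages$dose_response), {
    dr_data <- results$cohort %||% results$scored
    if (is.null(dr_data)) abort("no scored data available")
    covs <- config$dose_response$covariates
    covs <- covs[covs %in% names(dr_data)]
    fit1 <- fit_rcs_model(dr_data, "md_total", "cf_total",
      knots = config$dose_response$knots
    )
    results$model1 <- fit1
    if (length(covs) > 0) {
      results$model2 <- fit_rcs_model(dr_data, "md_total", "cf_total",
        covariates = covs, knots = config$dose_response$knots
      )
    }
    summ <- dplyr::bind_rows(
      dplyr::mutate(glance(fit1), model = "model1"),
      if (length(covs) > 0) dplyr::mutate(glance(results$model2), model = "model2")
    )
    artifacts$dose_response <- write_stage_csv(summ, config$out_dir, "dose_response")
    artifacts$curve <- write_stage_csv(
      predict_curve(fit1), config$out_dir, "dose_response_curve"
    )
  })

  stage("network", isTRUE(config$stages$network) && !is.null(results$binary), {
    results$network <- estimate_ising(
      results$binary,
      ising_config(gamma = config$network$gamma, rule = config$network$rule)
    )
    path <- file.path(config$out_dir, "network.json")
    write_ising_json(results$network, path)
    artifacts$network <- path
  })

  stage("bridges", isTRUE(config$stages$bridges) && !is.null(results$network), {
    results$bridges <- bridge_indices(results$network)
    artifacts$bridges <- write_stage_csv(results$bridges, config$out_dir, "bridge_indices")
  })

  stage("stability", isTRUE(config$stages$stability) && !is.null(results$binary), {
    results$stability <- case_drop_bootstrap(
      results$binary,
      drop_fractions = config$stability$drop_fractions,
      n_boot = config$stability$n_boot,
      seed = config$seeds$stability
    )
    artifacts$stability <- write_stage_csv(
      tidy(results$stability), config$out_dir, "stability"
    )
  })

  stage("nira", isTRUE(config$stages$nira) && !is.null(results$network), {
    raw <- run_scenarios(results$network,
      n_sim = config$nira$n_sim, k = config$nira$k,
      direction = config$nira$direction, seed = config$seeds$nira
    )
    results$nira <- compare_to_baseline(raw)
    artifacts$nira <- write_stage_csv(results$nira, config$out_dir, "nira")
  })

  log <- list(
    package_version = as.character(utils::packageVersion("moralnet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config)
  )
  log_path <- file.path(config$out_dir, "run.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, null = "null", digits = NA)
  artifacts$log <- log_path
  results$artifacts <- artifacts
  invisible(results)
}
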