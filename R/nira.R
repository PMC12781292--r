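#' Perturb one node's threshold for an in-silico intervention
#'
#' Shifts the target node's threshold by `k` times the sample standard
#' deviation (n − 1 denominator) of all estimated thresholds: alleviating
#' interventions lower it (the symptom becomes harder to activate),
#' aggravating interventions raise it. All couplings and other thresholds
#' are untouched.
#'
#' @param model An [ising_model()].
#' @param node Node label or index to perturb.
#' @param direction `"alleviating"` or `"aggravating"`.
#' @param k Effect size in threshold-SD multiples; default 2.
#' @return The perturbed [ising_model()].
#' @export
perturb_threshold <- function(model, node,
                              direction = c("alleviating", "aggravating"),
                              k = 2) {
  direction <- match.arg(direction)
  if (length(model$tau) < 2) abort("model must have at least 2 nodes")
  i <- node_index(model, node)
  s <- sd(model$tau)
  if (s == 0) abort("all thresholds identical: perturbation scale is degenerate")
  shift <- k * s * if (direction == "alleviating") -1 else 1
  tau <- model$tau
  tau[i] <- tau[i] + shift
  ising_model(tau, model$omega, labels = model$labels, partition = model$partition)
}

#' Simulate threshold-intervention scenarios on a symptom network
#'
#' For each direction, simulates one baseline scenario from the unmodified
#' model plus one scenario per node of the intervention community (the CF
#' sub-network), each with that node's threshold shifted by ±`k` SD — 31
#' scenarios per direction for a 30-node CF community. Every scenario draws
#' `n_sim` independent observations and records each observation's
#' outcome-community (MD) sum score.
#'
#' @param model An [ising_model()] with a two-community partition.
#' @param n_sim Observations per scenario; default 5000.
#' @param k Threshold shift in SD multiples; default 2.
#' @param direction `"alleviating"`, `"aggravating"` or `"both"`.
#' @param outcome_community,intervention_community Community labels of the
#'   outcome sum score and of the intervened nodes; defaults "MD" and "CF".
#' @param sweeps Gibbs sweeps per observation (see [sample_ising()]).
#' @param seed Integer seed; scenario sub-seeds are derived from it.
#' @return An object of class `nira_raw`: tibble `scores` with one row per
#'   scenario (`direction`, `scenario` — node label or "baseline",
#'   `mean_md`, and the per-observation sums as a list-column `md_sums`).
#' @export
run_scenarios <- function(model, n_sim = 5000, k = 2,
                          direction = c("both", "alleviating", "aggravating"),
                          outcome_community = "MD",
                          intervention_community = "CF",
                          sweeps = 100, seed = NULL) {
  direction <- match.arg(direction)
  if (n_sim < 2) abort("n_sim must be >= 2")
  if (is.null(model$partition)) abort("model needs a community partition")
  part <- model$partition
  if (!all(c(outcome_community, intervention_community) %in% part)) {
    abort("outcome and intervention communities must appear in the partition")
  }
  md_nodes <- model$labels[part == outcome_community]
  cf_nodes <- model$labels[part == intervention_community]
  dirs <- if (direction == "both") c("alleviating", "aggravating") else direction
  scen <- tidyr::expand_grid(
    direction = dirs,
    scenario = c("baseline", cf_nodes)
  )
  rows <- purrr::pmap(
    list(scen$direction, scen$scenario, seq_len(nrow(scen))),
    function(dir, sc, j) {
      m <- if (sc == "baseline") model else perturb_threshold(model, sc, dir, k)
      samp <- sample_ising(m, n_sim, sweeps = sweeps, seed = derive_seed(seed, j))
      sums <- rowSums(samp[, md_nodes, drop = FALSE])
      tibble(
        direction = dir, scenario = sc,
        mean_md = mean(sums), md_sums = list(sums)
      )
    }
  )
  structure(
    list(
      scores = dplyr::bind_rows(rows),
      n_sim = n_sim, k = k,
      outcome_community = outcome_community,
      intervention_community = intervention_community
    ),
    class = "nira_raw"
  )
}

#' Test intervention scenarios against baseline
#'
#' Welch two-sample t-tests of each scenario's per-observation MD sum scores
#' against the same direction's baseline, with Benjamini-Hochberg FDR
#' adjustment across the scenarios of each direction separately.
#'
#' @param raw A [run_scenarios()] result.
#' @param alpha Significance level on the adjusted p-values; default 0.05.
#' @return A tibble of class `nira_result`: `direction`, `scenario`,
#'   `mean_md`, `delta` (vs baseline), `statistic`, `p.value`, `p.adjusted`,
#'   `significant`. Baseline rows carry `delta = 0` and `NA` tests.
#' @export
compare_to_baseline <- function(raw, alpha = 0.05) {
  if (!inherits(raw, "nira_raw")) abort("raw must come from run_scenarios()")
  out <- raw$scores |>
    dplyr::group_by(.data$direction) |>
    dplyr::group_modify(function(d, key) {
      base <- d$md_sums[[which(d$scenario == "baseline")]]
      if (is.null(base)) abort("missing baseline observations")
      res <- purrr::map2_dfr(d$scenario, d$md_sums, function(sc, sums) {
        if (is.null(sums)) abort("missing per-observation scores")
        if (sc == "baseline") {
          return(tibble(delta = 0, statistic = NA_real_, p.value = NA_real_))
        }
        tt <- t.test(sums, base, var.equal = FALSE)
        tibble(
          delta = mean(sums) - mean(base),
          statistic = unname(tt$statistic), p.value = tt$p.value
        )
      })
      d2 <- dplyr::bind_cols(dplyr::select(d, "scenario", "mean_md"), res)
      d2$p.adjusted <- NA_real_
      is_scen <- d2$scenario != "baseline"
      d2$p.adjusted[is_scen] <- p.adjust(d2$p.value[is_scen], method = "BH")
      d2$significant <- !is.na(d2$p.adjusted) & d2$p.adjusted < alpha
      d2
    }) |>
    dplyr::ungroup()
  class(out) <- c("nira_result", class(out))
  attr(out, "n_sim") <- raw$n_sim
  attr(out, "k") <- raw$k
  out
}

#' Rank significant intervention targets
#'
#' Orders the significantly effective scenarios of one direction by the
#' absolute change in mean MD sum score, largest first — the "core
#' intervention target" readout. Ties break by node label.
#'
#' @param results A [compare_to_baseline()] tibble.
#' @param direction `"alleviating"` or `"aggravating"`.
#' @return The filtered, ordered tibble (possibly empty).
#' @export
identify_core_targets <- function(results,
                                  direction = c("alleviating", "aggravating")) {
  direction <- match.arg(direction)
  results |>
    dplyr::filter(
      .data$direction == !!direction,
      .data$scenario != "baseline",
      .data$significant
    ) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta)), .data$scenario)
}

#' @export
print.nira_raw <- function(x, ...) {
  cat(sprintf(
    "<nira_raw> %d scenarios x %d observations (k = %g SD)\n",
    nrow(x$scores), x$n_sim, x$k
  ))
  invisible(x)
}
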