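#' Case-dropping bootstrap of bridge-centrality indices
#'
#' For each drop fraction f, repeatedly subsamples `(1 - f) * n` respondents
#' without replacement, re-estimates the network and its bridge indices, and
#' correlates each subsample index vector with the full-sample one. The
#' resulting correlation profiles feed [cs_coefficient()].
#'
#' @param data Binary respondent-by-node matrix (e.g.
#'   [assemble_network_matrix()] output).
#' @param partition Community labels; defaults to the data's `partition`
#'   attribute.
#' @param indices Which bridge indices to track.
#' @param drop_fractions Grid of case-drop proportions in (0, 0.75].
#' @param n_boot Subsamples per fraction.
#' @param seed Integer seed.
#' @param config [ising_config()] used for every re-estimation.
#' @param cor_method Correlation between index vectors: `"spearman"`
#'   (default, robust to monotone distortion) or `"pearson"`.
#' @return An object of class `stability_result`: tibble `correlations`
#'   (`fraction`, `boot`, `index`, `correlation`; failed re-estimations are
#'   `NA`) plus the full-sample indices and settings.
#' @export
case_drop_bootstrap <- function(data, partition = NULL,
                                indices = c(
                                  "bridge_strength", "bridge_expected_influence",
                                  "bridge_closeness", "bridge_betweenness"
                                ),
                                drop_fractions = seq(0.05, 0.75, by = 0.05),
                                n_boot = 500, seed = NULL,
                                config = ising_config(),
                                cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  if (n_boot < 1) abort("n_boot must be >= 1")
  if (any(drop_fractions <= 0 | drop_fractions > 0.75)) {
    abort("drop_fractions must lie in (0, 0.75]")
  }
  partition <- partition %||% attr(data, "partition")
  x <- unclass(as.matrix(data))
  n <- nrow(x)
  full <- bridge_indices(estimate_ising(x, config, partition = partition))
  grid <- tidyr::expand_grid(fraction = drop_fractions, boot = seq_len(n_boot))
  cors <- with_seed_if(seed, {
    purrr::pmap(grid, function(fraction, boot) {
      keep <- sample.int(n, size = max(2, round((1 - fraction) * n)))
      sub <- tryCatch(
        bridge_indices(estimate_ising(x[keep, , drop = FALSE], config,
          partition = partition
        )),
        error = function(e) NULL
      )
      vapply(indices, function(ix) {
        if (is.null(sub)) return(NA_real_)
        suppressWarnings(cor(full[[ix]], sub[[ix]], method = cor_method))
      }, 0.0)
    })
  })
  correlations <- dplyr::bind_cols(
    grid[rep(seq_len(nrow(grid)), each = length(indices)), ],
    tibble(
      index = rep(indices, nrow(grid)),
      correlation = unlist(cors, use.names = FALSE)
    )
  )
  structure(
    list(
      correlations = correlations, full_indices = full,
      drop_fractions = drop_fractions, n_boot = n_boot,
      cor_method = cor_method, n = n
    ),
    class = "stability_result"
  )
}

#' Correlation-stability (CS) coefficient
#'
#' The largest case-drop fraction at which at least `conf` (default 95%) of
#' bootstrap correlations with the full-sample index stay at or above
#' `r_min` (default 0.7); 0 if no examined fraction qualifies. Bootstrap
#' replicates whose re-estimation failed count against the criterion.
#'
#' @param stability A [case_drop_bootstrap()] result (or its `correlations`
#'   tibble).
#' @param r_min Correlation floor.
#' @param conf Required proportion of qualifying bootstraps.
#' @return A tibble with `index`, `cs`, `label` (see [interpret_cs()]).
#' @export
cs_coefficient <- function(stability, r_min = 0.7, conf = 0.95) {
  cors <- if (inherits(stability, "stability_result")) {
    stability$correlations
  } else {
    stability
  }
  if (is.null(cors) || nrow(cors) == 0) abort("empty bootstrap output")
  cors |>
    dplyr::group_by(.data$index, .data$fraction) |>
    dplyr::summarise(
      ok = mean(!is.na(.data$correlation) & .data$correlation >= r_min) >= conf,
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      cs = {
        f <- .data$fraction[.data$ok]
        # CS requires the criterion to hold at the fraction and be the
        # largest such fraction; use the max qualifying fraction, 0 if none
        if (length(f) == 0) 0 else max(f)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(label = vapply(.data$cs, interpret_cs, ""))
}

#' Qualitative label for a CS coefficient
#'
#' `> 0.5` strong, `0.25`-`0.5` acceptable, `< 0.25` poor.
#'
#' @param cs CS coefficient in `[0, 0.75]`.
#' @return `"strong"`, `"acceptable"` or `"poor"`.
#' @examples
#' interpret_cs(0.6) # strong
#' interpret_cs(0.25) # acceptable
#' @export
interpret_cs <- function(cs) {
  if (cs < 0 || cs > 0.75) abort("cs must be in [0, 0.75]")
  if (cs > 0.5) "strong" else if (cs >= 0.25) "acceptable" else "poor"
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> %d bootstraps x %d fractions (%s correlation), n = %d\n",
    x$n_boot, length(x$drop_fractions), x$cor_method, x$n
  ))
  print(cs_coefficient(x))
  invisible(x)
}

#' @export
tidy.stability_result <- function(x, ...) {
  x$correlations |>
    dplyr::group_by(.data$index, .data$fraction) |>
    dplyr::summarise(
      mean_cor = mean(.data$correlation, na.rm = TRUE),
      q025 = quantile(.data$correlation, 0.025, na.rm = TRUE),
      q975 = quantile(.data$correlation, 0.975, na.rm = TRUE),
      n_failed = sum(is.na(.data$correlation)),
      .groups = "drop"
    )
}

#' @export
glance.stability_result <- function(x, ...) {
  cs <- cs_coefficient(x)
  tidyr::pivot_wider(
    dplyr::select(cs, "index", "cs"),
    names_from = "index", values_from = "cs", names_prefix = "cs_"
  )
}
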