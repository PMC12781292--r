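#' Default ProQOL item-to-subscale map
#'
#' The 30 ProQOL items split into three 10-item subscales: compassion
#' satisfaction (CS), burnout (BO) and secondary traumatic stress (STS). The
#' published item order of the licensed instrument interleaves the subscales,
#' so the map is configurable; the default used here orders the composite as
#' CS items first (nodes CF1-CF10), then BO (CF11-CF20), then STS
#' (CF21-CF30). `cf_node` gives each item's position in the 30-item
#' compassion-fatigue composite, i.e. its network node label `CF<cf_node>`.
#'
#' @param order Character vector of the three subscale codes in composite
#'   order; default `c("CS", "BO", "STS")`.
#' @return A tibble with columns `item` (1-30), `subscale` (CS/BO/STS),
#'   `reverse` (TRUE for CS items, which are reverse-scored into compassion
#'   dissatisfaction) and `cf_node`.
#' @export
proqol_subscale_map <- function(order = c("CS", "BO", "STS")) {
  order <- match.arg(order, c("CS", "BO", "STS"), several.ok = TRUE)
  if (length(order) != 3 || anyDuplicated(order)) {
    abort("order must be a permutation of CS, BO, STS")
  }
  tibble(
    item = 1:30,
    subscale = rep(order, each = 10),
    reverse = rep(order, each = 10) == "CS",
    cf_node = 1:30
  )
}

validate_subscale_map <- function(map) {
  need <- c("item", "subscale", "reverse", "cf_node")
  if (!all(need %in% names(map))) {
    abort(paste0("subscale map needs columns: ", paste(need, collapse = ", ")))
  }
  if (!setequal(map$item, 1:30) || !setequal(map$cf_node, 1:30)) {
    abort("subscale map must cover items 1..30 and cf_node 1..30 exactly once each")
  }
  counts <- table(map$subscale)
  if (!setequal(names(counts), c("BO", "CS", "STS")) || any(counts != 10)) {
    abort("each ProQOL subscale must contain exactly 10 items")
  }
  invisible(map)
}

#' Score the ProQOL into the compassion-fatigue composite
#'
#' Burnout and STS items are summed raw; compassion-satisfaction items are
#' reverse-scored (`6 - response`, turning satisfaction into dissatisfaction)
#' before summing, so that the composite `cf_total = bo_sum + sts_sum +
#' cs_reversed_sum` ranges 30-150 with higher values meaning more severe
#' compassion fatigue.
#'
#' @param responses Integer vector of 30 Likert responses in 1..5, in item
#'   order of `map`.
#' @param map Item-to-subscale map, see [proqol_subscale_map()].
#' @return A one-row tibble with `bo_sum`, `sts_sum`, `cs_reversed_sum`,
#'   `cf_total`.
#' @examples
#' score_proqol_cf(rep(1, 30)) # bo 10, sts 10, reversed cs 50 -> cf 70
#' @export
score_proqol_cf <- function(responses, map = proqol_subscale_map()) {
  validate_subscale_map(map)
  if (length(responses) != 30) {
    abort(sprintf("expected 30 ProQOL responses, got %d", length(responses)))
  }
  assert_int_range(responses, 1L, 5L, "ProQOL response")
  x <- ifelse(map$reverse[order(map$item)][seq_along(responses)],
    6 - responses, responses
  )
  sub <- map$subscale[order(map$item)]
  tibble(
    bo_sum = sum(x[sub == "BO"]),
    sts_sum = sum(x[sub == "STS"]),
    cs_reversed_sum = sum(x[sub == "CS"]),
    cf_total = sum(x)
  )
}

#' Score the MDS-R moral-distress composite
#'
#' Each of the 22 items contributes the product of its frequency (0-4) and
#' intensity (0-4) ratings; the composite is the sum of the 22 products and
#' ranges 0-352.
#'
#' @param freq,intensity Integer vectors of length 22 in 0..4.
#' @return The composite score (single number).
#' @examples
#' score_mdsr(rep(4, 22), rep(4, 22)) # 352
#' @export
score_mdsr <- function(freq, intensity) {
  if (length(freq) != 22 || length(intensity) != 22) {
    abort(sprintf(
      "expected 22 (frequency, intensity) pairs, got %d and %d",
      length(freq), length(intensity)
    ))
  }
  assert_int_range(freq, 0L, 4L, "MDS-R frequency")
  assert_int_range(intensity, 0L, 4L, "MDS-R intensity")
  sum(freq * intensity)
}

#' Dichotomize MDS-R items for the symptom network
#'
#' An item is symptomatic (1) unless its frequency-by-intensity product is
#' zero, i.e. the situation was never encountered or caused no distress.
#'
#' @param freq,intensity Integer vectors in 0..4 (recycled elementwise).
#' @return Integer vector of 0/1.
#' @examples
#' dichotomize_md(c(0, 1, 2), c(3, 0, 3)) # 0 0 1
#' @export
dichotomize_md <- function(freq, intensity) {
  assert_int_range(freq, 0L, 4L, "MDS-R frequency")
  assert_int_range(intensity, 0L, 4L, "MDS-R intensity")
  as.integer(freq * intensity != 0)
}

#' Dichotomize ProQOL items for the symptom network
#'
#' "Never experienced" (raw response 1) codes as 0; any endorsement
#' (responses 2-5) codes as 1. By default the rule is applied to the raw
#' administered response for every item, including the reverse-scored
#' compassion-satisfaction items; set `on_reversed = TRUE` to apply it to the
#' reversed (`6 - x`) value instead, under which a CS response of 5 becomes
#' the non-symptomatic level.
#'
#' @param response Integer vector in 1..5.
#' @param reverse Logical vector (recycled) marking reverse-scored items;
#'   only consulted when `on_reversed = TRUE`.
#' @param on_reversed Apply the cut to the reversed value of reverse-scored
#'   items? Default FALSE.
#' @return Integer vector of 0/1.
#' @examples
#' dichotomize_cf(c(1, 2, 5)) # 0 1 1
#' @export
dichotomize_cf <- function(response, reverse = FALSE, on_reversed = FALSE) {
  assert_int_range(response, 1L, 5L, "ProQOL response")
  x <- if (on_reversed) ifelse(rep_len(reverse, length(response)), 6 - response, response) else response
  as.integer(x != 1)
}

proqol_cols <- function() paste0("proqol_", 1:30)
mdsr_freq_cols <- function() paste0("mdsr_freq_", 1:22)
mdsr_int_cols <- function() paste0("mdsr_intensity_", 1:22)

check_item_table <- function(data) {
  need <- c(proqol_cols(), mdsr_freq_cols(), mdsr_int_cols())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "item table is missing column(s): ",
      paste(head(missing, 6), collapse = ", "),
      if (length(missing) > 6) sprintf(" (and %d more)", length(missing) - 6) else ""
    ))
  }
  if (!all(complete.cases(data[need]))) {
    abort("item table contains missing responses; complete data are required")
  }
  invisible(data)
}

#' Score an item-level response table
#'
#' Takes a respondent-by-item table with columns `proqol_1..proqol_30`,
#' `mdsr_freq_1..mdsr_freq_22` and `mdsr_intensity_1..mdsr_intensity_22`
#' (plus any covariates, which are carried through) and appends the scale
#' scores: `bo_sum`, `sts_sum`, `cs_reversed_sum`, `cf_total`, `md_total`.
#'
#' @param data Item-level data frame.
#' @param map ProQOL subscale map, see [proqol_subscale_map()].
#' @return The input as a tibble with five score columns appended.
#' @export
score_responses <- function(data, map = proqol_subscale_map()) {
  check_item_table(data)
  validate_subscale_map(map)
  pro <- as.matrix(data[proqol_cols()])
  fr <- as.matrix(data[mdsr_freq_cols()])
  it <- as.matrix(data[mdsr_int_cols()])
  assert_int_range(as.vector(pro), 1L, 5L, "ProQOL response")
  assert_int_range(as.vector(fr), 0L, 4L, "MDS-R frequency")
  assert_int_range(as.vector(it), 0L, 4L, "MDS-R intensity")
  ord <- order(map$item)
  rev <- map$reverse[ord]
  sub <- map$subscale[ord]
  adj <- sweep(pro, 2, rev, function(x, r) ifelse(r, 6 - x, x))
  out <- as_tibble(data)
  out$bo_sum <- as.integer(rowSums(adj[, sub == "BO", drop = FALSE]))
  out$sts_sum <- as.integer(rowSums(adj[, sub == "STS", drop = FALSE]))
  out$cs_reversed_sum <- as.integer(rowSums(adj[, sub == "CS", drop = FALSE]))
  out$cf_total <- out$bo_sum + out$sts_sum + out$cs_reversed_sum
  out$md_total <- as.integer(rowSums(fr * it))
  out
}

#' Assemble the binary MD-CF symptom matrix
#'
#' Dichotomizes the 22 MDS-R items (product rule) and the 30 ProQOL items
#' (never vs ever) of a complete item table into the n-by-52 binary matrix
#' used for network estimation. Columns are ordered MD1..MD22 then
#' CF1..CF30, where CF node numbers follow `map$cf_node`.
#'
#' @param data Item-level data frame (see [score_responses()] for the
#'   expected columns).
#' @param map ProQOL subscale map.
#' @param cs_on_reversed Dichotomize compassion-satisfaction items on their
#'   reversed value instead of the raw response? Default FALSE.
#' @return An integer matrix of class `symptom_matrix` with column names
#'   MD1..MD22, CF1..CF30 and a `partition` attribute (named character
#'   vector, "MD"/"CF" per node).
#' @export
assemble_network_matrix <- function(data, map = proqol_subscale_map(),
                                    cs_on_reversed = FALSE) {
  check_item_table(data)
  validate_subscale_map(map)
  fr <- as.matrix(data[mdsr_freq_cols()])
  it <- as.matrix(data[mdsr_int_cols()])
  pro <- as.matrix(data[proqol_cols()])
  md <- matrix(dichotomize_md(as.vector(fr), as.vector(it)), nrow = nrow(data))
  rev_by_item <- map$reverse[order(map$item)]
  cf_raw <- matrix(
    dichotomize_cf(as.vector(pro),
      reverse = rep(rev_by_item, each = nrow(data)),
      on_reversed = cs_on_reversed
    ),
    nrow = nrow(data)
  )
  # reorder item columns into CF-node order
  cf <- cf_raw[, order(map$cf_node[order(map$item)]), drop = FALSE]
  out <- cbind(md, cf)
  colnames(out) <- c(paste0("MD", 1:22), paste0("CF", 1:30))
  partition <- setNames(
    c(rep("MD", 22), rep("CF", 30)),
    colnames(out)
  )
  structure(out, partition = partition, class = c("symptom_matrix", class(out)))
}

#' @export
print.symptom_matrix <- function(x, ...) {
  part <- attr(x, "partition")
  cat(sprintf(
    "<symptom_matrix> %d respondents x %d nodes (%d MD, %d CF)\n",
    nrow(x), ncol(x), sum(part == "MD"), sum(part == "CF")
  ))
  invisible(x)
}

#' @export
as_tibble.symptom_matrix <- function(x, ...) {
  as_tibble(unclass(x), .name_repair = "minimal")
}
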