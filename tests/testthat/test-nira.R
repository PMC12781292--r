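# 6-node toy: 3 MD, 3 CF, one strong positive bridge CF1-MD1
toy_bridge_model <- function(bridge_w = 2, seed = 81) {
  make_ground_truth_ising(
    network_truth_spec(
      n_md = 3, n_cf = 3, intra_density = 0.5,
      intra_weight_range = c(0.4, 0.8),
      threshold_range = c(-2, 0),
      bridge_edges = tibble::tibble(cf = "CF1", md = "MD1", weight = bridge_w)
    ),
    seed = seed
  )
}

test_that("threshold perturbation shifts by k times the threshold SD", {
  m <- ising_model(c(-1, -2, -3), matrix(0, 3, 3))
  expect_equal(sd(m$tau), 1)
  allev <- perturb_threshold(m, 2, "alleviating", k = 2)
  expect_equal(unname(allev$tau), c(-1, -4, -3))
  aggr <- perturb_threshold(m, 2, "aggravating", k = 2)
  expect_equal(unname(aggr$tau), c(-1, 0, -3))
  expect_equal(perturb_threshold(m, 2, "alleviating", k = 0)$tau, m$tau)
  flat <- ising_model(c(-1, -1), matrix(0, 2, 2))
  expect_error(perturb_threshold(flat, 1, "alleviating"), "degenerate")
})

test_that("scenario sets contain one baseline plus one scenario per CF node", {
  m <- toy_bridge_model()
  raw <- run_scenarios(m, n_sim = 200, direction = "both", sweeps = 20, seed = 82)
  counts <- table(raw$scores$direction)
  expect_equal(unname(counts[["alleviating"]]), 4) # 1 baseline + 3 CF nodes
  expect_equal(unname(counts[["aggravating"]]), 4)
  expect_true(all(c("baseline", "CF1", "CF2", "CF3") %in% raw$scores$scenario))
  expect_error(run_scenarios(m, n_sim = 1), "n_sim")
})

test_that("simulated scenario means match exact enumeration", {
  m <- toy_bridge_model()
  md_nodes <- m$labels[m$partition == "MD"]
  raw <- run_scenarios(m, n_sim = 5000, direction = "alleviating", seed = 83)
  exact_base <- expected_sum_score(m, md_nodes)
  got_base <- raw$scores$mean_md[raw$scores$scenario == "baseline"]
  expect_lt(abs(got_base - exact_base), 0.05)
  pert <- perturb_threshold(m, "CF1", "alleviating", k = 2)
  exact_cf1 <- expected_sum_score(pert, md_nodes)
  got_cf1 <- raw$scores$mean_md[raw$scores$scenario == "CF1"]
  expect_lt(abs(got_cf1 - exact_cf1), 0.05)
})

test_that("baseline comparison applies Welch tests with BH correction", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  m <- toy_bridge_model()
  raw <- run_scenarios(m, n_sim = 5000, direction = "alleviating", seed = 84)
  res <- compare_to_baseline(raw)
  base_row <- dplyr::filter(res, scenario == "baseline")
  expect_equal(base_row$delta, 0)
  expect_true(is.na(base_row$p.value))
  scen <- dplyr::filter(res, scenario != "baseline")
  expect_true(all(scen$p.adjusted >= scen$p.value, na.rm = TRUE))
  expect_identical(scen$significant, scen$p.adjusted < 0.05)
  # the strong planted bridge is detected
  expect_true(scen$significant[scen$scenario == "CF1"])
  expect_lt(scen$delta[scen$scenario == "CF1"], 0)
  # null (k = 0) interventions are indistinguishable from baseline
  raw0 <- run_scenarios(m, n_sim = 2000, k = 0, direction = "alleviating", seed = 85)
  res0 <- compare_to_baseline(raw0)
  expect_false(any(dplyr::filter(res0, scenario != "baseline")$significant))
})

test_that("a node with no edges cannot move the MD sum beyond noise", {
  labels <- c(paste0("MD", 1:2), paste0("CF", 1:2))
  omega <- matrix(0, 4, 4, dimnames = list(labels, labels))
  omega["MD1", "MD2"] <- omega["MD2", "MD1"] <- 0.5
  m <- ising_model(c(-1, -0.5, -1.5, -0.2), omega,
    labels = labels,
    partition = setNames(c("MD", "MD", "CF", "CF"), labels)
  )
  raw <- run_scenarios(m, n_sim = 4000, direction = "alleviating", seed = 86)
  res <- compare_to_baseline(raw)
  iso <- dplyr::filter(res, scenario == "CF2") # CF2 is isolated
  se <- sqrt(2 * 0.5 / 4000) * 2 # generous bound on the difference SE
  expect_lt(abs(iso$delta), 3 * max(se, 0.03))
})

test_that("aggravation cannot lower the exact MD sum on nonnegative models", {
  set.seed(87)
  for (rep in 1:4) {
    labels <- c(paste0("MD", 1:3), paste0("CF", 1:3))
    omega <- matrix(0, 6, 6, dimnames = list(labels, labels))
    for (i in 1:5) {
      for (j in (i + 1):6) {
        if (runif(1) < 0.5) omega[i, j] <- omega[j, i] <- runif(1, 0, 1)
      }
    }
    m <- ising_model(rnorm(6, -1, 0.5), omega,
      labels = labels,
      partition = setNames(rep(c("MD", "CF"), each = 3), labels)
    )
    md_nodes <- labels[1:3]
    base <- expected_sum_score(m, md_nodes)
    for (cf in labels[4:6]) {
      up <- expected_sum_score(perturb_threshold(m, cf, "aggravating"), md_nodes)
      dn <- expected_sum_score(perturb_threshold(m, cf, "alleviating"), md_nodes)
      expect_gte(up, base - 1e-12)
      expect_lte(dn, base + 1e-12)
    }
  }
})

test_that("core-target ranking orders significant scenarios by |delta|", {
  m <- toy_bridge_model()
  raw <- run_scenarios(m, n_sim = 5000, direction = "alleviating", seed = 88)
  res <- compare_to_baseline(raw)
  targets <- identify_core_targets(res, "alleviating")
  if (nrow(targets) > 1) {
    expect_true(all(diff(abs(targets$delta)) <= 1e-12))
  }
  expect_identical(targets$scenario[1], "CF1")
  # empty ranking when nothing is significant
  raw0 <- run_scenarios(m, n_sim = 500, k = 0, direction = "aggravating", seed = 89)
  expect_equal(nrow(identify_core_targets(compare_to_baseline(raw0), "aggravating")), 0)
})

test_that("intervention results are reproducible under a fixed seed", {
  m <- toy_bridge_model()
  r1 <- compare_to_baseline(run_scenarios(m, n_sim = 500, sweeps = 30, seed = 90))
  r2 <- compare_to_baseline(run_scenarios(m, n_sim = 500, sweeps = 30, seed = 90))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
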