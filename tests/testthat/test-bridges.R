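two_comm <- function(omega, labels, md) {
  part <- setNames(ifelse(labels %in% md, "MD", "CF"), labels)
  ising_model(rep(0, length(labels)), omega, labels = labels, partition = part)
}

test_that("bridge strength and expected influence are cross-community sums", {
  labels <- c("MD1", "MD2", "CF1")
  omega <- matrix(0, 3, 3, dimnames = list(labels, labels))
  omega["CF1", "MD1"] <- omega["MD1", "CF1"] <- 0.3
  omega["CF1", "MD2"] <- omega["MD2", "CF1"] <- -0.2
  omega["MD1", "MD2"] <- omega["MD2", "MD1"] <- 0.5 # intra edge, excluded
  m <- two_comm(omega, labels, md = c("MD1", "MD2"))
  expect_equal(bridge_strength(m, node = "CF1"), 0.5)
  expect_equal(bridge_expected_influence(m, node = "CF1"), 0.1, tolerance = 1e-12)
  expect_equal(bridge_strength(m, node = "MD2"), 0.2)
  # no cross edges -> zero
  m0 <- two_comm(diag(0, 3), labels, md = c("MD1", "MD2"))
  expect_equal(bridge_strength(m0, node = "CF1"), 0)
  # homogeneity and oddness
  m2 <- two_comm(2 * omega, labels, md = c("MD1", "MD2"))
  expect_equal(bridge_strength(m2, node = "CF1"), 1.0)
  mneg <- two_comm(-omega, labels, md = c("MD1", "MD2"))
  expect_equal(bridge_expected_influence(mneg, node = "CF1"), -0.1, tolerance = 1e-12)
})

test_that("bridge closeness uses inverse-|weight| geodesics", {
  labels <- c("MD1", "CF1")
  omega <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(labels, labels))
  m <- two_comm(omega, labels, md = "MD1")
  expect_equal(bridge_closeness(m, node = "CF1"), 0.5) # distance 2
  # 3-node path MD1 -0.5- X(CF) -0.5- nothing: distance via two hops = 4
  labels3 <- c("MD1", "CF1", "CF2")
  o3 <- matrix(0, 3, 3, dimnames = list(labels3, labels3))
  o3["MD1", "CF1"] <- o3["CF1", "MD1"] <- 0.5
  o3["CF1", "CF2"] <- o3["CF2", "CF1"] <- 0.5
  m3 <- two_comm(o3, labels3, md = "MD1")
  expect_equal(bridge_closeness(m3, node = "CF2"), 0.25)
  # disconnected node scores zero
  o4 <- matrix(0, 3, 3, dimnames = list(labels3, labels3))
  o4["MD1", "CF1"] <- o4["CF1", "MD1"] <- 0.5
  expect_equal(bridge_closeness(two_comm(o4, labels3, md = "MD1"), node = "CF2"), 0)
})

test_that("bridge betweenness counts cross-community geodesic intermediates", {
  labels <- c("CF1", "CF2", "MD1")
  o <- matrix(0, 3, 3, dimnames = list(labels, labels))
  o["CF1", "CF2"] <- o["CF2", "CF1"] <- 1
  o["CF2", "MD1"] <- o["MD1", "CF2"] <- 1
  m <- two_comm(o, labels, md = "MD1")
  bi <- bridge_indices(m)
  expect_equal(bi$bridge_betweenness[bi$node == "CF2"], 1)
  expect_equal(bi$bridge_betweenness[bi$node == "CF1"], 0) # leaf
  # two tied geodesics -> half credit each
  labels4 <- c("CF1", "CF2", "CF3", "MD1")
  o4 <- matrix(0, 4, 4, dimnames = list(labels4, labels4))
  for (via in c("CF2", "CF3")) {
    o4["CF1", via] <- o4[via, "CF1"] <- 1
    o4[via, "MD1"] <- o4["MD1", via] <- 1
  }
  m4 <- two_comm(o4, labels4, md = "MD1")
  bi4 <- bridge_indices(m4)
  expect_equal(bi4$bridge_betweenness[bi4$node == "CF2"], 0.5)
  expect_equal(bi4$bridge_betweenness[bi4$node == "CF3"], 0.5)
})

test_that("closeness and betweenness agree with the brute-force oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    labels <- paste0("N", 1:n)
    part <- setNames(sample(c("MD", "CF"), n, replace = TRUE), labels)
    while (length(unique(part)) < 2) part[] <- sample(c("MD", "CF"), n, replace = TRUE)
    m <- random_ising(n, density = 0.45, wmax = 1, partition = part)
    bi <- bridge_indices(m)
    oracle <- brute_bridge_oracle(m$omega, unname(part[m$labels]))
    expect_equal(bi$bridge_closeness, oracle$closeness, tolerance = 1e-8)
    expect_equal(bi$bridge_betweenness, oracle$betweenness, tolerance = 1e-8)
  }
})

test_that("bridge indices obey their structural invariants", {
  set.seed(63)
  for (rep in 1:5) {
    n <- 7
    labels <- paste0("N", 1:n)
    part <- setNames(c(rep("MD", 3), rep("CF", 4)), labels)
    m <- random_ising(n, density = 0.5, wmax = 1, partition = part)
    bi <- bridge_indices(m)
    expect_true(all(abs(bi$bridge_expected_influence) <= bi$bridge_strength + 1e-12))
    # removing all cross edges zeroes every index
    cut <- m$omega
    cross <- outer(part, part, "!=")
    cut[cross] <- 0
    mcut <- ising_model(m$tau, cut, labels = labels, partition = part)
    bcut <- bridge_indices(mcut)
    expect_true(all(bcut$bridge_strength == 0))
    expect_true(all(bcut$bridge_closeness == 0))
    expect_true(all(bcut$bridge_betweenness == 0))
    # permutation equivariance
    perm <- sample(n)
    mp <- ising_model(m$tau[perm], m$omega[perm, perm],
      labels = labels[perm], partition = part[perm]
    )
    bp <- bridge_indices(mp)
    expect_equal(
      bp[match(bi$node, bp$node), ]$bridge_strength,
      bi$bridge_strength,
      tolerance = 1e-12
    )
    expect_equal(
      bp[match(bi$node, bp$node), ]$bridge_betweenness,
      bi$bridge_betweenness,
      tolerance = 1e-8
    )
  }
})

test_that("node ranking is deterministic with label tie-breaks", {
  bi <- bridge_indices(two_comm(
    matrix(0, 3, 3, dimnames = list(c("MD1", "CF1", "CF2"), c("MD1", "CF1", "CF2"))),
    c("MD1", "CF1", "CF2"),
    md = "MD1"
  ))
  ranked <- rank_bridge_nodes(bi, "bridge_strength")
  expect_identical(ranked$node, c("CF1", "CF2", "MD1")) # all-zero: label order
  expect_error(rank_bridge_nodes(bi, "degree"), "unknown index")
  # a planted dominant bridge ranks first
  truth <- make_ground_truth_ising(
    network_truth_spec(
      n_md = 5, n_cf = 6,
      bridge_edges = tibble::tibble(
        cf = c("CF3", "CF5"), md = c("MD1", "MD2"), weight = c(1.5, 0.4)
      )
    ),
    seed = 65
  )
  top <- rank_bridge_nodes(bridge_indices(truth), "bridge_strength", community = "CF")
  expect_identical(top$node[1], "CF3")
})
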