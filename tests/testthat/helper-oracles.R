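# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Noncentral-F survival function as a Poisson mixture of central F tails.
ncf_surv_oracle <- function(x, df1, df2, lambda) {
  k <- 0:300
  w <- dpois(k, lambda / 2)
  sum(w * pf(x * df1 / (df1 + 2 * k), df1 + 2 * k, df2, lower.tail = FALSE))
}

# Brute-force weighted geodesics by simple-path enumeration (<= 8 nodes).
# Edge length 1/|w|; returns shortest distance and all tied geodesics.
brute_paths <- function(len, i, j, tol = 1e-9) {
  n <- nrow(len)
  best <- Inf
  geod <- list()
  rec <- function(path, d) {
    if (d > best + tol) return()
    cur <- path[length(path)]
    if (cur == j) {
      if (d < best - tol) {
        best <<- d
        geod <<- list(path)
      } else {
        geod[[length(geod) + 1]] <<- path
      }
      return()
    }
    for (k in seq_len(n)) {
      if (!(k %in% path) && is.finite(len[cur, k])) rec(c(path, k), d + len[cur, k])
    }
  }
  rec(i, 0)
  list(dist = best, geodesics = geod)
}

# Oracle bridge closeness and betweenness from brute-force geodesics.
brute_bridge_oracle <- function(omega, partition) {
  n <- nrow(omega)
  len <- ifelse(omega != 0, 1 / abs(omega), Inf)
  diag(len) <- Inf
  other <- outer(partition, partition, "!=")
  closeness <- numeric(n)
  betweenness <- numeric(n)
  dist_cache <- array(NA_real_, c(n, n))
  for (i in seq_len(n)) {
    targets <- which(other[i, ])
    d <- vapply(targets, function(j) brute_paths(len, i, j)$dist, 0.0)
    dist_cache[i, targets] <- d
    d <- d[is.finite(d)]
    closeness[i] <- if (length(d) == 0 || mean(d) == 0) 0 else 1 / mean(d)
  }
  comms <- unique(partition)
  for (i in which(partition == comms[1])) {
    for (j in which(partition == comms[2])) {
      bp <- brute_paths(len, i, j)
      if (!is.finite(bp$dist)) next
      m <- length(bp$geodesics)
      for (p in bp$geodesics) {
        if (length(p) > 2) {
          inner <- p[-c(1, length(p))]
          betweenness[inner] <- betweenness[inner] + 1 / m
        }
      }
    }
  }
  list(closeness = closeness, betweenness = betweenness)
}

# Random small Ising model for property tests.
random_ising <- function(n, density = 0.5, wmax = 1, tmax = 1,
                         partition = NULL, labels = names(partition)) {
  omega <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) {
        omega[i, j] <- omega[j, i] <- runif(1, -wmax, wmax)
      }
    }
  }
  ising_model(runif(n, -tmax, tmax), omega,
    labels = labels, partition = partition
  )
}

# Deterministic item-level table exercising every scoring rule.
toy_item_table <- function(n = 3) {
  set.seed(42)
  b <- matrix(rbinom(n * 52, 1, 0.5), n, 52)
  colnames(b) <- c(paste0("MD", 1:22), paste0("CF", 1:30))
  synthesize_item_responses(
    structure(b,
      partition = setNames(c(rep("MD", 22), rep("CF", 30)), colnames(b)),
      class = c("symptom_matrix", class(b))
    ),
    seed = 43
  )
}
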