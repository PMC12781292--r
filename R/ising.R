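#' Construct a binary (0/1-domain) Ising model
#'
#' The model places probability `P(x) ∝ exp(Σ τ_i x_i + Σ_{i<j} ω_ij x_i x_j)`
#' on binary symptom vectors `x ∈ {0,1}^n`. `tau` are per-node thresholds
#' (the intercepts of the node-conditional logistic regressions) and `omega`
#' the symmetric pairwise couplings with zero diagonal.
#'
#' @param tau Numeric vector of n thresholds.
#' @param omega n-by-n symmetric numeric matrix, zero diagonal.
#' @param labels Node names; defaults to `omega` dimnames or V1..Vn.
#' @param partition Optional named character vector of community labels
#'   (e.g. "MD"/"CF") per node.
#' @return An object of class `ising_model`.
#' @examples
#' m <- ising_model(tau = c(0, 0), omega = matrix(c(0, 1, 1, 0), 2))
#' exact_distribution(m)
#' @export
ising_model <- function(tau, omega, labels = NULL, partition = NULL) {
  omega <- as.matrix(omega)
  n <- length(tau)
  if (!all(dim(omega) == n)) abort("omega must be n x n with n = length(tau)")
  if (!all(is.finite(tau)) || !all(is.finite(omega))) {
    abort("tau and omega must be finite")
  }
  if (max(abs(omega - t(omega))) > 1e-8) abort("omega must be symmetric")
  if (max(abs(diag(omega))) > 1e-12) abort("omega must have zero diagonal")
  omega <- (omega + t(omega)) / 2
  diag(omega) <- 0
  labels <- labels %||% colnames(omega) %||% paste0("V", seq_len(n))
  if (length(labels) != n || anyDuplicated(labels)) {
    abort("labels must be n unique names")
  }
  dimnames(omega) <- list(labels, labels)
  names(tau) <- labels
  if (!is.null(partition)) {
    if (is.null(names(partition))) names(partition) <- labels
    if (!setequal(names(partition), labels)) {
      abort("partition must name every node exactly once")
    }
    partition <- partition[labels]
  }
  structure(
    list(labels = labels, tau = tau, omega = omega, partition = partition),
    class = "ising_model"
  )
}

#' @export
print.ising_model <- function(x, ...) {
  ne <- sum(x$omega[upper.tri(x$omega)] != 0)
  cat(sprintf(
    "<ising_model> %d nodes, %d nonzero couplings%s\n",
    length(x$tau), ne,
    if (is.null(x$partition)) "" else {
      paste0(" (", paste(sprintf(
        "%d %s", as.integer(table(x$partition)), names(table(x$partition))
      ), collapse = ", "), ")")
    }
  ))
  invisible(x)
}

node_index <- function(model, node) {
  if (is.character(node)) {
    i <- match(node, model$labels)
    if (anyNA(i)) abort(paste0("unknown node(s): ", paste(node[is.na(i)], collapse = ", ")))
    i
  } else {
    if (any(node < 1 | node > length(model$labels))) abort("node index out of range")
    as.integer(node)
  }
}

#' Conditional activation probability of one node
#'
#' `P(x_i = 1 | x_{-i}) = logistic(τ_i + Σ_j ω_ij x_j)` — the logistic
#' regression of node i on the remaining nodes that defines the Ising model
#' nodewise.
#'
#' @param model An [ising_model()].
#' @param node Node label or index.
#' @param others 0/1 vector for the other n-1 nodes, in label order with
#'   `node` removed.
#' @return Probability in (0, 1).
#' @export
conditional_probability <- function(model, node, others) {
  i <- node_index(model, node)
  if (length(i) != 1) abort("one node at a time")
  if (length(others) != length(model$tau) - 1) {
    abort("others must have one value per remaining node")
  }
  if (!all(others %in% c(0, 1))) abort("others must be 0/1")
  x <- numeric(length(model$tau))
  x[-i] <- others
  plogis(model$tau[[i]] + sum(model$omega[i, ] * x))
}

enumerate_states <- function(n) {
  if (n > 20) abort("exact enumeration is limited to 20 nodes; use sample_ising()")
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(m) <- NULL
  m
}

#' Exact state distribution of a small Ising model
#'
#' Enumerates all 2^n states (n <= 20) and returns their normalized
#' probabilities; the enumeration oracle behind tests of the sampler and of
#' the intervention simulations.
#'
#' @param model An [ising_model()] with at most 20 nodes.
#' @return A tibble with one 0/1 column per node and a `prob` column summing
#'   to 1.
#' @export
exact_distribution <- function(model) {
  n <- length(model$tau)
  states <- enumerate_states(n)
  loge <- states %*% model$tau + rowSums((states %*% model$omega) * states) / 2
  w <- exp(loge - max(loge))
  out <- as_tibble(as.data.frame(states), .name_repair = "minimal")
  names(out) <- model$labels
  out$prob <- as.vector(w / sum(w))
  out
}

#' Exact expected sum score over a node subset
#'
#' The expectation, under [exact_distribution()], of the number of active
#' nodes in `nodes` — e.g. the expected moral-distress sum score of the MD
#' community.
#'
#' @param model An [ising_model()], n <= 20.
#' @param nodes Character vector of node labels (or indices); may be empty.
#' @return A single number in `[0, length(nodes)]`.
#' @export
expected_sum_score <- function(model, nodes) {
  if (length(nodes) == 0) return(0)
  i <- node_index(model, nodes)
  d <- exact_distribution(model)
  states <- as.matrix(d[model$labels])
  sum(d$prob * rowSums(states[, i, drop = FALSE]))
}

#' Sample observations from an Ising model
#'
#' Single-site Metropolis-within-Gibbs sampling: each observation starts
#' from an independent uniform 0/1 state and receives `sweeps` full
#' sequential passes in which every node is redrawn from its conditional
#' distribution given the rest. Chains are independent across observations,
#' so downstream two-sample t-tests on per-observation scores meet their
#' independence assumption by construction.
#'
#' @param model An [ising_model()].
#' @param n_samples Number of observations (rows).
#' @param sweeps Full update passes per observation; default 100.
#' @param seed Optional integer seed for reproducibility.
#' @return A `symptom_matrix` (n_samples x n nodes) carrying the model's
#'   partition, if any.
#' @export
sample_ising <- function(model, n_samples, sweeps = 100, seed = NULL) {
  if (!inherits(model, "ising_model")) abort("model must be an ising_model")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1) abort("n_samples must be >= 1")
  if (sweeps < 1) abort("sweeps must be >= 1")
  out <- with_seed_if(seed, {
    sample_ising_cpp(model$tau, model$omega, n_samples, as.integer(sweeps))
  })
  colnames(out) <- model$labels
  structure(out,
    partition = model$partition,
    class = c("symptom_matrix", class(out))
  )
}

#' Tidy an Ising model into an edge list
#'
#' @param x An [ising_model()].
#' @param ... Unused.
#' @return A tibble of the nonzero couplings: `from`, `to`, `weight`, and
#'   `bridge` (TRUE when the edge crosses the community partition, when one
#'   is present).
#' @export
tidy.ising_model <- function(x, ...) {
  idx <- which(upper.tri(x$omega) & x$omega != 0, arr.ind = TRUE)
  out <- tibble(
    from = x$labels[idx[, 1]],
    to = x$labels[idx[, 2]],
    weight = x$omega[idx]
  )
  if (!is.null(x$partition)) {
    out$bridge <- x$partition[out$from] != x$partition[out$to]
  }
  out
}

#' @export
glance.ising_model <- function(x, ...) {
  ut <- x$omega[upper.tri(x$omega)]
  tibble(
    n_nodes = length(x$tau),
    n_edges = sum(ut != 0),
    density = mean(ut != 0),
    mean_abs_weight = if (any(ut != 0)) mean(abs(ut[ut != 0])) else 0,
    mean_threshold = mean(x$tau)
  )
}

#' Serialize / deserialize an Ising model as JSON
#'
#' @param model An [ising_model()].
#' @param path File path.
#' @return `read_ising_json` returns an [ising_model()]; `write_ising_json`
#'   returns `path` invisibly.
#' @export
write_ising_json <- function(model, path) {
  obj <- list(
    labels = model$labels, tau = unname(model$tau),
    omega = unname(model$omega),
    partition = if (is.null(model$partition)) NULL else unname(model$partition)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ising_json
#' @export
read_ising_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  part <- if (is.null(obj$partition)) NULL else setNames(obj$partition, obj$labels)
  ising_model(
    tau = obj$tau, omega = obj$omega,
    labels = obj$labels, partition = part
  )
}
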