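# Shared fixture builders and independent naive oracles.

# brute-force permissibility: check the defining implication directly
brute_permissible <- function(h) {
  M <- pattern_matrix(h$K)
  ok <- logical(nrow(M))
  for (i in seq_len(nrow(M))) {
    good <- TRUE
    for (r in seq_len(nrow(h$prerequisites))) {
      a <- h$prerequisites[r, 1L]; b <- h$prerequisites[r, 2L]
      if (M[i, b] == 1L && M[i, a] == 0L) good <- FALSE
    }
    ok[i] <- good
  }
  which(ok)
}

# naive marginal log-likelihood: explicit double loop over classes and items
naive_loglik <- function(X, Q, item_probs, pi) {
  G <- hiercdm:::group_map(as_qmatrix(Q))
  total <- 0
  for (i in seq_len(nrow(X))) {
    mix <- 0
    for (l in seq_along(pi)) {
      p <- 1
      for (j in seq_len(ncol(X))) {
        pj <- unname(min(max(item_probs[[j]][G[j, l]], 1e-10), 1 - 1e-10))
        p <- p * ifelse(X[i, j] == 1, pj, 1 - pj)
      }
      mix <- mix + pi[l] * p
    }
    total <- total + log(mix)
  }
  unname(total)
}

# a random acyclic hierarchy on K attributes (edges respect a random
# topological order, so the result is always a DAG)
random_hierarchy <- function(K, p_edge = 0.4) {
  ord <- sample(K)
  pairs <- list()
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      if (runif(1) < p_edge) pairs <- c(pairs, list(c(ord[i], ord[j])))
    }
  }
  attribute_hierarchy(K, if (length(pairs)) pairs else NULL)
}

# small simulated dataset + saturated fit, for information-matrix tests
small_interior_fit <- function(N = 200, J = 10, K = 2, quality = "moderate",
                               seed = 1, ...) {
  qm <- sim_qmatrix(J, K, seed = seed)
  sim <- sim_cdm_data(N = N, qmatrix = qm, quality = quality,
                      hierarchy = hierarchy_preset("none", K), seed = seed + 1)
  X <- as_response_matrix(sim$responses)
  list(sim = sim, X = X, fit = fit_cdm(X, qm, ...))
}

# evaluate the marginal log-likelihood at a free-parameter vector theta
# laid out as in fit$param_map (reference class absorbs the pi remainder)
loglik_at_theta <- function(fit, X, theta) {
  ip <- fit$item_probs
  pi <- fit$pi
  map <- fit$param_map
  for (r in seq_len(nrow(map))) {
    if (map$type[r] == "item") {
      ip[[map$item[r]]][map$group[r]] <- theta[r]
    } else {
      pi[map$class[r]] <- theta[r]
    }
  }
  L <- length(pi)
  pi[L] <- 1 - sum(pi[-L])
  marginal_loglik(X, fit$qmatrix, ip, pi)
}

theta_of <- function(fit) {
  map <- fit$param_map
  vapply(seq_len(nrow(map)), function(r) {
    if (map$type[r] == "item") fit$item_probs[[map$item[r]]][map$group[r]]
    else fit$pi[map$class[r]]
  }, numeric(1))
}
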