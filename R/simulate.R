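# Data generation for the simulation studies: hierarchy-constrained
# attribute patterns, structured Q-matrices, equal-increment identity-link
# item parameters, and binary responses.

.quality_grid <- list(
  high = c(P0 = 0.1, P1 = 0.9),
  moderate = c(P0 = 0.2, P1 = 0.8),
  low = c(P0 = 0.3, P1 = 0.7)
)

#' Generate a structured Q-matrix
#'
#' The first `2K` items form two `K x K` identity blocks (each attribute
#' measured in isolation twice, which secures identifiability of the
#' saturated model); the remaining rows are drawn uniformly from the
#' nonzero binary vectors and then repaired so that every attribute is
#' measured by at least three items.
#'
#' @param J Number of items (`J >= 2K`).
#' @param K Number of attributes.
#' @param seed Optional RNG seed.
#' @return `J x K` binary integer matrix.
#' @examples
#' sim_qmatrix(30, 3, seed = 1)
#' @export
sim_qmatrix <- function(J, K, seed = NULL) {
  if (J < 2 * K) stop("Need J >= 2K for the two identity blocks.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Q <- matrix(0L, J, K)
  Q[1:K, ] <- diag(K)
  Q[(K + 1):(2 * K), ] <- diag(K)
  for (j in seq_len(J - 2 * K) + 2L * K) {
    repeat {
      row <- stats::rbinom(K, 1L, 0.5)
      if (sum(row) > 0L) break
    }
    Q[j, ] <- row
  }
  # repair: every attribute measured >= 3 times
  repeat {
    deficit <- which(colSums(Q) < 3L)
    if (length(deficit) == 0L) break
    k <- deficit[1L]
    cand <- setdiff(seq_len(J), seq_len(2L * K))
    cand <- cand[Q[cand, k] == 0L]
    if (length(cand) == 0L) {
      warning(sprintf("Cannot measure attribute %d three times with J = %d.",
                      k, J), call. = FALSE)
      break
    }
    Q[cand[sample.int(length(cand), 1L)], k] <- 1L
  }
  as_qmatrix(Q)
}

#' Equal-increment identity-link item parameters
#'
#' Sets, per item, the baseline to `P0` and every main and interaction
#' effect to the common increment `(P1 - P0) / s_j`, where
#' `s_j = 2^{K_j} - 1` is the number of effects of an item measuring
#' `K_j` attributes. A latent group mastering `m` of the required
#' attributes then has success probability
#' `P0 + (P1 - P0) (2^m - 1) / s_j`; in particular `P0` with nothing
#' mastered and `P1` with everything mastered.
#'
#' @param qmatrix `J x K` binary Q-matrix.
#' @param quality `"high"` (`P0 = 0.1, P1 = 0.9`), `"moderate"`
#'   (`0.2, 0.8`) or `"low"` (`0.3, 0.7`).
#' @return List of per-item group success probability vectors (the
#'   canonical item parameter representation, see [marginal_loglik()]),
#'   with attributes `P0`, `P1` and `quality`.
#' @export
sim_item_probs <- function(qmatrix, quality = c("high", "moderate", "low")) {
  quality <- match.arg(quality)
  Q <- as_qmatrix(qmatrix)
  pq <- .quality_grid[[quality]]
  probs <- lapply(seq_len(nrow(Q)), function(j) {
    K_j <- sum(Q[j, ])
    s_j <- 2L^K_j - 1L
    m <- rowSums(group_patterns(K_j))
    unname(pq["P0"] + (pq["P1"] - pq["P0"]) * (2^m - 1) / s_j)
  })
  attr(probs, "P0") <- unname(pq["P0"])
  attr(probs, "P1") <- unname(pq["P1"])
  attr(probs, "quality") <- quality
  probs
}

#' Generate attribute mastery patterns
#'
#' Under the `"uniform"` distribution, patterns are drawn i.i.d. uniformly
#' from the hierarchy's permissible set. Under `"non_uniform"`, a latent
#' multivariate normal vector (mean 0, unit variances, off-diagonal
#' correlations drawn once per call from U(0.5, 0.8) and repaired to the
#' nearest positive-definite correlation matrix if needed) is dichotomised
#' at 0; with an active hierarchy an examinee's vector is redrawn until it
#' is permissible (rejection sampling, which preserves the marginal
#' mechanism restricted to the permissible set).
#'
#' @param N Number of examinees.
#' @param hierarchy An [attribute_hierarchy()]; use the `"none"` preset
#'   for an unconstrained population.
#' @param distribution `"uniform"` or `"non_uniform"`.
#' @param seed Optional RNG seed.
#' @return Integer vector of pattern positions (canonical order); the
#'   pattern matrix rows can be recovered with
#'   `pattern_matrix(K)[positions, ]`.
#' @export
sim_attributes <- function(N, hierarchy,
                           distribution = c("uniform", "non_uniform"),
                           seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  if (!is.null(seed)) set.seed(seed)
  K <- hierarchy$K
  perm <- permissible_patterns(hierarchy)
  if (distribution == "uniform") {
    return(sample(perm, N, replace = TRUE))
  }
  # non-uniform: dichotomised MVN with one correlation draw per call
  R <- diag(K)
  R[upper.tri(R)] <- runif(K * (K - 1) / 2, 0.5, 0.8)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R <- .nearest_pd_corr(R)
  M <- pattern_matrix(K)
  lookup <- integer(2L^K)
  lookup[1L + drop(M %*% 2L^((K - 1):0))] <- seq_len(nrow(M))
  ok_mask <- logical(2L^K)
  ok_mask[perm] <- TRUE
  pos <- integer(N)
  todo <- seq_len(N)
  guard <- 0L
  while (length(todo) > 0L) {
    Z <- MASS::mvrnorm(length(todo), mu = rep(0, K), Sigma = R)
    A <- matrix(as.integer(Z > 0), ncol = K)
    p <- lookup[1L + drop(A %*% 2L^((K - 1):0))]
    good <- ok_mask[p]
    pos[todo[good]] <- p[good]
    todo <- todo[!good]
    guard <- guard + 1L
    if (guard > 10000L) stop("Rejection sampling failed to terminate.",
                             call. = FALSE)
  }
  pos
}

# clip eigenvalues and rescale to a correlation matrix
.nearest_pd_corr <- function(R, eps = 1e-6) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) > eps) return(R)
  V <- ev$vectors %*% diag(pmax(ev$values, eps)) %*% t(ev$vectors)
  D <- 1 / sqrt(diag(V))
  V * tcrossprod(D)
}

#' Generate binary item responses
#'
#' Each response is drawn by the uniform-comparison rule: the model success
#' probability of examinee `i` on item `j` is compared with an independent
#' U(0, 1) draw, and the response is 1 when the probability exceeds it.
#'
#' @param patterns Integer vector of pattern positions, or an `N x K`
#'   pattern matrix.
#' @param qmatrix `J x K` binary Q-matrix.
#' @param item_probs Per-item group success probabilities (e.g. from
#'   [sim_item_probs()]).
#' @param seed Optional RNG seed.
#' @return `N x J` binary response matrix.
#' @export
sim_responses <- function(patterns, qmatrix, item_probs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- as_qmatrix(qmatrix)
  K <- ncol(Q)
  if (is.matrix(patterns)) {
    M <- pattern_matrix(K)
    lookup <- integer(2L^K)
    lookup[1L + drop(M %*% 2L^((K - 1):0))] <- seq_len(nrow(M))
    patterns <- lookup[1L + drop(patterns %*% 2L^((K - 1):0))]
  }
  G <- group_map(Q)
  Pc <- class_prob_matrix(item_probs, G)   # J x L
  P <- t(Pc)[patterns, , drop = FALSE]     # N x J
  X <- matrix(as.integer(P > runif(length(P))), nrow = nrow(P))
  colnames(X) <- rownames(Q)
  X
}

#' Simulate a complete dataset
#'
#' One call bundling the generator chain: Q-matrix (unless supplied),
#' equal-increment item parameters at the chosen quality, attribute
#' patterns under the generating regime, and binary responses. With a
#' hierarchy this is generation from the identity-link HDCM (only
#' permissible patterns occur); with the `"none"` hierarchy it is the
#' unconstrained saturated G-DINA used in the power studies.
#'
#' @param N Number of examinees.
#' @param qmatrix A Q-matrix, or `NULL` to draw one with [sim_qmatrix()].
#' @param J Number of items when `qmatrix` is `NULL`.
#' @param quality Item quality, see [sim_item_probs()].
#' @param hierarchy Generating [attribute_hierarchy()] (use preset
#'   `"none"` for no hierarchy).
#' @param distribution Attribute distribution, see [sim_attributes()].
#' @param seed Optional RNG seed for the whole chain.
#' @return List with `responses` (tibble, items in columns), `qmatrix`,
#'   `item_probs`, `patterns` (true positions) and the design settings.
#' @export
sim_cdm_data <- function(N, qmatrix = NULL, J = 30, quality = "high",
                         hierarchy = hierarchy_preset("none", 3),
                         distribution = "uniform", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(qmatrix)) qmatrix <- sim_qmatrix(J, hierarchy$K)
  qmatrix <- as_qmatrix(qmatrix)
  stopifnot(ncol(qmatrix) == hierarchy$K)
  item_probs <- sim_item_probs(qmatrix, quality)
  patterns <- sim_attributes(N, hierarchy, distribution)
  X <- sim_responses(patterns, qmatrix, item_probs)
  list(
    responses = tibble::as_tibble(as.data.frame(X)),
    qmatrix = qmatrix,
    item_probs = item_probs,
    patterns = patterns,
    quality = attr(item_probs, "quality"),
    hierarchy = hierarchy,
    distribution = distribution
  )
}
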