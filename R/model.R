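#' @importFrom rlang %||%
#' @importFrom stats plogis qlogis pchisq rnorm runif setNames
#' @importFrom utils head
NULL

# ---- Q-matrix and latent group bookkeeping ---------------------------------
#
# The canonical internal representation of the item side of the model is the
# vector of class-conditional success probabilities on *reduced latent
# groups*: for item j measuring K_j attributes there are 2^{K_j} groups, one
# per mastery subset of the required attributes. Both the identity link
# (G-DINA) and the logit link (LCDM) are views onto these probabilities.

#' Validate and coerce a Q-matrix
#'
#' @param qmatrix A `J x K` binary matrix or data frame mapping items to the
#'   attributes they measure; every row must contain at least one 1.
#' @return An integer matrix with item rownames.
#' @export
as_qmatrix <- function(qmatrix) {
  Q <- as.matrix(qmatrix)
  storage.mode(Q) <- "integer"
  if (any(is.na(Q)) || !all(Q %in% c(0L, 1L))) {
    stop("Q-matrix entries must be binary 0/1.", call. = FALSE)
  }
  if (any(rowSums(Q) == 0L)) {
    stop("Every Q-matrix row must measure at least one attribute.", call. = FALSE)
  }
  if (is.null(rownames(Q))) rownames(Q) <- paste0("item", seq_len(nrow(Q)))
  colnames(Q) <- paste0("A", seq_len(ncol(Q)))
  Q
}

# Group index of each latent class for each item: G[j, l] in 1..2^{K_j},
# where bit r-1 of G[j, l] - 1 records mastery of the r-th required
# attribute (in increasing attribute order) of item j.
group_map <- function(Q, patterns = pattern_matrix(ncol(Q))) {
  J <- nrow(Q)
  L <- nrow(patterns)
  G <- matrix(1L, J, L)
  for (j in seq_len(J)) {
    req <- which(Q[j, ] == 1L)
    bits <- patterns[, req, drop = FALSE]
    G[j, ] <- 1L + as.integer(bits %*% 2^(seq_along(req) - 1L))
  }
  G
}

# Mastery-subset indicator matrix for one item: rows = groups 1..2^Kj,
# cols = required attributes in increasing attribute order.
group_patterns <- function(K_j) {
  g <- 0:(2L^K_j - 1L)
  vapply(seq_len(K_j), function(r) as.integer(bitwAnd(g, 2L^(r - 1L)) > 0L),
         integer(2L^K_j))
}

# Subset-inclusion design matrix for one item (intercept + one column per
# nonempty mastery subset, in binary subset order): row g says which effect
# terms are active for latent group g.
effect_design <- function(K_j) {
  n <- 2L^K_j
  D <- matrix(0L, n, n)
  for (g in 0:(n - 1L)) {
    for (e in 0:(n - 1L)) D[g + 1L, e + 1L] <- as.integer(bitwAnd(g, e) == e)
  }
  colnames(D) <- c("(intercept)", effect_labels(K_j))
  D
}

effect_labels <- function(K_j) {
  vapply(1:(2L^K_j - 1L), function(e) {
    paste0("e", paste0(which(as.logical(bitwAnd(e, 2L^(0:(K_j - 1L)))> 0L)),
                       collapse = ""))
  }, character(1L))
}

# ---- Item response functions ------------------------------------------------

# shared: active effect-term sum for a pattern
.effect_sum <- function(coefs, q, alpha) {
  if (length(alpha) != length(q)) {
    stop("`alpha` and `q` must have the same length.", call. = FALSE)
  }
  req <- which(q == 1L)
  K_j <- length(req)
  if (length(coefs) != 2L^K_j) {
    stop(sprintf("Expected %d coefficients (intercept + %d effects).",
                 2L^K_j, 2L^K_j - 1L), call. = FALSE)
  }
  g <- sum(alpha[req] * 2^(seq_along(req) - 1L))
  act <- vapply(1:(2L^K_j - 1L), function(e) bitwAnd(g, e) == e, logical(1L))
  unname(coefs[1L] + sum(coefs[-1L][act]))
}

#' LCDM item response probability (logit link)
#'
#' Probability of a correct response under the log-linear cognitive
#' diagnosis model: the logit of the success probability is the intercept
#' plus all main and interaction effects whose attribute subsets are both
#' required by the item and fully mastered in `alpha`. Effects are ordered
#' by binary subset index over the item's required attributes (main effects
#' of the 1st, 2nd, ... required attribute, then the two-way interactions,
#' etc.; see [effect_design()] column names via `lcdm_effects()`).
#'
#' @param lambda Numeric vector `c(intercept, effects...)` of length
#'   `2^{K_j}` where `K_j` is the number of required attributes.
#' @param q Binary Q-matrix row for the item.
#' @param alpha Binary mastery pattern of length `K`.
#' @return Success probability in (0, 1).
#' @examples
#' # two-attribute item with intercept logit(0.1) and equal effects
#' lam <- c(qlogis(0.1), rep((qlogis(0.9) - qlogis(0.1)) / 3, 3))
#' lcdm_prob(lam, q = c(1, 1), alpha = c(1, 1)) # 0.9
#' @export
lcdm_prob <- function(lambda, q, alpha) {
  plogis(.effect_sum(lambda, q, alpha))
}

#' HDCM item response probability
#'
#' The hierarchical diagnostic classification model removes from the LCDM
#' kernel every effect term whose attribute subset cannot occur as the
#' mastered required-attribute set of a permissible pattern. For an item
#' with `q = (1, 1)` under the hierarchy `1 -> 2` this leaves
#' `lambda_0 + lambda_1 alpha_1 + lambda_12 alpha_1 alpha_2`: the main
#' effect of the nested attribute 2 is removed.
#'
#' @inheritParams lcdm_prob
#' @param hierarchy An [attribute_hierarchy()].
#' @return Success probability in (0, 1).
#' @export
hdcm_prob <- function(lambda, q, alpha, hierarchy) {
  keep <- retained_effects(q, hierarchy)
  lambda[!keep] <- 0
  plogis(.effect_sum(lambda, q, alpha))
}

# Logical mask over c(intercept, effects) marking the terms an HDCM retains:
# a nonempty subset S of the item's required attributes is retained iff S is
# the required-attribute projection of some permissible pattern.
retained_effects <- function(q, hierarchy) {
  req <- which(q == 1L)
  K_j <- length(req)
  M <- pattern_matrix(hierarchy$K)[permissible_mask(hierarchy), , drop = FALSE]
  reach <- unique(1L + as.integer(M[, req, drop = FALSE] %*% 2^(seq_along(req) - 1L)))
  c(TRUE, (1:(2L^K_j - 1L) + 1L) %in% reach)
}

#' G-DINA item response probability (identity link)
#'
#' Success probability as the baseline `delta_0` plus the sum of the
#' probability-scale increments of every effect term whose attribute subset
#' is fully mastered.
#'
#' @param delta Numeric vector `c(baseline, increments...)` of length
#'   `2^{K_j}` on the probability scale.
#' @inheritParams lcdm_prob
#' @return Success probability in `[0, 1]`; out-of-range parameter
#'   combinations are an error.
#' @examples
#' identity_prob(c(0.1, rep(0.8 / 7, 7)), q = c(1, 1, 1), alpha = c(1, 1, 0))
#' @export
identity_prob <- function(delta, q, alpha) {
  p <- .effect_sum(delta, q, alpha)
  if (p < -1e-12 || p > 1 + 1e-12) {
    stop("Identity-link parameters produce a probability outside [0, 1].",
         call. = FALSE)
  }
  min(max(p, 0), 1)
}

# ---- Class-conditional probability table and marginal likelihood ----------

# J x L matrix of class-conditional success probabilities from the per-item
# group probability vectors and the group map.
class_prob_matrix <- function(item_probs, G) {
  J <- nrow(G)
  Pc <- matrix(0, J, ncol(G))
  for (j in seq_len(J)) Pc[j, ] <- item_probs[[j]][G[j, ]]
  Pc
}

# N x L log class-conditional likelihood of each response row, via one BLAS
# product; probabilities clamped away from 0/1 so log() is finite.
log_class_lik <- function(X, Pc) {
  Pc <- pmin(pmax(Pc, 1e-10), 1 - 1e-10)
  X %*% log(Pc) + (1 - X) %*% log1p(-Pc)
}

#' Observed-data marginal log-likelihood
#'
#' The standard latent class marginal likelihood
#' `sum_i log sum_l pi_l prod_j P_{jl}^{x_ij} (1 - P_{jl})^{1 - x_ij}`
#' where `P_{jl}` is the class-conditional success probability of item `j`
#' in latent class `l`.
#'
#' @param data Binary `N x J` response matrix or data frame.
#' @param qmatrix `J x K` binary Q-matrix.
#' @param item_probs List of length `J`; element `j` holds the success
#'   probabilities of item `j` over its `2^{K_j}` reduced latent groups
#'   (binary subset order).
#' @param pi Structural probability vector over the `2^K` patterns in
#'   canonical order (non-negative, summing to 1).
#' @return The log-likelihood (scalar).
#' @export
marginal_loglik <- function(data, qmatrix, item_probs, pi) {
  X <- as_response_matrix(data)
  Q <- as_qmatrix(qmatrix)
  if (ncol(X) != nrow(Q)) stop("Response columns must match Q-matrix rows.",
                               call. = FALSE)
  G <- group_map(Q)
  lp <- log_class_lik(X, class_prob_matrix(item_probs, G))
  sum(.logsumexp_rows(lp, pi))
}

# log sum_l pi_l exp(lp[, l]) per row, guarded for pi_l = 0
.logsumexp_rows <- function(lp, pi) {
  keep <- which(pi > 0)
  lp <- sweep(lp[, keep, drop = FALSE], 2L, log(pi[keep]), "+")
  m <- apply(lp, 1L, max)
  m + log(rowSums(exp(lp - m)))
}

#' @rdname marginal_loglik
#' @param data Binary response data; `as_response_matrix()` coerces a data
#'   frame or matrix (an optional non-numeric examinee identifier column is
#'   dropped) and checks that all entries are 0/1.
#' @export
as_response_matrix <- function(data) {
  if (is.data.frame(data)) {
    keep <- vapply(data, is.numeric, logical(1L))
    data <- as.matrix(data[, keep, drop = FALSE])
  }
  X <- as.matrix(data)
  if (any(is.na(X)) || !all(X %in% c(0, 1))) {
    stop("Responses must be binary 0/1 with no missing values.", call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' Effect-view of fitted item probabilities
#'
#' Re-expresses an item's reduced-group success probabilities as intercept
#' plus main/interaction effects under the identity link (probability-scale
#' increments) or the logit link (LCDM coefficients), by inverting the
#' subset-inclusion design.
#'
#' @param probs Success probabilities over the `2^{K_j}` groups of one item.
#' @param link `"identity"` or `"logit"`.
#' @return Named numeric vector `c("(intercept)", effects...)`.
#' @export
item_effects <- function(probs, link = c("identity", "logit")) {
  link <- match.arg(link)
  K_j <- as.integer(round(log2(length(probs))))
  if (2L^K_j != length(probs)) {
    stop("`probs` must have length 2^{K_j}.", call. = FALSE)
  }
  D <- effect_design(K_j)
  y <- if (link == "identity") probs else qlogis(pmin(pmax(probs, 1e-10), 1 - 1e-10))
  setNames(drop(solve(D, y)), colnames(D))
}
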