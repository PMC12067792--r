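# Marginal maximum likelihood estimation by EM for the saturated
# identity-link G-DINA and the hierarchy-restricted HDCM.

#' Fit a (possibly hierarchy-restricted) cognitive diagnosis model
#'
#' Maximises the observed-data marginal likelihood of an identity-link
#' saturated G-DINA, or of the HDCM obtained by fixing the structural
#' probabilities of impermissible patterns at zero and dropping item
#' effects that the permissible patterns cannot identify, using the EM
#' algorithm with closed-form M-steps.
#'
#' Latent classes are the `2^K` mastery patterns in canonical order (see
#' [attribute_patterns()]). Under a hierarchy restriction only permissible
#' classes carry probability; per item, latent groups that no permissible
#' pattern reaches are frozen at their initial value, carry no posterior
#' mass, and are not counted as free parameters (the probability-scale
#' counterpart of removing nested LCDM effects).
#'
#' @param data Binary `N x J` response matrix or data frame (a non-numeric
#'   identifier column is ignored).
#' @param qmatrix `J x K` binary Q-matrix.
#' @param hierarchy `NULL` for the saturated model, or an
#'   [attribute_hierarchy()] for the restricted HDCM fit.
#' @param weights Optional non-negative case weights (length `N`).
#' @param maxit Maximum EM iterations.
#' @param tol_param Stop when the largest absolute parameter change falls
#'   below this value.
#' @param tol_loglik Stop when the relative log-likelihood change falls
#'   below this value.
#' @param pi_floor Lower bound kept on admitted structural probabilities
#'   during EM (renormalised), so that information matrices evaluated at
#'   the estimate stay finite.
#' @param init Optional list with elements `item_probs` and/or `pi` to
#'   override the deterministic default initialisation (a monotone
#'   0.2--0.8 ramp over each item's groups; uniform `pi` over admitted
#'   classes).
#'
#' @return An object of class `cdm_fit`: a list with `item_probs` (per-item
#'   group success probabilities), `pi` (length `2^K`, zeros at
#'   impermissible positions), `posterior` (`N x 2^K`), `loglik`,
#'   `loglik_trace`, `npar`, `param_map`, `iterations`, `converged`,
#'   `hierarchy`, `qmatrix`, and the group bookkeeping used internally.
#' @examples
#' sim <- sim_cdm_data(N = 150, qmatrix = sim_qmatrix(12, 3, seed = 1),
#'                     quality = "high",
#'                     hierarchy = hierarchy_preset("linear", 3), seed = 1)
#' fit <- fit_cdm(sim$responses, sim$qmatrix)
#' glance(fit)
#' @export
fit_cdm <- function(data, qmatrix, hierarchy = NULL, weights = NULL,
                    maxit = 1000L, tol_param = 1e-5, tol_loglik = 1e-8,
                    pi_floor = 1e-8, init = NULL) {
  X <- as_response_matrix(data)
  Q <- as_qmatrix(qmatrix)
  if (ncol(X) != nrow(Q)) {
    stop("Response columns must match Q-matrix rows.", call. = FALSE)
  }
  J <- nrow(Q); K <- ncol(Q); L <- 2L^K
  N <- nrow(X)
  w <- if (is.null(weights)) rep(1, N) else as.numeric(weights)
  stopifnot(length(w) == N, all(w >= 0))
  patterns <- pattern_matrix(K)
  G <- group_map(Q, patterns)

  if (!is.null(hierarchy)) {
    stopifnot(inherits(hierarchy, "attribute_hierarchy"), hierarchy$K == K)
    admitted <- permissible_patterns(hierarchy)
  } else {
    admitted <- seq_len(L)
  }
  Gadm <- G[, admitted, drop = FALSE]
  # groups estimable from admitted classes, per item
  est_groups <- lapply(seq_len(J), function(j) sort(unique(Gadm[j, ])))

  # deterministic monotone-ramp initialisation
  item_probs <- lapply(seq_len(J), function(j) {
    K_j <- sum(Q[j, ])
    m <- rowSums(group_patterns(K_j))      # mastered count per group
    0.2 + 0.6 * m / K_j
  })
  pi <- numeric(L)
  pi[admitted] <- 1 / length(admitted)
  if (!is.null(init)) {
    if (!is.null(init$item_probs)) item_probs <- init$item_probs
    if (!is.null(init$pi)) {
      pi <- init$pi
      pi[-admitted] <- 0
      pi <- pi / sum(pi)
    }
  }

  sumw <- sum(w)
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step on admitted classes
    Pc <- class_prob_matrix(item_probs, Gadm)
    lp <- log_class_lik(X, Pc)                       # N x |A|
    lp <- sweep(lp, 2L, log(pi[admitted]), "+")
    m <- lp[cbind(seq_len(N), max.col(lp, ties.method = "first"))]
    post <- exp(lp - m)
    rs <- rowSums(post)
    ll <- sum(w * (m + log(rs)))
    post <- post / rs
    loglik_trace <- c(loglik_trace, ll)

    # M-step
    wpost <- w * post
    n_l <- colSums(wpost)                            # expected class sizes
    S <- crossprod(X, wpost)                         # J x |A| expected successes
    old <- c(unlist(item_probs), pi)
    for (j in seq_len(J)) {
      gj <- Gadm[j, ]
      Mg <- rowsum(n_l, gj)                          # expected membership
      Rg <- rowsum(S[j, ], gj)
      upd <- pmin(pmax(Rg / Mg, 1e-4), 1 - 1e-4)
      ids <- as.integer(rownames(Mg))
      ok <- Mg > 1e-9
      item_probs[[j]][ids[ok]] <- upd[ok]
    }
    pin <- pmax(n_l / sumw, pi_floor)
    pi[admitted] <- pin / sum(pin)

    delta <- max(abs(c(unlist(item_probs), pi) - old))
    rel <- abs(ll - prev_ll) / (abs(prev_ll) + 1e-10)
    if (it > 1L && (delta < tol_param || rel < tol_loglik)) {
      converged <- TRUE
      break
    }
    if (it >= maxit) break
    prev_ll <- ll
  }

  # final E-step quantities at the converged parameters
  Pc <- class_prob_matrix(item_probs, Gadm)
  lp <- log_class_lik(X, Pc)
  lp <- sweep(lp, 2L, log(pi[admitted]), "+")
  m <- lp[cbind(seq_len(N), max.col(lp, ties.method = "first"))]
  post <- exp(lp - m)
  rs <- rowSums(post)
  loglik <- sum(w * (m + log(rs)))
  post <- post / rs
  posterior <- matrix(0, N, L)
  posterior[, admitted] <- post
  colnames(posterior) <- apply(patterns, 1L, paste0, collapse = "")

  param_map <- .free_param_map(Q, est_groups, admitted, L)
  fit <- structure(list(
    item_probs = item_probs,
    pi = setNames(pi, colnames(posterior)),
    posterior = posterior,
    loglik = loglik,
    loglik_trace = loglik_trace,
    npar = nrow(param_map),
    param_map = param_map,
    iterations = it,
    converged = converged,
    hierarchy = hierarchy,
    admitted = admitted,
    est_groups = est_groups,
    qmatrix = Q,
    group_map = G,
    patterns = patterns,
    n = N,
    weights = w
  ), class = "cdm_fit")
  fit
}

# index map of the free parameter vector gamma = (item group probs, pi_free):
# the reference class of the sum-to-one constraint is the all-ones pattern
# (position L), permissible under every hierarchy.
.free_param_map <- function(Q, est_groups, admitted, L) {
  items <- dplyr::bind_rows(lapply(seq_len(nrow(Q)), function(j) {
    tibble::tibble(type = "item", item = j, group = est_groups[[j]],
                   class = NA_integer_)
  }))
  pis <- tibble::tibble(type = "pi", item = NA_integer_, group = NA_integer_,
                        class = setdiff(admitted, L))
  out <- dplyr::bind_rows(items, pis)
  out$index <- seq_len(nrow(out))
  out$name <- ifelse(out$type == "item",
                     paste0("P", out$item, ".", out$group),
                     paste0("pi", out$class))
  out
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat(sprintf(
    "<cdm_fit> %s model: N = %d, J = %d, K = %d\n",
    if (is.null(x$hierarchy)) "saturated" else
      sprintf("restricted (%s hierarchy)", x$hierarchy$name),
    x$n, nrow(x$qmatrix), ncol(x$qmatrix)
  ))
  cat(sprintf("  log-likelihood %.3f, %d free parameters, %d EM iteration(s)%s\n",
              x$loglik, x$npar, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' EM posterior (E-step) for a cognitive diagnosis model
#'
#' Posterior class membership probabilities: entry `(i, l)` is proportional
#' to `pi_l` times the class-conditional likelihood of response row `i`;
#' rows sum to one. Classes with `pi_l = 0` get posterior zero.
#'
#' @inheritParams marginal_loglik
#' @return `N x 2^K` posterior matrix.
#' @export
e_step <- function(data, qmatrix, item_probs, pi) {
  X <- as_response_matrix(data)
  Q <- as_qmatrix(qmatrix)
  G <- group_map(Q)
  adm <- which(pi > 0)
  lp <- log_class_lik(X, class_prob_matrix(item_probs, G[, adm, drop = FALSE]))
  lp <- sweep(lp, 2L, log(pi[adm]), "+")
  m <- apply(lp, 1L, max)
  post <- exp(lp - m)
  post <- post / rowSums(post)
  out <- matrix(0, nrow(X), length(pi))
  out[, adm] <- post
  out
}

#' EM update (M-step) for the identity link
#'
#' Closed-form update given a posterior matrix: each reduced-group success
#' probability becomes expected successes over expected membership, and the
#' structural vector becomes the posterior column means, renormalised over
#' the admitted (permissible) classes when a hierarchy restriction is
#' active. Groups with (numerically) no expected membership keep their
#' previous value.
#'
#' @inheritParams marginal_loglik
#' @param posterior `N x 2^K` posterior matrix with rows summing to 1.
#' @param hierarchy Optional [attribute_hierarchy()] restriction.
#' @return List with updated `item_probs` and `pi`.
#' @export
m_step <- function(data, posterior, qmatrix, item_probs,
                   hierarchy = NULL) {
  X <- as_response_matrix(data)
  Q <- as_qmatrix(qmatrix)
  L <- 2L^ncol(Q)
  admitted <- if (is.null(hierarchy)) seq_len(L) else
    permissible_patterns(hierarchy)
  G <- group_map(Q)[, admitted, drop = FALSE]
  post <- posterior[, admitted, drop = FALSE]
  n_l <- colSums(post)
  S <- crossprod(X, post)
  for (j in seq_len(nrow(Q))) {
    Mg <- rowsum(n_l, G[j, ])
    Rg <- rowsum(S[j, ], G[j, ])
    ids <- as.integer(rownames(Mg))
    ok <- Mg > 1e-9
    if (any(!ok)) {
      warning(sprintf("Item %d: group(s) %s have no expected membership; keeping previous value.",
                      j, paste(ids[!ok], collapse = ", ")), call. = FALSE)
    }
    item_probs[[j]][ids[ok]] <- pmin(pmax(Rg[ok] / Mg[ok], 1e-4), 1 - 1e-4)
  }
  pi <- numeric(L)
  pi[admitted] <- n_l / sum(n_l)
  list(item_probs = item_probs, pi = pi)
}

#' Posterior-mode (MAP) attribute classification
#'
#' @param fit A [fit_cdm()] object.
#' @return Integer vector of MAP pattern positions (ties broken toward the
#'   lowest position).
#' @export
map_patterns <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"))
  max.col(fit$posterior, ties.method = "first")
}
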