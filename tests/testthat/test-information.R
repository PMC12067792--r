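test_that("score vectors match finite differences of the log-likelihood", {
  set.seed(101)
  sm <- small_interior_fit(N = 120, J = 8, K = 2, seed = 101)
  f <- sm$fit; X <- sm$X
  S <- score_matrix(f, X)
  th <- theta_of(f)
  eps <- 1e-6
  # perturbing parameters at the simplex floor is not differentiable
  idx <- sort(sample(which(th > 0.01 & th < 0.99), 8))
  for (r in idx) {
    tp <- th; tp[r] <- th[r] + eps; up <- loglik_at_theta(f, X, tp)
    tp[r] <- th[r] - eps; dn <- loglik_at_theta(f, X, tp)
    expect_lt(abs(sum(S[, r]) - (up - dn) / (2 * eps)), 1e-4)
  }
})

test_that("score column sums vanish at an interior maximum", {
  sm <- small_interior_fit(N = 300, J = 8, K = 2, seed = 102,
                           tol_param = 1e-9, tol_loglik = 1e-13, maxit = 5000)
  S <- score_matrix(sm$fit, sm$X)
  expect_lt(max(abs(colSums(S))), 1e-3)
})

test_that("XPD information is a PSD cross-product with closed-form cases", {
  sm <- small_interior_fit(N = 150, J = 8, K = 2, seed = 103)
  f <- sm$fit; X <- sm$X
  S <- score_matrix(f, X)
  I <- information_matrix(f, X, "XPD")
  expect_equal(I, (crossprod(S) + t(crossprod(S))) / 2, ignore_attr = TRUE)
  expect_gte(min(eigen(I, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # a single examinee gives rank <= 1
  f1 <- fit_cdm(X[1, , drop = FALSE], f$qmatrix, maxit = 5)
  I1 <- information_matrix(f1, X[1, , drop = FALSE], "XPD")
  expect_lte(sum(svd(I1)$d > 1e-8 * max(svd(I1)$d)), 1L)
  # permutation of examinee rows leaves XPD unchanged
  f2 <- fit_cdm(X[rev(seq_len(nrow(X))), ], f$qmatrix)
  I2 <- information_matrix(f2, X[rev(seq_len(nrow(X))), ], "XPD")
  expect_equal(I2, I, tolerance = 1e-4)
  # Bernoulli algebra: for scores s_i = (x_i - p)/(p(1-p)) at p = mean(x),
  # sum s_i^2 equals n / (p (1 - p))
  x <- rbinom(40, 1, 0.3); p <- mean(x)
  expect_equal(sum(((x - p) / (p * (1 - p)))^2), length(x) / (p * (1 - p)))
})

test_that("Obs information equals the numerical Hessian", {
  set.seed(104)
  sm <- small_interior_fit(N = 80, J = 6, K = 2, seed = 104)
  f <- sm$fit; X <- sm$X
  Iobs <- information_matrix(f, X, "Obs")
  th <- theta_of(f)
  d <- length(th)
  eps <- 1e-5
  Hn <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in a:d) {
    pp <- th; pp[a] <- pp[a] + eps; pp[b] <- pp[b] + eps; f1 <- loglik_at_theta(f, X, pp)
    pp <- th; pp[a] <- pp[a] + eps; pp[b] <- pp[b] - eps; f2 <- loglik_at_theta(f, X, pp)
    pp <- th; pp[a] <- pp[a] - eps; pp[b] <- pp[b] + eps; f3 <- loglik_at_theta(f, X, pp)
    pp <- th; pp[a] <- pp[a] - eps; pp[b] <- pp[b] - eps; f4 <- loglik_at_theta(f, X, pp)
    Hn[a, b] <- Hn[b, a] <- (f1 - f2 - f3 + f4) / (4 * eps^2)
  }
  expect_lt(max(abs(Iobs - (-Hn))) / max(abs(Iobs)), 1e-3)
  expect_equal(Iobs, t(Iobs))
})

test_that("Obs approaches XPD as N grows under a correct model", {
  qm <- sim_qmatrix(10, 2, seed = 105)
  rel_dist <- vapply(c(1000, 8000), function(N) {
    sim <- sim_cdm_data(N = N, qmatrix = qm, quality = "moderate",
                        hierarchy = hierarchy_preset("none", 2),
                        seed = 105 + N)
    X <- as_response_matrix(sim$responses)
    f <- fit_cdm(X, qm)
    A <- information_matrix(f, X, "XPD")
    B <- information_matrix(f, X, "Obs")
    norm(A - B, "F") / norm(A, "F")
  }, numeric(1))
  expect_lt(rel_dist[2], rel_dist[1])
  expect_lt(rel_dist[2], 0.1)
})

test_that("covariance inverts the information and exposes the pi block", {
  # identity information -> identity covariance
  I <- diag(5)
  colnames(I) <- rownames(I) <- c("P1.1", "P1.2", "pi1", "pi2", "pi3")
  v <- cdm_vcov(I)
  expect_equal(v$vcov, I, ignore_attr = TRUE)
  expect_equal(v$sigma_pp, diag(3), ignore_attr = TRUE)
  expect_equal(v$pi_classes, 1:3)
  expect_equal(v$rank, 5L)
  # round trip against the parameter index map
  sm <- small_interior_fit(N = 400, J = 8, K = 2, seed = 106)
  f <- sm$fit
  vc <- cdm_vcov(f, sm$X, "XPD")
  pi_names <- f$param_map$name[f$param_map$type == "pi"]
  expect_equal(vc$sigma_pp, vc$vcov[pi_names, pi_names])
  # rank deficiency warns
  I2 <- diag(c(1, 1, 0, 1, 1)); dimnames(I2) <- dimnames(I)
  expect_warning(cdm_vcov(I2), "rank deficient")
})

test_that("structural covariance approaches the multinomial limit for
           near-perfect items", {
  qm <- sim_qmatrix(8, 2, seed = 107)
  ip <- lapply(seq_len(nrow(qm)), function(j) {
    K_j <- sum(qm[j, ])
    m <- rowSums(hiercdm:::group_patterns(K_j))
    0.01 + 0.98 * (2^m - 1) / (2^K_j - 1)
  })
  set.seed(108)
  N <- 2000
  pats <- sample(1:4, N, replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15))
  X <- sim_responses(pats, qm, ip)
  f <- fit_cdm(X, qm)
  vc <- suppressWarnings(cdm_vcov(f, X, "XPD"))
  pi_hat <- unname(f$pi[1:4])
  mult <- (diag(pi_hat) - tcrossprod(pi_hat))[1:3, 1:3] / N
  expect_lt(max(abs(vc$sigma_pp - mult)), 0.25 * max(abs(mult)))
})

test_that("structural variances scale as 1/N", {
  qm <- sim_qmatrix(10, 2, seed = 109)
  Ns <- c(500, 1000, 2000, 4000)
  vars <- vapply(Ns, function(N) {
    sim <- sim_cdm_data(N = N, qmatrix = qm, quality = "moderate",
                        hierarchy = hierarchy_preset("none", 2),
                        seed = 110 + N)
    X <- as_response_matrix(sim$responses)
    f <- fit_cdm(X, qm)
    mean(diag(suppressWarnings(cdm_vcov(f, X, "XPD"))$sigma_pp))
  }, numeric(1))
  slope <- coef(lm(log(vars) ~ log(Ns)))[2]
  expect_lt(abs(slope + 1), 0.25)
})
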