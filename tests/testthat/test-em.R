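test_that("E-step is Bayes' rule", {
  qm <- sim_qmatrix(4, 2, seed = 81)
  ip <- sim_item_probs(qm, "moderate")
  X <- sim_responses(sample(1:4, 12, replace = TRUE), qm, ip, seed = 82)
  # degenerate prior: all posterior mass on that class
  post <- e_step(X, qm, ip, c(0, 1, 0, 0))
  expect_equal(post[, 2], rep(1, nrow(X)))
  expect_equal(rowSums(post), rep(1, nrow(X)))
  # identical class-conditional probabilities: posterior equals the prior
  ip_flat <- lapply(ip, function(p) rep(0.6, length(p)))
  pi <- c(0.1, 0.2, 0.3, 0.4)
  post <- e_step(X, qm, ip_flat, pi)
  for (i in seq_len(nrow(X))) expect_equal(post[i, ], pi)
  # naive Bayes loop
  pi <- c(0.4, 0.3, 0.2, 0.1)
  post <- e_step(X, qm, ip, pi)
  G <- hiercdm:::group_map(qm)
  for (i in seq_len(nrow(X))) {
    lik <- vapply(1:4, function(l) {
      prod(vapply(seq_len(nrow(qm)), function(j) {
        pj <- ip[[j]][G[j, l]]
        if (X[i, j] == 1) pj else 1 - pj
      }, numeric(1)))
    }, numeric(1))
    expect_equal(post[i, ], pi * lik / sum(pi * lik), tolerance = 1e-8)
  }
})

test_that("M-step matches closed forms and respects restrictions", {
  qm <- sim_qmatrix(5, 2, seed = 83)
  ip <- sim_item_probs(qm, "moderate")
  X <- sim_responses(sample(1:4, 40, replace = TRUE), qm, ip, seed = 84)
  # posterior concentrated on the all-ones class: its group probabilities
  # become the observed item means
  post <- matrix(0, nrow(X), 4); post[, 4] <- 1
  upd <- m_step(X, post, qm, ip)
  G <- hiercdm:::group_map(qm)
  for (j in seq_len(nrow(qm))) {
    expect_equal(upd$item_probs[[j]][G[j, 4]], mean(X[, j]), tolerance = 1e-9)
  }
  expect_equal(upd$pi, c(0, 0, 0, 1))
  # hierarchy restriction: impermissible entries stay exactly zero
  h <- attribute_hierarchy(2, list(c(1, 2)))
  sim <- sim_cdm_data(N = 60, qmatrix = qm, quality = "moderate",
                      hierarchy = h, seed = 85)
  post <- e_step(sim$responses, qm, ip, c(1, 1, 0, 1) / 3)
  upd <- m_step(sim$responses, post, qm, ip, hierarchy = h)
  expect_identical(upd$pi[3], 0)
  expect_equal(sum(upd$pi), 1)
})

test_that("EM ascends the marginal likelihood", {
  set.seed(86)
  for (rep in 1:8) {
    K <- sample(2:3, 1)
    sim <- sim_cdm_data(N = 80, qmatrix = sim_qmatrix(2 * K + 3, K),
                        quality = sample(c("high", "moderate", "low"), 1),
                        hierarchy = hierarchy_preset("none", K))
    f <- fit_cdm(sim$responses, sim$qmatrix, maxit = 200)
    expect_gte(min(diff(f$loglik_trace)), -1e-8)
  }
})

test_that("fits recover generating parameters on identified groups", {
  qm <- sim_qmatrix(30, 3, seed = 87)
  sim <- sim_cdm_data(N = 2000, qmatrix = qm, quality = "high",
                      hierarchy = hierarchy_preset("none", 3), seed = 88)
  f <- fit_cdm(sim$responses, qm)
  G <- hiercdm:::group_map(qm)
  # baseline (no required attribute) and full-mastery probabilities
  err <- vapply(seq_len(nrow(qm)), function(j) {
    max(abs(f$item_probs[[j]][c(1, G[j, 8])] -
              sim$item_probs[[j]][c(1, G[j, 8])]))
  }, numeric(1))
  expect_lt(max(err), 0.05)
  # structural probabilities near uniform (1/8 each)
  expect_lt(max(abs(f$pi - 1 / 8)), 0.04)
})

test_that("fit is invariant to row order and handles duplicates by weights", {
  qm <- sim_qmatrix(8, 2, seed = 89)
  sim <- sim_cdm_data(N = 120, qmatrix = qm, quality = "moderate",
                      hierarchy = hierarchy_preset("none", 2), seed = 90)
  X <- as_response_matrix(sim$responses)
  f1 <- fit_cdm(X, qm)
  f2 <- fit_cdm(X[rev(seq_len(nrow(X))), ], qm)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$pi, f2$pi, tolerance = 1e-6)
  # duplicated rows = weight-2 fit, exactly
  f3 <- fit_cdm(rbind(X, X), qm)
  f4 <- fit_cdm(X, qm, weights = rep(2, nrow(X)))
  expect_equal(f3$loglik, f4$loglik, tolerance = 1e-9)
  expect_equal(f3$pi, f4$pi, tolerance = 1e-9)
  expect_equal(f3$item_probs, f4$item_probs, tolerance = 1e-9)
})

test_that("restricted fits are nested with the documented parameter counts", {
  h <- hierarchy_preset("linear", 3)
  qm <- sim_qmatrix(15, 3, seed = 91)
  sim <- sim_cdm_data(N = 300, qmatrix = qm, quality = "high",
                      hierarchy = h, seed = 92)
  fs <- fit_cdm(sim$responses, qm)
  fr <- fit_cdm(sim$responses, qm, hierarchy = h)
  expect_gte(fs$loglik, fr$loglik - 1e-6)
  expect_true(all(fr$pi[-permissible_patterns(h)] == 0))
  expect_lt(fr$npar, fs$npar)
  # the ECPE design: saturated vs linear-HDCM differ by 13 free parameters
  qe <- ecpe_qmatrix()
  he <- ecpe_linear_hierarchy()
  sime <- sim_cdm_data(N = 150, qmatrix = qe, quality = "high",
                       hierarchy = he, seed = 93)
  fe_s <- fit_cdm(sime$responses, qe, maxit = 50)
  fe_r <- fit_cdm(sime$responses, qe, hierarchy = he, maxit = 50)
  expect_equal(fe_s$npar - fe_r$npar, 13L)
})

test_that("non-convergence is flagged rather than hidden", {
  sim <- sim_cdm_data(N = 150, qmatrix = sim_qmatrix(10, 2, seed = 94),
                      quality = "low", hierarchy = hierarchy_preset("none", 2),
                      seed = 95)
  f <- fit_cdm(sim$responses, sim$qmatrix, maxit = 2)
  expect_false(f$converged)
  expect_equal(f$iterations, 2L)
})
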