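test_that("chi-square p-values reproduce the reference table", {
  expect_equal(chisq_pvalue(0, 1), 1)
  expect_equal(chisq_pvalue(0, 13), 1)
  expect_equal(round(chisq_pvalue(12.032, 4), 3), 0.017)
  expect_equal(round(chisq_pvalue(25.509, 13), 3), 0.020)
  expect_error(chisq_pvalue(1, 0), "df")
  expect_error(chisq_pvalue(-1, 2), "non-negative")
})

test_that("single-constraint Wald equals the squared z statistic", {
  h <- attribute_hierarchy(2, list(c(1, 2))) # one impermissible pattern: 01
  sim <- sim_cdm_data(N = 400, qmatrix = sim_qmatrix(10, 2, seed = 121),
                      quality = "high", hierarchy = hierarchy_preset("none", 2),
                      seed = 122)
  X <- as_response_matrix(sim$responses)
  f <- fit_cdm(X, qm <- sim$qmatrix)
  vc <- suppressWarnings(cdm_vcov(f, X, "XPD"))
  w <- suppressWarnings(wald_hierarchy_test(f, h, vcov = vc))
  pos <- attr(constraint_matrix(h), "positions")
  z2 <- unname(f$pi[pos]^2 / vc$sigma_pp[match(pos, vc$pi_classes),
                                         match(pos, vc$pi_classes)])
  expect_equal(w$statistic, z2, tolerance = 1e-8)
  expect_equal(w$df, 1L)
})

test_that("Wald statistic is invariant to constraint-row ordering", {
  h <- hierarchy_preset("linear", 3)
  sim <- sim_cdm_data(N = 300, qmatrix = sim_qmatrix(15, 3, seed = 123),
                      quality = "high", hierarchy = h, seed = 124)
  X <- as_response_matrix(sim$responses)
  f <- fit_cdm(X, sim$qmatrix)
  vc <- suppressWarnings(cdm_vcov(f, X, "XPD"))
  w <- suppressWarnings(wald_hierarchy_test(f, h, vcov = vc))
  # recompute the quadratic form with permuted constraint rows
  pos <- attr(constraint_matrix(h), "positions")
  idx <- match(pos, vc$pi_classes)
  for (rep in 1:3) {
    prm <- sample(length(idx))
    q <- unname(f$pi[pos][prm])
    mid <- vc$sigma_pp[idx[prm], idx[prm]]
    W <- drop(t(q) %*% solve(mid) %*% q)
    expect_equal(W, w$statistic, tolerance = 1e-6)
  }
})

test_that("Wald test requires a saturated fit and something to test", {
  h <- hierarchy_preset("linear", 3)
  sim <- sim_cdm_data(N = 150, qmatrix = sim_qmatrix(12, 3, seed = 125),
                      quality = "high", hierarchy = h, seed = 126)
  fr <- fit_cdm(sim$responses, sim$qmatrix, hierarchy = h)
  expect_error(wald_hierarchy_test(fr, h, data = sim$responses), "saturated")
  fs <- fit_cdm(sim$responses, sim$qmatrix)
  expect_error(
    suppressWarnings(wald_hierarchy_test(fs, hierarchy_preset("none", 3),
                                         data = sim$responses)),
    "nothing to test")
})

test_that("LR test behaves like a nested likelihood-ratio statistic", {
  h <- hierarchy_preset("linear", 3)
  sim <- sim_cdm_data(N = 250, qmatrix = sim_qmatrix(15, 3, seed = 127),
                      quality = "moderate", hierarchy = h, seed = 128)
  fs <- fit_cdm(sim$responses, sim$qmatrix)
  fr <- fit_cdm(sim$responses, sim$qmatrix, hierarchy = h)
  lr <- lr_hierarchy_test(fs, fr)
  expect_equal(lr$statistic, max(0, 2 * (fs$loglik - fr$loglik)))
  expect_equal(lr$df, fs$npar - fr$npar)
  expect_gte(lr$statistic, 0)
  # identical log-likelihoods give statistic 0, p-value 1
  fr0 <- fr; fr0$loglik <- fs$loglik
  lr0 <- lr_hierarchy_test(fs, fr0)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p.value, 1)
  expect_error(lr_hierarchy_test(fr, fr), "saturated")
})

test_that("LR statistics are non-negative across random nested fits", {
  set.seed(129)
  bad <- 0
  for (rep in 1:20) {
    K <- sample(2:3, 1)
    h <- random_hierarchy(K, p_edge = 0.6)
    if (length(permissible_patterns(h)) == 2^K) next
    sim <- sim_cdm_data(N = 120, qmatrix = sim_qmatrix(2 * K + 4, K),
                        quality = sample(c("high", "moderate"), 1),
                        hierarchy = h)
    fs <- fit_cdm(sim$responses, sim$qmatrix)
    fr <- fit_cdm(sim$responses, sim$qmatrix, hierarchy = h)
    lr <- lr_hierarchy_test(fs, fr)
    if (lr$statistic < 0) bad <- bad + 1
  }
  expect_equal(bad, 0)
})

test_that("rejection of a false hierarchy strengthens with sample size", {
  h <- hierarchy_preset("linear", 3)
  rates <- vapply(c(200, 1000), function(N) {
    st <- run_condition(N = N, hierarchy = h, quality = "high",
                        regime = "alternative", reps = 8, seed = 130,
                        methods = "wald_xpd")
    st$results$rate
  }, numeric(1))
  expect_gte(rates[2], rates[1])
  expect_equal(rates[2], 1) # power is essentially 1 at N = 1000
})

test_that("hierarchy_test returns one tidy row per method", {
  h <- hierarchy_preset("linear", 3)
  sim <- sim_cdm_data(N = 200, qmatrix = sim_qmatrix(12, 3, seed = 131),
                      quality = "high", hierarchy = h, seed = 132)
  tab <- suppressWarnings(
    hierarchy_test(sim$responses, sim$qmatrix, h))
  expect_equal(sort(tab$method), sort(c("Wald-XPD", "Wald-Obs", "LR")))
  expect_true(all(tab$statistic >= 0))
  expect_true(all(tab$p.value >= 0 & tab$p.value <= 1))
  expect_true(all(tab$df >= 1))
})
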