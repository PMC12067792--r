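# Constraint-matrix Wald test and likelihood-ratio test for a
# prespecified attribute hierarchy.

.new_test_result <- function(method, statistic, df, p.value, alpha,
                             diagnostics = character(0)) {
  structure(list(
    method = method, statistic = statistic, df = df, p.value = p.value,
    alpha = alpha, reject = is.finite(p.value) && p.value < alpha,
    diagnostics = diagnostics
  ), class = "hier_test")
}

#' @export
print.hier_test <- function(x, ...) {
  cat(sprintf("<hier_test> %s: statistic %.3f, df %d, p %.3f (%s H0 at alpha = %g)\n",
              x$method, x$statistic, x$df, x$p.value,
              if (x$reject) "reject" else "fail to reject", x$alpha))
  for (d in x$diagnostics) cat(" note:", d, "\n")
  invisible(x)
}

#' Upper-tail chi-square p-value
#'
#' @param stat Non-negative test statistic.
#' @param df Degrees of freedom (`>= 1`).
#' @return `P(chi^2_df >= stat)`.
#' @examples
#' chisq_pvalue(12.032, 4) # 0.017
#' @export
chisq_pvalue <- function(stat, df) {
  if (any(df < 1) || any(df != round(df))) {
    stop("`df` must be a positive integer.", call. = FALSE)
  }
  if (any(stat < 0)) stop("`stat` must be non-negative.", call. = FALSE)
  pchisq(stat, df, lower.tail = FALSE)
}

#' Wald test of an attribute hierarchy
#'
#' Tests whether the structural probabilities of the patterns a hierarchy
#' forbids are jointly zero in the saturated model:
#' `W = (R pi)' (R Sigma_pp R')^{-1} (R pi)` where `R` is the
#' [constraint_matrix()] selector and `Sigma_pp` the covariance of the free
#' structural probabilities from the XPD or Obs information. `W` is
#' referred to a chi-square distribution with degrees of freedom equal to
#' the rank of `R Sigma_pp R'` (the number of impermissible patterns in the
#' regular case). Rejection is evidence *against* the hierarchy.
#'
#' @param fit A converged saturated [fit_cdm()] object.
#' @param hierarchy The [attribute_hierarchy()] to validate.
#' @param vcov A [cdm_vcov()] for `fit`, or `NULL` to compute one from
#'   `data` with estimator `type`.
#' @param data Response data (needed when `vcov` is `NULL`).
#' @param type `"XPD"` or `"Obs"` covariance estimator.
#' @param alpha Significance level for the reported decision.
#' @return A `hier_test` object (see [tidy.hier_test()]).
#' @export
wald_hierarchy_test <- function(fit, hierarchy, vcov = NULL, data = NULL,
                                type = c("XPD", "Obs"), alpha = 0.05) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "cdm_fit"))
  if (!is.null(fit$hierarchy)) {
    stop("The Wald test needs the *saturated* fit.", call. = FALSE)
  }
  if (is.null(vcov)) {
    if (is.null(data)) stop("Supply `vcov` or `data`.", call. = FALSE)
    vcov <- cdm_vcov(fit, data, type)
  }
  stopifnot(inherits(vcov, "cdm_vcov"))
  R <- constraint_matrix(hierarchy)
  pos <- attr(R, "positions")
  rpi <- unname(fit$pi[pos])
  idx <- match(pos, vcov$pi_classes)
  if (anyNA(idx)) {
    stop("Covariance does not cover the tested structural parameters.",
         call. = FALSE)
  }
  mid <- vcov$sigma_pp[idx, idx, drop = FALSE]
  mid <- (mid + t(mid)) / 2
  diagnostics <- character(0)
  sv <- svd(mid)
  keep <- sv$d > 1e-12 * max(sv$d, 1e-300)
  df <- sum(keep)
  if (df < length(pos)) {
    diagnostics <- c(diagnostics, sprintf(
      "R Sigma R' is singular; df reduced from %d to %d.", length(pos), df))
  }
  if (df == 0L) {
    stop("R Sigma R' has rank zero; Wald statistic undefined.", call. = FALSE)
  }
  minv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  W <- max(0, drop(t(rpi) %*% minv %*% rpi))
  if (vcov$singular) {
    diagnostics <- c(diagnostics, "full information matrix was rank deficient")
  }
  .new_test_result(paste0("Wald-", vcov$estimator), W, df,
                   chisq_pvalue(W, df), alpha, diagnostics)
}

#' Likelihood-ratio test of an attribute hierarchy
#'
#' `LR = 2 (l_s - l_r)`, twice the log-likelihood gap between the saturated
#' model and the hierarchy-restricted HDCM, referred to a chi-square
#' distribution with degrees of freedom equal to the difference in free
#' parameter counts.
#'
#' @param fit_saturated Saturated [fit_cdm()] object.
#' @param fit_restricted Hierarchy-restricted [fit_cdm()] object on the
#'   same data.
#' @param alpha Significance level for the reported decision.
#' @param tol_negative Negative statistics no smaller than `-tol_negative`
#'   are treated as EM stopping-rule noise and clipped to zero (the
#'   restricted maximum cannot truly exceed the saturated one); anything
#'   below that margin is a convergence failure and an error.
#' @return A `hier_test` object.
#' @export
lr_hierarchy_test <- function(fit_saturated, fit_restricted, alpha = 0.05,
                              tol_negative = 0.01) {
  stopifnot(inherits(fit_saturated, "cdm_fit"),
            inherits(fit_restricted, "cdm_fit"))
  if (is.null(fit_restricted$hierarchy) || !is.null(fit_saturated$hierarchy)) {
    stop("Expected a saturated fit and a hierarchy-restricted fit.",
         call. = FALSE)
  }
  if (fit_saturated$n != fit_restricted$n) {
    stop("Both fits must use the same data.", call. = FALSE)
  }
  stat <- 2 * (fit_saturated$loglik - fit_restricted$loglik)
  diagnostics <- character(0)
  if (stat < -tol_negative) {
    stop(sprintf("LR statistic is %.3g < 0: a fit did not converge to its maximum.",
                 stat), call. = FALSE)
  }
  if (stat < 0) {
    diagnostics <- "small negative statistic clipped to 0"
    stat <- 0
  }
  df <- fit_saturated$npar - fit_restricted$npar
  if (df < 1L) stop("Restricted model is not nested with fewer parameters.",
                    call. = FALSE)
  .new_test_result("LR", stat, df, chisq_pvalue(stat, df), alpha, diagnostics)
}

#' Run all hierarchy validation methods on a dataset
#'
#' Convenience wrapper: fits the saturated identity-link model (and, for
#' the LR test, the restricted HDCM), computes the requested test
#' statistics and returns them as one tidy table with a row per method.
#'
#' @inheritParams fit_cdm
#' @param hierarchy The [attribute_hierarchy()] to validate.
#' @param methods Any of `"wald_xpd"`, `"wald_obs"`, `"lr"`.
#' @param alpha Significance level.
#' @param ... Passed on to [fit_cdm()].
#' @return A tibble with columns `method`, `statistic`, `df`, `p.value`,
#'   `reject`.
#' @examples
#' sim <- sim_cdm_data(N = 300, qmatrix = sim_qmatrix(12, 3, seed = 2),
#'                     quality = "high",
#'                     hierarchy = hierarchy_preset("linear", 3), seed = 2)
#' hierarchy_test(sim$responses, sim$qmatrix, hierarchy_preset("linear", 3),
#'                methods = "wald_xpd")
#' @export
hierarchy_test <- function(data, qmatrix, hierarchy,
                           methods = c("wald_xpd", "wald_obs", "lr"),
                           alpha = 0.05, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  fit_s <- fit_cdm(data, qmatrix, hierarchy = NULL, ...)
  out <- list()
  if ("wald_xpd" %in% methods) {
    out$wald_xpd <- wald_hierarchy_test(fit_s, hierarchy, data = data,
                                        type = "XPD", alpha = alpha)
  }
  if ("wald_obs" %in% methods) {
    out$wald_obs <- wald_hierarchy_test(fit_s, hierarchy, data = data,
                                        type = "Obs", alpha = alpha)
  }
  if ("lr" %in% methods) {
    fit_r <- fit_cdm(data, qmatrix, hierarchy = hierarchy, ...)
    out$lr <- lr_hierarchy_test(fit_s, fit_r, alpha = alpha)
  }
  dplyr::bind_rows(lapply(out, tidy.hier_test))
}
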