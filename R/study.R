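# Replication harness: empirical Type I error and power of the hierarchy
# validation methods over the factorial simulation design.

#' Normal-approximation confidence interval for a Monte Carlo rate
#'
#' `p +/- 1.96 sqrt(p (1 - p) / n)`, truncated to `[0, 1]`; the 95%
#' interval for an observed rejection rate over `n` replications. At the
#' nominal level 0.05 with 500 replications the interval is
#' `[0.031, 0.069]`.
#'
#' @param p Observed rate in `[0, 1]`.
#' @param n Number of replications.
#' @param digits Decimal places for the reported endpoints (`NULL` for no
#'   rounding).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' rate_ci(0.05, 500)
#' @export
rate_ci <- function(p, n, digits = 3) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  half <- 1.96 * sqrt(p * (1 - p) / n)
  out <- c(lower = max(0, p - half), upper = min(1, p + half))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Pattern-level classification accuracy
#'
#' Proportion of examinees whose posterior-mode (MAP) mastery pattern under
#' the fitted model equals the data-generating pattern (ties broken toward
#' the lowest pattern position). Only meaningful for simulated data where
#' the truth is known.
#'
#' @param fit A [fit_cdm()] object.
#' @param true_patterns Integer vector of true pattern positions (as
#'   returned by [sim_attributes()]) or an `N x K` pattern matrix.
#' @return Proportion in `[0, 1]`.
#' @export
classification_accuracy <- function(fit, true_patterns) {
  stopifnot(inherits(fit, "cdm_fit"))
  if (is.matrix(true_patterns)) {
    K <- ncol(fit$patterns)
    lookup <- integer(2L^K)
    lookup[1L + drop(fit$patterns %*% 2L^((K - 1):0))] <- seq_len(nrow(fit$patterns))
    true_patterns <- lookup[1L + drop(true_patterns %*% 2L^((K - 1):0))]
  }
  if (length(true_patterns) != fit$n) {
    stop("`true_patterns` must have one entry per examinee.", call. = FALSE)
  }
  mean(map_patterns(fit) == true_patterns)
}

#' Run one cell of the simulation design
#'
#' Repeatedly generates data, fits the saturated identity-link model,
#' computes the Wald statistics with XPD and Obs covariances, fits the
#' restricted HDCM for the LR statistic, and aggregates rejection rates at
#' the chosen significance level. Under `regime = "null"` the generating
#' model is the HDCM with `hierarchy` (rejections are Type I errors);
#' under `regime = "alternative"` data come from the unconstrained
#' saturated model and rejections of the tested hierarchy measure power.
#'
#' One Q-matrix is drawn per condition from the base seed (the study design
#' fixes a single structured test form); per-replication seeds are derived
#' from the base seed so any replication can be rerun in isolation.
#' Replications whose model fit throws an error are excluded from the
#' denominator and counted as failures.
#'
#' @param N Examinees per replication.
#' @param hierarchy Tested [attribute_hierarchy()] (also the generating
#'   hierarchy under the null regime).
#' @param quality Item quality, see [sim_item_probs()].
#' @param distribution Attribute distribution, see [sim_attributes()].
#' @param regime `"null"` (Type I error) or `"alternative"` (power).
#' @param reps Number of replications.
#' @param J Test length.
#' @param seed Base seed for the condition.
#' @param alpha Significance level.
#' @param methods Subset of `"wald_xpd"`, `"wald_obs"`, `"lr"`.
#' @return A `cdm_study` object: list with `results` (per-method tibble:
#'   rejections, completed, failures, `rate`, CI endpoints, mean MAP
#'   accuracy, mean stage runtimes) and `replications` (per-replication
#'   detail tibble), plus the design settings.
#' @examples
#' \donttest{
#' run_condition(N = 200, hierarchy = hierarchy_preset("linear", 3),
#'               quality = "high", reps = 10, seed = 7)
#' }
#' @export
run_condition <- function(N, hierarchy, quality = "high",
                          distribution = "uniform",
                          regime = c("null", "alternative"),
                          reps = 500, J = 30, seed = 1, alpha = 0.05,
                          methods = c("wald_xpd", "wald_obs", "lr")) {
  regime <- match.arg(regime)
  methods <- match.arg(methods, several.ok = TRUE)
  if (reps < 1) stop("`reps` must be at least 1.", call. = FALSE)
  K <- hierarchy$K
  set.seed(seed)
  qmatrix <- sim_qmatrix(J, K)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  gen_hier <- if (regime == "null") hierarchy else hierarchy_preset("none", K)
  item_probs <- sim_item_probs(qmatrix, quality)

  one_rep <- function(r) {
    set.seed(rep_seeds[r])
    patterns <- sim_attributes(N, gen_hier, distribution)
    X <- sim_responses(patterns, qmatrix, item_probs)
    out <- tibble::tibble(rep = r, method = methods, statistic = NA_real_,
                          df = NA_integer_, p.value = NA_real_,
                          reject = NA, error = NA_character_,
                          accuracy = NA_real_, seconds = NA_real_)
    t0 <- proc.time()[3L]
    fit_s <- fit_cdm(X, qmatrix)
    t_em <- proc.time()[3L] - t0
    acc <- classification_accuracy(fit_s, patterns)
    for (m in methods) {
      t0 <- proc.time()[3L]
      res <- tryCatch(suppressWarnings(switch(m,
        wald_xpd = wald_hierarchy_test(fit_s, hierarchy, data = X,
                                       type = "XPD", alpha = alpha),
        wald_obs = wald_hierarchy_test(fit_s, hierarchy, data = X,
                                       type = "Obs", alpha = alpha),
        lr = lr_hierarchy_test(fit_s, fit_cdm(X, qmatrix, hierarchy = hierarchy),
                               alpha = alpha)
      )), error = function(e) e)
      i <- which(out$method == m)
      if (inherits(res, "error")) {
        out$error[i] <- conditionMessage(res)
      } else {
        out$statistic[i] <- res$statistic
        out$df[i] <- res$df
        out$p.value[i] <- res$p.value
        out$reject[i] <- res$reject
        out$accuracy[i] <- acc
        out$seconds[i] <- (proc.time()[3L] - t0) + t_em
      }
    }
    out
  }

  detail <- dplyr::bind_rows(lapply(seq_len(reps), function(r) {
    tryCatch(one_rep(r), error = function(e) {
      tibble::tibble(rep = r, method = methods, statistic = NA_real_,
                     df = NA_integer_, p.value = NA_real_, reject = NA,
                     error = conditionMessage(e), accuracy = NA_real_,
                     seconds = NA_real_)
    })
  }))

  results <- detail |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      completed = sum(!is.na(.data$reject)),
      failures = sum(is.na(.data$reject)),
      rejections = sum(.data$reject, na.rm = TRUE),
      accuracy = mean(.data$accuracy, na.rm = TRUE),
      mean_seconds = mean(.data$seconds, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate = ifelse(.data$completed > 0,
                    .data$rejections / .data$completed, NA_real_),
      ci_lower = purrr::map2_dbl(.data$rate, .data$completed,
                                 ~ if (is.na(.x)) NA_real_ else rate_ci(.x, .y)[1L]),
      ci_upper = purrr::map2_dbl(.data$rate, .data$completed,
                                 ~ if (is.na(.x)) NA_real_ else rate_ci(.x, .y)[2L])
    )
  design <- tibble::tibble(
    N = N, K = K, J = J, quality = quality, hierarchy = hierarchy$name,
    distribution = distribution, regime = regime, reps = reps,
    seed = seed, alpha = alpha
  )
  structure(list(results = dplyr::bind_cols(design[rep(1L, nrow(results)), ],
                                            results),
                 replications = detail, design = design,
                 hierarchy = hierarchy),
            class = "cdm_study")
}

#' @export
print.cdm_study <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "<cdm_study> %s regime: %s hierarchy, K = %d, N = %d, %s quality, %s, %d reps\n",
    d$regime, d$hierarchy, d$K, d$N, d$quality, d$distribution, d$reps))
  print(as.data.frame(x$results[, c("method", "rate", "ci_lower", "ci_upper",
                                    "completed", "failures", "accuracy")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run a factorial study grid
#'
#' Maps [run_condition()] over the rows of a design tibble and binds the
#' per-method summaries into one long table (the machine-readable analogue
#' of the Type I error and power tables).
#'
#' @param design Tibble with columns among `N`, `K`, `quality`,
#'   `hierarchy` (preset name), `distribution`, `regime`, `reps`, `seed`;
#'   missing columns fall back to [run_condition()] defaults.
#' @param ... Passed to every [run_condition()] call.
#' @return Tibble with one row per condition x method.
#' @export
hierarchy_study <- function(design, ...) {
  design <- tibble::as_tibble(design)
  dplyr::bind_rows(lapply(seq_len(nrow(design)), function(i) {
    row <- as.list(design[i, ])
    h <- hierarchy_preset(row$hierarchy, K = row$K %||% 3)
    args <- row[setdiff(names(row), c("hierarchy", "K"))]
    do.call(run_condition, c(list(hierarchy = h), args, list(...)))$results
  }))
}
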