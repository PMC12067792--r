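# broom-style tidiers for fitted models, tests and studies.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted cognitive diagnosis model
#'
#' @param x A [fit_cdm()] object.
#' @param parameters `"items"` for one row per item x latent group
#'   (success probabilities), `"structural"` for one row per mastery
#'   pattern (mixing probabilities).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cdm_fit
#' @export
tidy.cdm_fit <- function(x, parameters = c("items", "structural"), ...) {
  parameters <- match.arg(parameters)
  if (parameters == "structural") {
    return(tibble::tibble(
      position = seq_along(x$pi),
      pattern = names(x$pi),
      permissible = seq_along(x$pi) %in% x$admitted,
      estimate = unname(x$pi)
    ))
  }
  dplyr::bind_rows(lapply(seq_along(x$item_probs), function(j) {
    gp <- group_patterns(sum(x$qmatrix[j, ]))
    tibble::tibble(
      item = rownames(x$qmatrix)[j],
      group = seq_along(x$item_probs[[j]]),
      mastered = apply(gp, 1L, paste0, collapse = ""),
      free = seq_along(x$item_probs[[j]]) %in% x$est_groups[[j]],
      estimate = x$item_probs[[j]]
    )
  }))
}

#' @rdname tidy.cdm_fit
#' @method glance cdm_fit
#' @export
glance.cdm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    npar = x$npar,
    n = x$n,
    AIC = -2 * x$loglik + 2 * x$npar,
    BIC = -2 * x$loglik + log(x$n) * x$npar,
    iterations = x$iterations,
    converged = x$converged,
    restricted = !is.null(x$hierarchy)
  )
}

#' Tidy a hierarchy test result
#'
#' @param x A `hier_test` from [wald_hierarchy_test()] or
#'   [lr_hierarchy_test()].
#' @param ... Unused.
#' @return One-row tibble with `method`, `statistic`, `df`, `p.value`,
#'   `reject`.
#' @method tidy hier_test
#' @export
tidy.hier_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p.value = x$p.value, reject = x$reject)
}

#' Tidy a simulation study
#'
#' @param x A `cdm_study` from [run_condition()].
#' @param ... Unused.
#' @return The per-method results tibble (one row per method, with design
#'   columns).
#' @method tidy cdm_study
#' @export
tidy.cdm_study <- function(x, ...) {
  x$results
}

#' @rdname tidy.cdm_study
#' @method glance cdm_study
#' @export
glance.cdm_study <- function(x, ...) {
  x$design
}
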