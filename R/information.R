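# Observed-data score vectors, XPD and Obs information matrices, and the
# covariance of the free parameters gamma = (item group probabilities,
# pi_1 .. pi_{L-1}) with the all-ones pattern as reference class.

# shared setup for score / information computations
.info_context <- function(fit, data) {
  X <- as_response_matrix(data)
  stopifnot(inherits(fit, "cdm_fit"), nrow(X) == fit$n,
            ncol(X) == nrow(fit$qmatrix))
  A <- fit$admitted
  L <- length(fit$pi)
  ref <- L # all-ones pattern, always admitted
  map <- fit$param_map
  p_beta <- sum(map$type == "item")
  # column of the free vector for each (item, group); NA when frozen
  J <- nrow(fit$qmatrix)
  colof <- matrix(NA_integer_, J, max(vapply(fit$item_probs, length, 1L)))
  bmap <- map[map$type == "item", ]
  colof[cbind(bmap$item, bmap$group)] <- bmap$index
  picol <- setNames(map$index[map$type == "pi"], map$class[map$type == "pi"])
  Pc <- class_prob_matrix(fit$item_probs, fit$group_map[, A, drop = FALSE])
  Pc <- pmin(pmax(Pc, 1e-10), 1 - 1e-10)
  post <- fit$posterior[, A, drop = FALSE]
  # p_il / L_i = post_il / pi_l on admitted classes
  r <- sweep(post, 2L, fit$pi[A], "/")
  list(X = X, A = A, ref = ref, map = map, p_beta = p_beta, colof = colof,
       picol = picol, Pc = Pc, post = post, r = r, J = J,
       d = nrow(map), w = fit$weights)
}

# per-class pointwise derivative d log f_j / d P at the class's active group
.u_class <- function(X, Pc, a) {
  p <- Pc[, a]
  sweep(sweep(X, 2L, p, "-"), 2L, p * (1 - p), "/")
}

#' Per-examinee score vectors
#'
#' Row `i` is the gradient of examinee `i`'s marginal log-likelihood with
#' respect to the free parameter vector `gamma` (item group probabilities,
#' then free structural probabilities with the all-ones pattern as
#' reference class), evaluated at the fitted estimates. At an interior
#' maximum the column sums vanish.
#'
#' @param fit A converged [fit_cdm()] object.
#' @param data The response data the model was fitted to.
#' @return `N x npar` matrix with columns named as in `fit$param_map`.
#' @export
score_matrix <- function(fit, data) {
  cx <- .info_context(fit, data)
  N <- nrow(cx$X)
  S <- matrix(0, N, cx$d)
  for (a in seq_along(cx$A)) {
    l <- cx$A[a]
    U <- .u_class(cx$X, cx$Pc, a)
    cols <- cx$colof[cbind(seq_len(cx$J), fit$group_map[, l])]
    keep <- !is.na(cols)
    S[, cols[keep]] <- S[, cols[keep]] + cx$post[, a] * U[, keep, drop = FALSE]
  }
  aref <- match(cx$ref, cx$A)
  for (l in names(cx$picol)) {
    al <- match(as.integer(l), cx$A)
    S[, cx$picol[[l]]] <- cx$r[, al] - cx$r[, aref]
  }
  colnames(S) <- cx$map$name
  S
}

#' XPD and Obs information matrices
#'
#' `information_matrix()` returns, for the free parameter vector `gamma`,
#' either the empirical cross-product information (XPD), the sum over
#' examinees of outer products of the per-examinee score vectors, or the
#' observed information (Obs), the negative Hessian of the observed-data
#' log-likelihood at the estimates. The Obs matrix is computed in closed
#' form: for Bernoulli items the class-conditional likelihood is linear in
#' each group probability, so its same-parameter second derivatives vanish
#' and the Hessian reduces to score outer products minus posterior-weighted
#' cross-item curvature terms (a Louis-type identity). Both matrices are
#' symmetrised; XPD is positive semi-definite by construction.
#'
#' @inheritParams score_matrix
#' @param type `"XPD"` or `"Obs"`.
#' @return `npar x npar` symmetric matrix with `estimator` attribute.
#' @export
information_matrix <- function(fit, data, type = c("XPD", "Obs")) {
  type <- match.arg(type)
  cx <- .info_context(fit, data)
  S <- score_matrix(fit, data)
  I <- crossprod(sqrt(cx$w) * S)
  if (type == "Obs") {
    M <- matrix(0, cx$d, cx$d)
    aref <- match(cx$ref, cx$A)
    Uref <- .u_class(cx$X, cx$Pc, aref)
    colsref <- cx$colof[cbind(seq_len(cx$J), fit$group_map[, cx$ref])]
    vref <- crossprod(Uref, cx$w * cx$r[, aref])
    for (a in seq_along(cx$A)) {
      l <- cx$A[a]
      U <- .u_class(cx$X, cx$Pc, a)
      cols <- cx$colof[cbind(seq_len(cx$J), fit$group_map[, l])]
      keep <- which(!is.na(cols))
      Tl <- crossprod(U[, keep, drop = FALSE],
                      (cx$w * cx$post[, a]) * U[, keep, drop = FALSE])
      diag(Tl) <- 0 # same-item second derivatives vanish
      idx <- cols[keep]
      M[idx, idx] <- M[idx, idx] + Tl
      pc <- cx$picol[as.character(l)]
      if (!is.na(pc)) {
        v <- crossprod(U, cx$w * cx$r[, a])
        bp <- numeric(cx$d)
        bp[cols[keep]] <- v[keep]
        okr <- which(!is.na(colsref))
        bp[colsref[okr]] <- bp[colsref[okr]] - vref[okr]
        M[, pc] <- M[, pc] + bp
        M[pc, ] <- M[pc, ] + bp
      }
    }
    I <- I - M
  }
  I <- (I + t(I)) / 2
  dimnames(I) <- list(cx$map$name, cx$map$name)
  attr(I, "estimator") <- type
  I
}

#' Covariance of the free parameters
#'
#' Inverts an information matrix (Moore-Penrose pseudo-inverse when rank
#' deficient: singular values below `tol` times the largest are treated as
#' zero) and extracts the structural block, the covariance of the free
#' structural probabilities `pi_1 .. pi_{L-1}`.
#'
#' @param info An information matrix from [information_matrix()], or a
#'   `cdm_fit`; in the latter case `data` and `type` say which information
#'   to compute first.
#' @inheritParams information_matrix
#' @param tol Relative singular value tolerance of the pseudo-inverse.
#' @return An object of class `cdm_vcov`: list with `vcov` (full),
#'   `sigma_pp` (structural block, rows/columns named by pattern
#'   position), `estimator`, `rank`, `rcond` and `singular` flag.
#' @export
cdm_vcov <- function(info, data = NULL, type = c("XPD", "Obs"), tol = 1e-12) {
  type <- match.arg(type)
  if (inherits(info, "cdm_fit")) {
    fit <- info
    info <- information_matrix(fit, data, type)
    map <- fit$param_map
  } else {
    map <- NULL
  }
  est <- attr(info, "estimator") %||% type
  sv <- svd(info)
  dmax <- max(sv$d)
  pos <- sv$d > tol * dmax
  rank <- sum(pos)
  rc <- if (dmax > 0) min(sv$d) / dmax else 0
  singular <- rank < nrow(info)
  if (singular) {
    warning(sprintf("%s information matrix is rank deficient (rank %d of %d); using a pseudo-inverse.",
                    est, rank, nrow(info)), call. = FALSE)
  }
  V <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  dimnames(V) <- dimnames(info)
  pi_cols <- grep("^pi[0-9]+$", colnames(V))
  spp <- V[pi_cols, pi_cols, drop = FALSE]
  structure(list(
    vcov = V, sigma_pp = spp,
    pi_classes = as.integer(sub("^pi", "", colnames(V)[pi_cols])),
    estimator = est, rank = rank, rcond = rc, singular = singular
  ), class = "cdm_vcov")
}

#' @export
print.cdm_vcov <- function(x, ...) {
  cat(sprintf("<cdm_vcov> %s estimator: %d parameters, rank %d, rcond %.2e\n",
              x$estimator, nrow(x$vcov), x$rank, x$rcond))
  invisible(x)
}
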