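#' Define an attribute hierarchy
#'
#' An attribute hierarchy is a set of prerequisite relations among the `K`
#' binary latent attributes of a cognitive diagnosis model: the pair
#' `(a, b)` states that attribute `a` must be mastered before attribute `b`
#' can be mastered. Patterns that master `b` without `a` are *impermissible*
#' and their structural (mixing) probabilities are zero if the hierarchy
#' holds. The relation must be acyclic; an empty relation is a valid
#' "no hierarchy" specification.
#'
#' @param K Number of attributes (integer, `K >= 1`).
#' @param prerequisites Two-column matrix or list of length-2 integer
#'   vectors; each row/element `c(a, b)` declares `a` a prerequisite of `b`.
#'   `NULL` or an empty set means no hierarchy.
#' @param name Optional label for the hierarchy (used in printing).
#'
#' @return An object of class `attribute_hierarchy`: a list with elements
#'   `K`, `prerequisites` (two-column integer matrix, possibly 0 rows) and
#'   `name`.
#'
#' @examples
#' # linear chain 1 -> 2 -> 3
#' attribute_hierarchy(3, list(c(1, 2), c(2, 3)), name = "linear")
#' @export
attribute_hierarchy <- function(K, prerequisites = NULL, name = NULL) {
  if (length(K) != 1L || !is.finite(K) || K < 1 || K != round(K)) {
    stop("`K` must be a single integer >= 1.", call. = FALSE)
  }
  K <- as.integer(K)
  if (is.null(prerequisites) || length(prerequisites) == 0L) {
    prereq <- matrix(integer(0), ncol = 2L)
  } else {
    if (is.list(prerequisites)) {
      prereq <- do.call(rbind, lapply(prerequisites, as.integer))
    } else {
      prereq <- matrix(as.integer(prerequisites), ncol = 2L)
    }
    if (ncol(prereq) != 2L) {
      stop("`prerequisites` must be pairs (a, b).", call. = FALSE)
    }
    if (any(prereq < 1L) || any(prereq > K)) {
      stop("Prerequisite attribute indices must lie in 1..K.", call. = FALSE)
    }
    if (any(prereq[, 1L] == prereq[, 2L])) {
      stop("An attribute cannot be its own prerequisite.", call. = FALSE)
    }
    prereq <- unique(prereq)
  }
  colnames(prereq) <- c("prerequisite", "dependent")
  h <- structure(
    list(K = K, prerequisites = prereq, name = name %||% "custom"),
    class = "attribute_hierarchy"
  )
  if (.has_cycle(h)) {
    stop("The prerequisite relation contains a cycle.", call. = FALSE)
  }
  h
}

# DFS cycle check on the prerequisite digraph
.has_cycle <- function(h) {
  K <- h$K
  adj <- split(h$prerequisites[, 2L], factor(h$prerequisites[, 1L], levels = 1:K))
  state <- integer(K) # 0 unseen, 1 on stack, 2 done
  visit <- function(v) {
    state[v] <<- 1L
    for (w in adj[[v]]) {
      if (state[w] == 1L) return(TRUE)
      if (state[w] == 0L && visit(w)) return(TRUE)
    }
    state[v] <<- 2L
    FALSE
  }
  for (v in 1:K) if (state[v] == 0L && visit(v)) return(TRUE)
  FALSE
}

#' @export
print.attribute_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<attribute_hierarchy> %s: K = %d, %d prerequisite pair(s)\n",
    x$name, x$K, nrow(x$prerequisites)
  ))
  if (nrow(x$prerequisites) > 0L) {
    cat(paste(
      sprintf("  %d -> %d", x$prerequisites[, 1L], x$prerequisites[, 2L]),
      collapse = "\n"
    ), "\n")
  }
  invisible(x)
}

#' Built-in hierarchy presets
#'
#' Named prerequisite structures used throughout the simulation studies.
#' `"linear"` is the chain `1 -> 2 -> ... -> K` for any `K`. The shaped
#' presets place attribute 1 at the apex: for `K = 3`, `"pyramid"` is
#' `1 -> 2, 1 -> 3` and `"inverted_pyramid"` is the convergent mirror
#' `1 -> 3, 2 -> 3`; for `K = 5`, `"pyramid"` is the two-level branching
#' tree `1 -> {2, 3}`, `2 -> 4`, `3 -> 5`, `"inverted_pyramid"` its mirror
#' (`4 -> 2`, `5 -> 3`, `{2, 3} -> 1`) and `"diamond"` is
#' `1 -> {2, 3, 4}`, `{2, 3, 4} -> 5`. `"none"` is the empty relation.
#' These realise the standard external shapes of the attribute-hierarchy
#' literature; the linear chains coincide with the worked examples used
#' for the constraint-matrix construction.
#'
#' @param name One of `"linear"`, `"pyramid"`, `"inverted_pyramid"`,
#'   `"diamond"` (K = 5 only), `"none"`.
#' @param K Number of attributes (3 or 5 for the shaped presets; any K for
#'   `"linear"` and `"none"`).
#' @return An [attribute_hierarchy()] object.
#' @examples
#' hierarchy_preset("pyramid", K = 3)
#' @export
hierarchy_preset <- function(name = c("linear", "pyramid", "inverted_pyramid",
                                      "diamond", "none"),
                             K = 3) {
  name <- match.arg(name)
  K <- as.integer(K)
  pairs <- switch(name,
    none = NULL,
    linear = if (K >= 2) lapply(seq_len(K - 1L), function(k) c(k, k + 1L)),
    pyramid = switch(as.character(K),
      "3" = list(c(1, 2), c(1, 3)),
      "5" = list(c(1, 2), c(1, 3), c(2, 4), c(3, 5)),
      stop("`pyramid` preset is defined for K = 3 or K = 5.", call. = FALSE)
    ),
    inverted_pyramid = switch(as.character(K),
      "3" = list(c(1, 3), c(2, 3)),
      "5" = list(c(4, 2), c(5, 3), c(2, 1), c(3, 1)),
      stop("`inverted_pyramid` preset is defined for K = 3 or K = 5.", call. = FALSE)
    ),
    diamond = switch(as.character(K),
      "5" = list(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(3, 5), c(4, 5)),
      stop("`diamond` preset is defined for K = 5.", call. = FALSE)
    )
  )
  attribute_hierarchy(K, pairs, name = name)
}

#' Read a hierarchy from a config file
#'
#' Reads a YAML (or JSON) file with fields `K`, `prerequisites` (a list of
#' `[a, b]` pairs) and optionally `name` or `preset`. With `preset`, the
#' named [hierarchy_preset()] is returned and `prerequisites` is ignored.
#'
#' @param path Path to the config file.
#' @return An [attribute_hierarchy()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("K: 3", "prerequisites: [[1, 2], [2, 3]]"), cfg)
#' read_hierarchy(cfg)
#' @export
read_hierarchy <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    return(hierarchy_preset(cfg$preset, K = cfg$K %||% 3))
  }
  if (is.null(cfg$K)) stop("Config must give `K`.", call. = FALSE)
  attribute_hierarchy(cfg$K, cfg$prerequisites, name = cfg$name)
}

#' Enumerate all attribute mastery patterns
#'
#' Lists the `L = 2^K` binary mastery patterns in the canonical order used
#' for the structural parameter vector: ascending number of mastered
#' attributes, and within a mastery count, descending value of the pattern
#' read as a binary number with attribute 1 as the most significant bit.
#' For `K = 3` this is `000, 100, 010, 001, 110, 101, 011, 111`, so e.g.
#' position 3 is `010` and position 6 is `101`. Position 1 is always the
#' all-zeros pattern and position `2^K` the all-ones pattern.
#'
#' @param K Number of attributes (`K >= 1`).
#' @return A tibble with one row per pattern: `position`, `label` (the
#'   pattern as a 0/1 string), `n_mastered`, and attribute columns
#'   `A1 ... AK`.
#' @examples
#' attribute_patterns(3)
#' @export
attribute_patterns <- function(K) {
  M <- pattern_matrix(K)
  out <- tibble::as_tibble(M, .name_repair = "minimal")
  names(out) <- paste0("A", seq_len(ncol(M)))
  dplyr::bind_cols(
    tibble::tibble(
      position = seq_len(nrow(M)),
      label = apply(M, 1L, paste0, collapse = ""),
      n_mastered = rowSums(M)
    ),
    out
  )
}

#' Pattern matrix in canonical order
#'
#' Matrix backend of [attribute_patterns()]: the `2^K x K` 0/1 matrix whose
#' rows are the mastery patterns in canonical order.
#'
#' @inheritParams attribute_patterns
#' @return Integer matrix of dimension `2^K x K`.
#' @export
pattern_matrix <- function(K) {
  if (length(K) != 1L || !is.finite(K) || K < 1 || K != round(K)) {
    stop("`K` must be a single integer >= 1.", call. = FALSE)
  }
  K <- as.integer(K)
  M <- as.matrix(expand.grid(rep(list(0:1), K)))[, K:1, drop = FALSE]
  # binary value with attribute 1 as the most significant bit
  val <- drop(M %*% 2^((K - 1):0))
  ord <- order(rowSums(M), -val)
  M <- M[ord, , drop = FALSE]
  dimnames(M) <- list(NULL, paste0("A", 1:K))
  storage.mode(M) <- "integer"
  M
}

#' Permissible mastery patterns under a hierarchy
#'
#' A pattern is permissible when, for every prerequisite pair `(a, b)`,
#' mastery of `b` implies mastery of `a`. The all-zeros and all-ones
#' patterns are permissible under every (acyclic) hierarchy.
#'
#' @param hierarchy An [attribute_hierarchy()].
#' @return Integer vector of permissible pattern positions (canonical
#'   order, see [attribute_patterns()]).
#' @examples
#' permissible_patterns(hierarchy_preset("linear", 3))
#' @export
permissible_patterns <- function(hierarchy) {
  which(permissible_mask(hierarchy))
}

#' @rdname permissible_patterns
#' @return `permissible_mask()` returns the same information as a logical
#'   vector of length `2^K`.
#' @export
permissible_mask <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  M <- pattern_matrix(hierarchy$K)
  ok <- rep(TRUE, nrow(M))
  pr <- hierarchy$prerequisites
  for (r in seq_len(nrow(pr))) {
    ok <- ok & !(M[, pr[r, 2L]] == 1L & M[, pr[r, 1L]] == 0L)
  }
  ok
}

#' Wald constraint matrix for a hierarchy
#'
#' Builds the binary selector matrix `R` whose rows pick the structural
#' parameters of the impermissible patterns out of the free structural
#' vector `(pi_1, ..., pi_{L-1})`. The all-ones pattern (position `2^K`)
#' is the reference class of the sum-to-one constraint; it is permissible
#' under every hierarchy, so every tested parameter is a free parameter.
#' `R %*% pi_free` returns the impermissible-pattern probabilities in
#' ascending position order, and `R %*% t(R)` is the identity.
#'
#' @param hierarchy An [attribute_hierarchy()] with at least one
#'   impermissible pattern.
#' @return A 0/1 matrix with one row per impermissible pattern and
#'   `2^K - 1` columns; attribute `positions` holds the selected pattern
#'   positions.
#' @examples
#' constraint_matrix(hierarchy_preset("linear", 3)) # selects 3, 4, 6, 7
#' @export
constraint_matrix <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  L <- 2L^hierarchy$K
  imp <- setdiff(seq_len(L), permissible_patterns(hierarchy))
  if (length(imp) == 0L) {
    stop("Hierarchy admits all patterns: nothing to test.", call. = FALSE)
  }
  imp <- sort(imp)
  R <- matrix(0L, nrow = length(imp), ncol = L - 1L)
  R[cbind(seq_along(imp), imp)] <- 1L
  rownames(R) <- paste0("pi", imp)
  attr(R, "positions") <- imp
  R
}
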