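# The ECPE grammar section: the standard real-data illustration for
# attribute hierarchy validation.

#' Q-matrix of the ECPE grammar section
#'
#' The published 28-item, 3-attribute Q-matrix of the Examination for the
#' Certificate of Proficiency in English grammar section. Attributes:
#' A1 morphosyntactic rules, A2 cohesive rules, A3 lexical rules. The
#' response data (2,922 examinees) are distributed in the CRAN packages
#' `CDM` and `GDINA` and are not bundled here; [ecpe_linear_hierarchy()]
#' returns the linear hierarchy `A3 -> A2 -> A1` (lexical before cohesive
#' before morphosyntactic) whose validation is the standard analysis of
#' this dataset. Under the canonical pattern order its impermissible
#' patterns are `100, 010, 110, 101` (positions 2, 3, 5, 6).
#'
#' @return `ecpe_qmatrix()`: a 28 x 3 binary matrix.
#' @examples
#' colSums(ecpe_qmatrix())
#' attr(constraint_matrix(ecpe_linear_hierarchy()), "positions") # 2 3 5 6
#' @export
ecpe_qmatrix <- function() {
  q <- matrix(c(
    1, 1, 0,
    0, 1, 0,
    1, 0, 1,
    0, 0, 1,
    0, 0, 1,
    0, 0, 1,
    1, 0, 1,
    0, 1, 0,
    0, 0, 1,
    1, 0, 0,
    1, 0, 1,
    1, 0, 1,
    1, 0, 0,
    1, 0, 0,
    0, 0, 1,
    1, 0, 1,
    0, 1, 1,
    0, 0, 1,
    0, 0, 1,
    1, 0, 1,
    1, 0, 1,
    0, 0, 1,
    0, 1, 0,
    0, 1, 0,
    1, 0, 0,
    0, 0, 1,
    1, 0, 0,
    0, 0, 1
  ), ncol = 3, byrow = TRUE)
  rownames(q) <- paste0("E", seq_len(nrow(q)))
  as_qmatrix(q)
}

#' @rdname ecpe_qmatrix
#' @return `ecpe_linear_hierarchy()`: the [attribute_hierarchy()]
#'   `3 -> 2 -> 1`.
#' @export
ecpe_linear_hierarchy <- function() {
  attribute_hierarchy(3, list(c(3, 2), c(2, 1)), name = "linear (3->2->1)")
}
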