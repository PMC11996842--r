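#' Numerical tolerances used across the package
#'
#' Two tolerance scales are used throughout: a *structural* tolerance for
#' algebraic identities on states and operators (Hermiticity, idempotence,
#' normalization, trace preservation) and a looser *probabilistic* tolerance
#' for quantities accumulated over sums or quadrature. Every `is_*` predicate
#' takes an explicit `tol` argument defaulting to one of these.
#'
#' @format A named list with elements `structural` (1e-10) and
#'   `probabilistic` (1e-8).
#' @export
#' @examples
#' qcog_tol$structural
qcog_tol <- list(structural = 1e-10, probabilistic = 1e-8)

# internal: abort with a classed condition so callers/tests can match on class
qcog_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "qcogsim_error"))
}
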