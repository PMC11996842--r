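#' Kraus instrument
#'
#' A quantum instrument as a list of Kraus operators `{K_i}` with outcome
#' labels: the operator-sum machinery behind both measurement-and-update and
#' CPTP context channels. Completeness `sum K_i^dag K_i = I` is checked to
#' within `tol` (probabilistic default 1e-8) unless `subnormalized = TRUE`,
#' which permits instruments covering only a sub-event (e.g. the collapse
#' propagator pieces of [collapse_instrument()]).
#'
#' @param operators List of `qop`s on a shared basis.
#' @param outcome_labels Character vector naming each operator's outcome.
#' @param subnormalized Allow `sum K^dag K <= I` instead of equality.
#' @param tol Completeness tolerance.
#' @return Object of class `kraus_instrument`.
#' @export
kraus_instrument <- function(operators, outcome_labels = NULL,
                             subnormalized = FALSE,
                             tol = qcog_tol$probabilistic) {
  stopifnot(is.list(operators), length(operators) >= 1L,
            all(vapply(operators, inherits, TRUE, "qop")))
  labels <- operators[[1]]$labels
  for (op in operators) check_same_basis(labels, op$labels, "Kraus operators")
  if (is.null(outcome_labels)) outcome_labels <- paste0("k", seq_along(operators))
  stopifnot(length(outcome_labels) == length(operators))
  comp <- Reduce(`+`, lapply(operators, function(k) Conj(t(k$matrix)) %*% k$matrix))
  dev <- max(Mod(comp - diag(length(labels))))
  if (!subnormalized && dev > tol) {
    qcog_abort(sprintf("instrument not complete: max |sum K'K - I| = %.3g", dev),
               "qcog_contract_error")
  }
  if (subnormalized) {
    ev <- eigen((comp + Conj(t(comp))) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (max(Re(ev)) > 1 + tol) {
      qcog_abort("subnormalized instrument must satisfy sum K'K <= I", "qcog_contract_error")
    }
  }
  structure(list(operators = operators, outcome_labels = outcome_labels,
                 labels = labels, subnormalized = subnormalized),
            class = "kraus_instrument")
}

#' Context map (CPTP channel)
#'
#' A context is modeled as a completely positive trace-preserving map acting
#' on the agent's density operator before any outcome probability is
#' assigned: `rho -> sum_k K_k rho K_k^dag`. Trace preservation is the
#' instrument completeness condition, checked at construction.
#'
#' @param kraus A complete [kraus_instrument()] used as one CPTP channel.
#' @param description Free-text name of the context.
#' @return Object of class `context_map`.
#' @export
#' @examples
#' identity_context(c("B", "F"))
context_map <- function(kraus, description = "") {
  stopifnot(inherits(kraus, "kraus_instrument"))
  if (kraus$subnormalized) {
    qcog_abort("context channel must be trace preserving (complete instrument)",
               "qcog_contract_error")
  }
  structure(list(kraus = kraus, description = description), class = "context_map")
}

#' @rdname context_map
#' @param labels Basis names for the identity context.
#' @export
identity_context <- function(labels) {
  context_map(kraus_instrument(list(qop_identity(labels))), "identity")
}

#' Apply a context channel to a density operator
#'
#' Returns `sum_k K_k rho K_k^dag`, a valid density operator for any valid
#' input. The identity context returns `rho` unchanged (context reduction).
#'
#' @param rho A `qdensity`.
#' @param ctx A [context_map()].
#' @return A `qdensity`.
#' @export
apply_context <- function(rho, ctx) {
  stopifnot(inherits(rho, "qdensity"), inherits(ctx, "context_map"))
  check_same_basis(rho$labels, ctx$kraus$labels, "state and context")
  out <- Reduce(`+`, lapply(ctx$kraus$operators, function(k) {
    k$matrix %*% rho$matrix %*% Conj(t(k$matrix))
  }))
  qdensity(out, rho$labels, tol = qcog_tol$probabilistic)
}

#' Contextual Born probabilities
#'
#' The contextual rule: first transform the state by the context channel,
#' then apply the Born rule, `P(a_i | context) = Tr(E(rho) Pi_i)`. The
#' projector set must be orthogonal and complete (`sum Pi_i = I`), so the
#' probabilities sum to 1. With the identity context this reduces exactly —
#' bit for bit — to the standard Born rule.
#'
#' @param rho A `qdensity`.
#' @param projectors List of orthogonal, complete projector `qop`s.
#' @param ctx A [context_map()]; defaults to the identity context.
#' @return Numeric vector of probabilities, one per projector.
#' @export
contextual_probability <- function(rho, projectors, ctx = NULL) {
  stopifnot(inherits(rho, "qdensity"), is.list(projectors))
  labels <- rho$labels
  if (is.null(ctx)) ctx <- identity_context(labels)
  for (p in projectors) {
    check_same_basis(labels, p$labels, "state and projectors")
    if (!is_projector(p)) qcog_abort("non-projector in outcome set", "qcog_contract_error")
  }
  tot <- Reduce(`+`, lapply(projectors, function(p) p$matrix))
  if (max(Mod(tot - diag(length(labels)))) > qcog_tol$probabilistic) {
    qcog_abort("projector set is not complete (sum != I)", "qcog_normalization_error")
  }
  rho2 <- apply_context(rho, ctx)
  vapply(projectors, function(p) born_trace(rho2$matrix, p$matrix), numeric(1))
}

#' Measurement-operator (instrument) update
#'
#' The Bayesian-update reading of collapse: outcome probability
#' `P = Tr(rho M^dag M)` and posterior state
#' `rho' = M rho M^dag / Tr(rho M^dag M)`. For a projective `M` on a pure
#' state this is textbook collapse. A zero-probability outcome raises an
#' explicit zero-support error rather than producing NaNs.
#'
#' @param rho A `qdensity`.
#' @param M A `qop` measurement operator.
#' @return List with elements `state` (`qdensity`) and `probability`.
#' @export
instrument_update <- function(rho, M) {
  stopifnot(inherits(rho, "qdensity"), inherits(M, "qop"))
  check_same_basis(rho$labels, M$labels, "state and measurement operator")
  mm <- Conj(t(M$matrix)) %*% M$matrix
  p <- born_trace(rho$matrix, mm)
  if (p <= qcog_tol$structural) {
    qcog_abort("outcome has zero support on the state", "qcog_zero_support_error")
  }
  post <- M$matrix %*% rho$matrix %*% Conj(t(M$matrix)) / p
  list(state = qdensity(post, rho$labels, tol = qcog_tol$probabilistic),
       probability = p)
}

#' Context-dependent observable by unitary conjugation
#'
#' Builds the context-adjusted observable `A_con = U Q U^dag` from a base
#' observable `Q` and a supplied unitary encoding the context; unitarity is
#' validated to 1e-10.
#'
#' @param Q Base observable (`qop`).
#' @param U Unitary `qop` on the same basis.
#' @return The conjugated `qop`.
#' @export
context_observable <- function(Q, U) {
  stopifnot(inherits(Q, "qop"), inherits(U, "qop"))
  check_same_basis(Q$labels, U$labels, "observable and unitary")
  if (!is_unitary(U)) qcog_abort("U is not unitary", "qcog_contract_error")
  qop(U$matrix %*% Q$matrix %*% Conj(t(U$matrix)), Q$labels)
}

#' Subjective mixture update of outcome probabilities
#'
#' The dimension-weighted mixture update
#' `q(j) = ((d + 1) / d) * sum_i p(i) r(j|i)`, applied literally as printed
#' in the source model, together with a normalized variant
#' `q / sum(q)`. The literal form is not guaranteed to be a distribution
#' (its factor exceeds 1); both are returned and no corrected form is
#' guessed.
#'
#' @param p Prior distribution over `i` (sums to 1).
#' @param r Conditional matrix with `r[i, j] = r(j|i)`; rows are
#'   distributions.
#' @param d Hilbert-space dimension used in the `(d+1)/d` factor.
#' @return A tibble with columns `outcome`, `q_literal`, `q_normalized`.
#' @export
qbist_mixture_update <- function(p, r, d) {
  r <- as.matrix(r)
  stopifnot(length(p) == nrow(r), d >= 1)
  if (abs(sum(p) - 1) > qcog_tol$probabilistic) {
    qcog_abort("p must be a probability distribution", "qcog_contract_error")
  }
  if (max(abs(rowSums(r) - 1)) > qcog_tol$probabilistic) {
    qcog_abort("rows of r must be probability distributions", "qcog_contract_error")
  }
  q <- ((d + 1) / d) * as.vector(crossprod(r, p))
  tibble::tibble(outcome = seq_along(q), q_literal = q, q_normalized = q / sum(q))
}

#' Absorb a collapse generator into a measurement instrument
#'
#' Builds the measurement operators `M_i = Pi_i exp(-1i (H_sys - 1i Gamma) t)`
#' that absorb the non-Hermitian collapse propagator into a (subnormalized)
#' Kraus instrument: `Tr(rho M_i^dag M_i)` then reproduces the collapse
#' engine's raw populations `|a_i(t)|^2` exactly, recasting irreversible
#' decay as the agent's subjectively weighted instrument.
#'
#' @param H_sys Hermitian system Hamiltonian (`qop`).
#' @param Gamma Hermitian PSD decay operator (`qop`, same basis).
#' @param t Evolution time absorbed into the instrument.
#' @return A subnormalized [kraus_instrument()] with one rank-one operator
#'   per basis state.
#' @export
collapse_instrument <- function(H_sys, Gamma, t) {
  stopifnot(inherits(H_sys, "qop"), inherits(Gamma, "qop"))
  check_same_basis(H_sys$labels, Gamma$labels, "H_sys and Gamma")
  if (!is_hermitian(H_sys)) qcog_abort("H_sys must be Hermitian", "qcog_contract_error")
  if (!is_positive_semidefinite(Gamma)) {
    qcog_abort("Gamma must be Hermitian PSD", "qcog_contract_error")
  }
  prop <- expm_c(-1i * (H_sys$matrix - 1i * Gamma$matrix) * t)
  labels <- H_sys$labels
  ops <- lapply(seq_along(labels), function(i) {
    pi_i <- matrix(0, length(labels), length(labels))
    pi_i[i, i] <- 1
    qop(pi_i %*% prop, labels)
  })
  kraus_instrument(ops, outcome_labels = labels, subnormalized = TRUE)
}
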