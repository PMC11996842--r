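#' Observer context: focus state, initial state, influence strength
#'
#' Packages the observer-side quantities of the perturbation layer: a focus
#' state (directed intent), the observer's initial state, the dimensionless
#' influence strength `eta`, and the system-observer coupling `lam`
#' (inverse-time units, hbar = 1). Both states must live on the same observer
#' basis and be normalized.
#'
#' `observer_context_from_overlap()` builds a canonical two-state observer
#' whose focus/initial squared overlap equals `overlap_sq`, for scenarios
#' specified only through the overlap.
#'
#' @param focus_state,initial_state Normalized `qstate`s on a shared basis.
#' @param eta Influence strength, `eta >= 0` (warns above 0.2: the layer is
#'   a first-order perturbation).
#' @param lam Coupling constant (inverse time).
#' @return An object of class `observer_context`.
#' @export
#' @examples
#' ctx <- observer_context_from_overlap(0.5, eta = 0.01)
#' conscious_influence_factor(ctx) # 1.005
observer_context <- function(focus_state, initial_state, eta, lam = 0) {
  stopifnot(inherits(focus_state, "qstate"), inherits(initial_state, "qstate"))
  check_same_basis(focus_state$labels, initial_state$labels, "observer states")
  for (s in list(focus_state, initial_state)) {
    if (abs(sum(Mod(s$amplitudes)^2) - 1) > qcog_tol$structural) {
      qcog_abort("observer states must be normalized", "qcog_contract_error")
    }
  }
  stopifnot(eta >= 0)
  if (eta > 0.2) warning("eta > 0.2: outside the small-influence regime", call. = FALSE)
  structure(list(focus_state = focus_state, initial_state = initial_state,
                 eta = eta, lam = lam),
            class = "observer_context")
}

#' @rdname observer_context
#' @param overlap_sq Squared overlap `|<focus|initial>|^2` in `[0, 1]`.
#' @export
observer_context_from_overlap <- function(overlap_sq, eta, lam = 0) {
  stopifnot(overlap_sq >= 0, overlap_sq <= 1)
  a <- sqrt(overlap_sq)
  labels <- c("o1", "o2")
  observer_context(
    focus_state = make_state(labels, c(1, 0)),
    initial_state = make_state(labels, c(a, sqrt(1 - overlap_sq))),
    eta = eta, lam = lam
  )
}

#' Conscious-influence factor g
#'
#' The multiplicative modifier `g = 1 + eta * |<focus|initial>|^2`, bounded
#' in `[1, 1 + eta]`. With `eta = 0` (or orthogonal focus and initial
#' states) the layer reduces exactly to standard quantum probabilities.
#'
#' @param ctx An [observer_context()].
#' @return The factor `g`.
#' @export
conscious_influence_factor <- function(ctx) {
  stopifnot(inherits(ctx, "observer_context"))
  overlap_sq <- Mod(inner_product(ctx$focus_state, ctx$initial_state))^2
  1 + ctx$eta * overlap_sq
}

#' Observer-modified outcome probability
#'
#' Multiplies a standard Born probability by the conscious-influence factor:
#' `P = P_standard * g`. The raw product is reported un-renormalized, matching
#' the model's printed arithmetic; when the full outcome distribution is
#' supplied via `outcomes`, a companion renormalized distribution (dividing by
#' `sum(p_i * g_i)`) is returned alongside.
#'
#' @param p_standard Probability (or vector of probabilities) in `[0, 1]`.
#' @param ctx An [observer_context()].
#' @param outcomes Optional: full vector of standard probabilities over a
#'   complete outcome set (must sum to 1) to which the same factor applies;
#'   when given, a tibble with raw and renormalized columns is returned.
#' @return A numeric vector of raw modified probabilities, or a tibble with
#'   columns `p_standard`, `p_raw`, `p_renormalized` when `outcomes` is given.
#' @export
modified_probability <- function(p_standard, ctx, outcomes = NULL) {
  stopifnot(all(p_standard >= 0), all(p_standard <= 1))
  g <- conscious_influence_factor(ctx)
  raw <- p_standard * g
  if (any(raw > 1)) {
    warning("modified probability exceeds 1; clipping raw value", call. = FALSE)
    raw <- pmin(raw, 1)
  }
  if (is.null(outcomes)) return(raw)
  stopifnot(abs(sum(outcomes) - 1) < qcog_tol$probabilistic)
  raw_all <- outcomes * g
  tibble::tibble(
    p_standard = outcomes,
    p_raw = pmin(raw_all, 1),
    p_renormalized = raw_all / sum(raw_all)
  )
}

#' Angle perturbation parameters
#'
#' Small contextual shifts `delta_theta`, `delta_phi` (radians) applied to the
#' two angles of the conjunction model. Warns outside `|delta| < 0.2` rad,
#' the regime where the first-order formula is meaningful.
#'
#' @param delta_theta,delta_phi Shifts in radians (or degrees with `unit`).
#' @param unit `"radians"` or `"degrees"`.
#' @export
perturbation_params <- function(delta_theta, delta_phi,
                                unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  if (unit == "degrees") {
    delta_theta <- delta_theta * pi / 180
    delta_phi <- delta_phi * pi / 180
  }
  if (max(abs(delta_theta), abs(delta_phi)) >= 0.2) {
    warning("|delta| >= 0.2 rad: outside first-order validity", call. = FALSE)
  }
  structure(list(delta_theta = delta_theta, delta_phi = delta_phi),
            class = "perturbation_params")
}

#' First-order and exact perturbed conjunction probability
#'
#' With `Delta = theta - phi`, the first-order expansion of
#' `cos^2(Delta + (delta_theta - delta_phi))` is
#' `cos^2(Delta) - sin(2*Delta) * (delta_theta - delta_phi)`; the linear term
#' is only dimensionally consistent with the shifts in radians, and degree
#' inputs are converted at the API boundary ([perturbation_params()]).
#' `exact_perturbed_conjunction()` evaluates the unexpanded closed form and
#' serves as the exact oracle: the truncation error is O(delta^2).
#'
#' @param model An [angle_model()].
#' @param pert A [perturbation_params()].
#' @return Probability.
#' @export
#' @examples
#' m <- angle_model(60, 50, unit = "degrees")
#' d <- perturbation_params(5, 2, unit = "degrees")
#' exact_perturbed_conjunction(m, d) # cos^2(13 deg) ~ 0.949
first_order_conjunction_shift <- function(model, pert) {
  delta <- model$theta - model$phi
  cos(delta)^2 - sin(2 * delta) * (pert$delta_theta - pert$delta_phi)
}

#' @rdname first_order_conjunction_shift
#' @export
exact_perturbed_conjunction <- function(model, pert) {
  cos((model$theta + pert$delta_theta) - (model$phi + pert$delta_phi))^2
}

#' Combined angle-shift and conscious-influence probability
#'
#' Combines the perturbed conjunction probability with the multiplicative
#' conscious factor. Two forms are exposed: `"product"` multiplies the exact
#' perturbed probability by `g` (the worked-example arithmetic), and
#' `"expansion"` is the first-order expansion
#' `P + P*eta*|<f|i>|^2 - sin(2 Delta)(dtheta - dphi)` that drops the
#' O(eta*delta) cross-terms.
#'
#' @param model An [angle_model()].
#' @param pert A [perturbation_params()].
#' @param ctx An [observer_context()].
#' @param method `"product"` (default) or `"expansion"`.
#' @return Probability.
#' @export
combined_conjunction_probability <- function(model, pert, ctx,
                                             method = c("product", "expansion")) {
  method <- match.arg(method)
  if (method == "product") {
    exact_perturbed_conjunction(model, pert) * conscious_influence_factor(ctx)
  } else {
    p0 <- p_conjunction(model)
    overlap_sq <- Mod(inner_product(ctx$focus_state, ctx$initial_state))^2
    delta <- model$theta - model$phi
    p0 + p0 * ctx$eta * overlap_sq -
      sin(2 * delta) * (pert$delta_theta - pert$delta_phi)
  }
}

#' First-order amplitude correction from the observer coupling
#'
#' First-order time-dependent perturbation theory for the interaction
#' `H_int = lam * (A_sys (x) |focus><focus|)`, assuming the observer's own
#' Hamiltonian vanishes (the conscious state is constant over the
#' measurement). The correction to the transition amplitude into `|target>`
#' is
#' \deqn{A^{(1)}(t) = -i \lambda \langle f|i\rangle
#'   \int_0^t \langle target | A_{sys}(t') | \psi_0 \rangle \, dt'}
#' with `A_sys(t') = e^{iHt'} A_sys e^{-iHt'}` the interaction-picture
#' operator (hbar = 1). The integral is evaluated by adaptive quadrature on
#' the real and imaginary parts with absolute tolerance `abs_tol`.
#'
#' @param sys_H Hermitian system Hamiltonian (`qop`). Non-Hermitian
#'   generators are rejected — that regime belongs to the collapse engine.
#' @param A_sys System observable entering the interaction (`qop`).
#' @param psi_sys0 Initial system state (normalized `qstate`).
#' @param target Target eigenstate/outcome state (normalized `qstate`).
#' @param ctx [observer_context()] supplying `lam` and the overlap.
#' @param t Final time.
#' @param abs_tol Quadrature absolute tolerance (default 1e-10).
#' @return Complex first-order amplitude `A^(1)`.
#' @export
first_order_amplitude_correction <- function(sys_H, A_sys, psi_sys0, target,
                                             ctx, t, abs_tol = 1e-10) {
  stopifnot(inherits(sys_H, "qop"), inherits(A_sys, "qop"))
  if (!is_hermitian(sys_H)) {
    qcog_abort("sys_H must be Hermitian for the perturbation layer", "qcog_contract_error")
  }
  check_same_basis(sys_H$labels, A_sys$labels, "Hamiltonian and observable")
  check_same_basis(sys_H$labels, psi_sys0$labels, "Hamiltonian and initial state")
  check_same_basis(sys_H$labels, target$labels, "Hamiltonian and target state")
  overlap <- inner_product(ctx$focus_state, ctx$initial_state)
  if (ctx$lam == 0 || Mod(overlap) == 0) return(complex(real = 0, imaginary = 0))

  es <- eigen(sys_H$matrix)        # Hermitian: unitary eigenbasis
  v <- es$vectors
  ev <- Re(es$values)
  vt <- Conj(t(v))
  a_eig <- vt %*% A_sys$matrix %*% v
  tgt_eig <- as.vector(vt %*% target$amplitudes)
  psi_eig <- as.vector(vt %*% psi_sys0$amplitudes)

  integrand <- function(tp) {
    vapply(tp, function(s) {
      ph_left <- exp(1i * ev * s)    # e^{iHt'} acting on <target|
      ph_right <- exp(-1i * ev * s)  # e^{-iHt'} acting on |psi0>
      sum(Conj(tgt_eig) * ph_left * as.vector(a_eig %*% (ph_right * psi_eig)))
    }, complex(1))
  }
  re <- stats::integrate(function(s) Re(integrand(s)), 0, t,
                         abs.tol = abs_tol, rel.tol = abs_tol)$value
  im <- stats::integrate(function(s) Im(integrand(s)), 0, t,
                         abs.tol = abs_tol, rel.tol = abs_tol)$value
  -1i * ctx$lam * overlap * complex(real = re, imaginary = im)
}

#' Probability corrected to first order in the coupling
#'
#' Combines the unperturbed amplitude `A0 = <target| e^{-iHt} |psi0>` with
#' the first-order correction: keeping terms to first order the corrected
#' probability is `|A0|^2 + 2 Re(Conj(A0) * A1)`.
#'
#' @inheritParams first_order_amplitude_correction
#' @return A tibble with columns `a0`, `a1` (complex) and `p0`, `p_corrected`.
#' @export
perturbed_transition_probability <- function(sys_H, A_sys, psi_sys0, target,
                                             ctx, t, abs_tol = 1e-10) {
  es <- eigen(sys_H$matrix)
  v <- es$vectors
  ev <- Re(es$values)
  psi_t <- v %*% (exp(-1i * ev * t) * as.vector(Conj(t(v)) %*% psi_sys0$amplitudes))
  a0 <- sum(Conj(target$amplitudes) * as.vector(psi_t))
  a1 <- first_order_amplitude_correction(sys_H, A_sys, psi_sys0, target, ctx, t, abs_tol)
  p0 <- Mod(a0)^2
  tibble::tibble(a0 = a0, a1 = a1, p0 = p0,
                 p_corrected = p0 + 2 * Re(Conj(a0) * a1))
}
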