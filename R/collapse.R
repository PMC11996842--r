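#' Complex matrix exponential
#'
#' Scaling-and-squaring with a degree-13 Padé approximant, valid for general
#' complex (including non-Hermitian) square matrices. Used by the collapse
#' engine, where the generator `H - i*Gamma` is deliberately non-Hermitian;
#' dimensions in this package are tiny (<= 12) so no sparse path is needed.
#'
#' @param a A square complex (or numeric) matrix.
#' @return The matrix exponential `exp(a)`.
#' @export
expm_c <- function(a) {
  a <- as.matrix(a)
  stopifnot(nrow(a) == ncol(a))
  storage.mode(a) <- "complex"
  n <- nrow(a)
  id <- diag(n)
  nrm <- max(colSums(Mod(a)))   # 1-norm
  # scaling: bring norm under theta_13 ~ 5.37
  s <- max(0L, ceiling(log2(nrm / 5.371920351148152)))
  if (!is.finite(s)) s <- 0L
  a <- a / 2^s
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600,
         670442572800, 33522128640, 1323241920,
         40840800, 960960, 16380, 182, 1)
  a2 <- a %*% a
  a4 <- a2 %*% a2
  a6 <- a2 %*% a4
  u <- a %*% (a6 %*% (b[14] * a6 + b[12] * a4 + b[10] * a2) +
                b[8] * a6 + b[6] * a4 + b[4] * a2 + b[2] * id)
  v <- a6 %*% (b[13] * a6 + b[11] * a4 + b[9] * a2) +
    b[7] * a6 + b[5] * a4 + b[3] * a2 + b[1] * id
  f <- solve(v - u, v + u)
  for (k in seq_len(s)) f <- f %*% f
  f
}

#' Labeled non-Hermitian cognitive system
#'
#' The collapse engine's scenario container: an ordered basis of cognitive
#' states (e.g. `F`, `F&BT`, `BT`), a per-state alignment/salience coupling
#' `lam[i]` (the diagonal of the interaction Hamiltonian), a per-state decay
#' rate `gamma[i] >= 0` (the diagonal of the collapse operator), and the
#' initial complex amplitudes. The effective generator is diagonal in this
#' basis, `H_eff[i] = lam[i] - 1i*gamma[i]`, so each amplitude obeys
#' `a_i(t) = a_i(0) * exp((-1i*lam[i] - gamma[i]) * t)` (hbar = 1).
#'
#' @param labels Ordered basis names.
#' @param lam Per-state couplings (real, inverse time).
#' @param gamma Per-state decay rates, all `>= 0`.
#' @param a0 Initial complex amplitudes, `sum(|a0|^2) = 1` within 1e-10.
#' @return Object of class `nh_system`.
#' @export
#' @examples
#' nh_system(c("F", "F&BT", "BT"), lam = c(1, .6, .3),
#'           gamma = c(.05, .15, .4), a0 = c(1, 0, 1) / sqrt(2))
nh_system <- function(labels, lam, gamma, a0) {
  n <- length(labels)
  stopifnot(length(lam) == n, length(gamma) == n, length(a0) == n)
  if (any(gamma < 0)) qcog_abort("decay rates gamma must be >= 0", "qcog_contract_error")
  a0 <- as.complex(a0)
  if (abs(sum(Mod(a0)^2) - 1) > qcog_tol$structural) {
    qcog_abort("initial amplitudes must satisfy sum |a0|^2 = 1", "qcog_contract_error")
  }
  structure(list(labels = labels, lam = as.numeric(lam),
                 gamma = as.numeric(gamma), a0 = a0, hbar = 1),
            class = "nh_system")
}

#' Total Hamiltonian with a non-Hermitian collapse term
#'
#' Assembles `(H_sys - 1i*Gamma) (x) I + I (x) H_intO + H_int` on the
#' system-observer tensor basis. `Gamma` must be Hermitian positive
#' semidefinite; the anti-Hermitian part of the result is then exactly
#' `-1i * (Gamma (x) I)`, the only source of norm decay.
#'
#' @param H_sys,Gamma `qop`s on the system basis (`H_sys` Hermitian, `Gamma`
#'   Hermitian PSD).
#' @param H_intO `qop` on the observer basis (Hermitian).
#' @param H_int `qop` on the tensor basis (may be zero).
#' @return A `qop` on the tensor basis.
#' @export
build_total_hamiltonian <- function(H_sys, Gamma, H_intO, H_int = NULL) {
  stopifnot(inherits(H_sys, "qop"), inherits(Gamma, "qop"), inherits(H_intO, "qop"))
  check_same_basis(H_sys$labels, Gamma$labels, "H_sys and Gamma")
  if (!is_hermitian(H_sys)) qcog_abort("H_sys must be Hermitian", "qcog_contract_error")
  if (!is_hermitian(H_intO)) qcog_abort("H_intO must be Hermitian", "qcog_contract_error")
  if (!is_positive_semidefinite(Gamma)) {
    qcog_abort("Gamma must be a positive semidefinite Hermitian operator", "qcog_contract_error")
  }
  i_sys <- qop_identity(H_sys$labels)
  i_obs <- qop_identity(H_intO$labels)
  eff <- qop(H_sys$matrix - 1i * Gamma$matrix, H_sys$labels)
  total <- qop(kronecker(eff$matrix, i_obs$matrix) +
                 kronecker(i_sys$matrix, H_intO$matrix),
               tensor_labels(H_sys$labels, H_intO$labels))
  if (!is.null(H_int)) {
    check_same_basis(total$labels, H_int$labels, "total Hamiltonian and H_int")
    total$matrix <- total$matrix + H_int$matrix
  }
  total
}

#' Targeted collapse operator
#'
#' Diagonal decay operator `Gamma = gamma * sum_{k != k0} |a_k><a_k|`: zero
#' on the target state, rate `gamma` on every other basis state. Evolving
#' under `-1i*Gamma` alone drives the (renormalized) population of the target
#' state to 1 — the continuous-measurement, quantum-Zeno-style mechanism of
#' collapse toward a preferred cognitive state.
#'
#' @param dim Basis dimension (or a character vector of labels).
#' @param target_index 1-based index of the protected target state.
#' @param gamma Decay rate, `> 0`.
#' @return A diagonal PSD `qop`.
#' @export
build_targeted_collapse_operator <- function(dim, target_index, gamma) {
  labels <- if (is.character(dim)) dim else paste0("a", seq_len(dim))
  n <- length(labels)
  stopifnot(gamma > 0)
  if (target_index < 1 || target_index > n) {
    qcog_abort("target_index out of range", "qcog_shape_error")
  }
  d <- rep(gamma, n)
  d[target_index] <- 0
  qop(diag(d, n), labels)
}

# internal: assemble the tidy evolution tibble shared by the engines
evolution_tibble <- function(labels, times, amp_matrix, raw_p = NULL) {
  # amp_matrix: length(times) x length(labels) complex
  p_mod2 <- Mod(amp_matrix)^2
  if (is.null(raw_p)) raw_p <- p_mod2
  norm_t <- rowSums(p_mod2)
  clamped <- pmax(raw_p, 0)
  reported <- clamped / ifelse(rowSums(clamped) > 0, rowSums(clamped), 1)
  out <- tibble::tibble(
    time = rep(times, times = length(labels)),
    state = rep(labels, each = length(times)),
    amplitude = as.vector(amp_matrix),
    raw_p = as.vector(raw_p),
    reported_p = as.vector(reported),
    norm = rep(norm_t, times = length(labels))
  )
  class(out) <- c("qevolution", class(out))
  out
}

#' Analytic amplitudes of a diagonal non-Hermitian system
#'
#' Closed-form evolution `a_i(t) = a_i(0) exp((-1i*lam_i - gamma_i) t)`,
#' valid when the generator is diagonal in the system's own basis (the
#' Linda/prisoner's-dilemma construction). Magnitudes decay as
#' `|a_i(0)| exp(-gamma_i t)`; this closed form is the oracle against which
#' the general matrix-exponential engine is tested.
#'
#' @param sys An [nh_system()].
#' @param times Numeric vector of time points.
#' @return A `qevolution` tibble: columns `time`, `state`, `amplitude`,
#'   `raw_p` (`|a_i|^2`), `reported_p` (clamped, renormalized), `norm`.
#' @export
analytic_amplitudes <- function(sys, times) {
  stopifnot(inherits(sys, "nh_system"))
  amp <- vapply(seq_along(sys$labels), function(i) {
    sys$a0[i] * exp((-1i * sys$lam[i] - sys$gamma[i]) * times / sys$hbar)
  }, complex(length(times)))
  amp <- matrix(amp, nrow = length(times))
  evolution_tibble(sys$labels, times, amp)
}

#' Evolve a state under an arbitrary (possibly non-Hermitian) generator
#'
#' Computes `psi(t) = exp(-1i*H*t) psi0` at each requested time via the
#' complex matrix exponential ([expm_c()]), one exponential per time point
#' (dimensions are tiny; no Trotterization). For Hermitian `H` the norm is
#' conserved; when the anti-Hermitian part is `-1i*Gamma` with `Gamma` PSD
#' the norm is non-increasing.
#'
#' @param H_total A `qop` (any square generator).
#' @param psi0 Normalized initial `qstate` on the same basis.
#' @param times Numeric vector of time points.
#' @return A `qevolution` tibble (see [analytic_amplitudes()]).
#' @export
evolve <- function(H_total, psi0, times) {
  stopifnot(inherits(H_total, "qop"), inherits(psi0, "qstate"))
  check_same_basis(H_total$labels, psi0$labels, "generator and state")
  if (abs(sum(Mod(psi0$amplitudes)^2) - 1) > qcog_tol$structural) {
    qcog_abort("psi0 must be normalized", "qcog_contract_error")
  }
  amp <- t(vapply(times, function(tt) {
    as.vector(expm_c(-1i * H_total$matrix * tt) %*% psi0$amplitudes)
  }, complex(length(psi0$labels))))
  amp <- matrix(amp, nrow = length(times))
  evolution_tibble(H_total$labels, times, amp)
}

#' Conjunction amplitude from its two branches
#'
#' The conjunction state is the balanced superposition
#' `|conj> = (|x> + |y>)/sqrt(2)`, so its amplitude is
#' `a2 = (a1 + a3)/sqrt(2)` and its probability
#' `|a2|^2 = (|a1|^2 + |a3|^2 + 2 Re(a1 * Conj(a3)))/2` — the interference
#' decomposition that boosts (or suppresses) the conjunction.
#'
#' @param a1,a3 Complex amplitudes of the two branch states.
#' @return Complex amplitude of the conjunction state.
#' @export
conjunction_amplitude <- function(a1, a3) (a1 + a3) / sqrt(2)

#' Interference-aware probabilities of a three-state collapse system
#'
#' For a system ordered as (branch-1, conjunction, branch-2) — e.g.
#' `(F, F&BT, BT)` or `(A, A&B, B)` — evolves the two branch amplitudes
#' analytically, derives the conjunction amplitude as `(a1 + a3)/sqrt(2)`,
#' and computes the model's raw probabilities exactly as defined:
#' `P(1) = |a1|^2`, `P(conj) = |a2|^2` (whose cross term carries the factor
#' `exp((-1i*dlam - dgam)t)` with `dlam = lam[1]-lam[3]`,
#' `dgam = gamma[1]-gamma[3]`), and `P(3) = |a3|^2 - P(conj)` — the
#' subtraction of the branch weight absorbed into the conjunction, which can
#' be negative. Raw values reproduce that algebra untouched;
#' `reported_p` clamps negatives to zero and renormalizes.
#'
#' @param sys An [nh_system()] with exactly three states; the middle initial
#'   amplitude is the derived conjunction slot and should be 0.
#' @param times Numeric vector of time points.
#' @return A `qevolution` tibble with both `raw_p` and `reported_p`.
#' @export
probabilities_with_interference <- function(sys, times) {
  stopifnot(inherits(sys, "nh_system"))
  if (length(sys$labels) != 3L) {
    qcog_abort("interference model requires a three-state system", "qcog_shape_error")
  }
  if (Mod(sys$a0[2]) > qcog_tol$structural) {
    warning("middle amplitude is derived from the branches; a0[2] is ignored",
            call. = FALSE)
  }
  a1 <- sys$a0[1] * exp((-1i * sys$lam[1] - sys$gamma[1]) * times)
  a3 <- sys$a0[3] * exp((-1i * sys$lam[3] - sys$gamma[3]) * times)
  a2 <- conjunction_amplitude(a1, a3)
  amp <- cbind(a1, a2, a3)
  raw <- cbind(Mod(a1)^2, Mod(a2)^2, Mod(a3)^2 - Mod(a2)^2)
  evolution_tibble(sys$labels, times, amp, raw_p = raw)
}

#' Zeno-style suppression ratio under targeted collapse
#'
#' Ratio of the total non-target population at time `t` to its initial
#' value, `P_nontarget(t) / P_nontarget(0)`, for a diagonal system whose
#' decay rates vanish on the target state (the [build_targeted_collapse_operator()]
#' construction: the target is the state with the smallest `gamma`). The
#' ratio is 1 at `gamma = 0`, strictly decreasing in `gamma`, and tends to 0
#' as `gamma*t` grows — frequent/continuous measurement freezing the system
#' into the target state.
#'
#' @param sys An [nh_system()].
#' @param t Evaluation time, `> 0`.
#' @return Suppression ratio in `[0, 1]`.
#' @export
zeno_suppression_ratio <- function(sys, t) {
  stopifnot(inherits(sys, "nh_system"), t > 0)
  target <- which.min(sys$gamma)
  nontarget <- setdiff(seq_along(sys$labels), target)
  p0 <- sum(Mod(sys$a0[nontarget])^2)
  if (p0 == 0) return(0)
  pt <- sum(Mod(sys$a0[nontarget])^2 * exp(-2 * sys$gamma[nontarget] * t))
  pt / p0
}
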