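#' Construct a state vector on a labeled basis
#'
#' A `qstate` is a complex amplitude vector over named basis states. Basis
#' labels are strings and all compatibility checks in the package compare
#' labels, not just dimensions, so states and operators built on different
#' bases can never be silently combined.
#'
#' Amplitudes can be supplied directly as (possibly complex) numbers, or as
#' magnitude/phase pairs via `magnitude` and `phase` (radians), which is
#' convenient when a model is parameterized by interference phases.
#'
#' @param labels Character vector of basis-state names (unique, length >= 1).
#' @param amplitudes Numeric or complex vector, one amplitude per label.
#' @param normalize If `TRUE`, divide by the vector norm; if `FALSE` the
#'   amplitudes must already be normalized to within `tol`.
#' @param magnitude,phase Alternative amplitude spec: `magnitude * exp(1i*phase)`.
#' @param tol Structural tolerance for the normalization check.
#' @return An object of class `qstate` with fields `labels` and `amplitudes`.
#' @export
#' @examples
#' make_state(c("B", "F"), c(1, 1), normalize = TRUE)
make_state <- function(labels, amplitudes = NULL, normalize = FALSE,
                       magnitude = NULL, phase = NULL,
                       tol = qcog_tol$structural) {
  stopifnot(is.character(labels), length(labels) >= 1L, !anyDuplicated(labels))
  if (is.null(amplitudes)) {
    if (is.null(magnitude)) {
      qcog_abort("supply `amplitudes` or `magnitude`(/`phase`)", "qcog_shape_error")
    }
    if (is.null(phase)) phase <- rep(0, length(magnitude))
    if (length(magnitude) != length(phase)) {
      qcog_abort("`magnitude` and `phase` lengths differ", "qcog_shape_error")
    }
    amplitudes <- magnitude * exp(1i * phase)
  }
  if (length(amplitudes) != length(labels)) {
    qcog_abort("length(amplitudes) != length(labels)", "qcog_shape_error")
  }
  amplitudes <- as.complex(amplitudes)
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (nrm == 0) {
    qcog_abort("all-zero amplitude vector is a degenerate state", "qcog_degenerate_state")
  }
  if (normalize) {
    amplitudes <- amplitudes / nrm
  } else if (abs(nrm - 1) > tol) {
    qcog_abort(
      sprintf("state not normalized (norm = %.12g); pass normalize = TRUE", nrm),
      "qcog_contract_error"
    )
  }
  structure(list(labels = labels, amplitudes = amplitudes), class = "qstate")
}

#' @export
print.qstate <- function(x, ...) {
  cat("<qstate> dim", length(x$labels), "\n")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  |%s>  %s\n", x$labels[i], format(x$amplitudes[i], digits = 6)))
  }
  invisible(x)
}

#' Construct a linear operator on a labeled basis
#'
#' @param matrix Square complex matrix (rows and columns share one basis).
#' @param labels Character vector of basis names, length `nrow(matrix)`.
#' @return An object of class `qop`.
#' @export
qop <- function(matrix, labels) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) qcog_abort("operator matrix not square", "qcog_shape_error")
  if (length(labels) != nrow(matrix)) qcog_abort("labels length != matrix dimension", "qcog_shape_error")
  storage.mode(matrix) <- "complex"
  dimnames(matrix) <- list(labels, labels)
  structure(list(matrix = matrix, labels = labels), class = "qop")
}

#' @export
print.qop <- function(x, ...) {
  cat("<qop> dim", length(x$labels), "on {", paste(x$labels, collapse = ", "), "}\n")
  print(x$matrix, digits = 4)
  invisible(x)
}

#' Identity operator on a labeled basis
#' @param labels Character vector of basis names.
#' @export
qop_identity <- function(labels) qop(diag(length(labels)), labels)

#' Construct a density operator
#'
#' Validates Hermiticity, positive semidefiniteness and unit trace to within
#' `tol` (structural default 1e-10).
#'
#' @param matrix Square complex matrix.
#' @param labels Basis names.
#' @param tol Structural tolerance.
#' @return An object of class `qdensity` (also a `qop`).
#' @export
qdensity <- function(matrix, labels, tol = qcog_tol$structural) {
  op <- qop(matrix, labels)
  if (!is_hermitian(op, tol)) qcog_abort("density matrix not Hermitian", "qcog_contract_error")
  if (!is_positive_semidefinite(op, tol)) {
    qcog_abort("density matrix not positive semidefinite", "qcog_contract_error")
  }
  tr <- Re(sum(diag(op$matrix)))
  if (abs(tr - 1) > tol) qcog_abort("density matrix trace != 1", "qcog_contract_error")
  class(op) <- c("qdensity", "qop")
  op
}

#' Density operator of a pure state
#' @param state A normalized `qstate`.
#' @export
density_from_state <- function(state) {
  stopifnot(inherits(state, "qstate"))
  qdensity(outer(state$amplitudes, Conj(state$amplitudes)), state$labels)
}

# ---- predicates ------------------------------------------------------------

#' Operator predicates
#'
#' Structural tests for operator classes used as preconditions across the
#' package: Hermitian, positive semidefinite, projector (idempotent and
#' Hermitian), unitary.
#'
#' @param op A `qop`.
#' @param tol Tolerance on the defining identity.
#' @return Logical scalar.
#' @export
is_hermitian <- function(op, tol = qcog_tol$structural) {
  m <- op$matrix
  max(Mod(m - Conj(t(m)))) <= tol
}

#' @rdname is_hermitian
#' @export
is_positive_semidefinite <- function(op, tol = qcog_tol$structural) {
  if (!is_hermitian(op, tol)) return(FALSE)
  ev <- eigen((op$matrix + Conj(t(op$matrix))) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(Re(ev)) >= -tol
}

#' @rdname is_hermitian
#' @export
is_projector <- function(op, tol = qcog_tol$structural) {
  m <- op$matrix
  is_hermitian(op, tol) && max(Mod(m %*% m - m)) <= tol
}

#' @rdname is_hermitian
#' @export
is_unitary <- function(op, tol = qcog_tol$structural) {
  m <- op$matrix
  max(Mod(Conj(t(m)) %*% m - diag(nrow(m)))) <= tol
}

# internal: label compatibility check
check_same_basis <- function(a_labels, b_labels, what = "objects") {
  if (!identical(a_labels, b_labels)) {
    qcog_abort(paste(what, "are defined on different bases"), "qcog_shape_error")
  }
  invisible(TRUE)
}

# internal: Tr(rho %*% P), real part (both Hermitian => trace real)
born_trace <- function(rho_matrix, p_matrix) {
  Re(sum(rho_matrix * t(p_matrix)))
}

# ---- Born rule and projectors ---------------------------------------------

#' Born-rule probability of a projective outcome
#'
#' Computes `Tr(rho P)` for the pure state `rho = |psi><psi|`, equal to
#' `<psi|P|psi>`. The operator must satisfy [is_projector()].
#'
#' @param state Normalized `qstate`.
#' @param projector A `qop` that is a projector.
#' @param tol Structural tolerance for the projector/normalization checks.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' psi <- make_state(c("B", "F"), c(cos(pi / 3), sin(pi / 3)))
#' born_probability(psi, projector_from_state(make_state(c("B", "F"), c(1, 0))))
born_probability <- function(state, projector, tol = qcog_tol$structural) {
  stopifnot(inherits(state, "qstate"), inherits(projector, "qop"))
  check_same_basis(state$labels, projector$labels, "state and projector")
  if (!is_projector(projector, tol)) {
    qcog_abort("operator is not a projector", "qcog_contract_error")
  }
  if (abs(sum(Mod(state$amplitudes)^2) - 1) > tol) {
    qcog_abort("state is not normalized", "qcog_contract_error")
  }
  rho <- outer(state$amplitudes, Conj(state$amplitudes))
  p <- born_trace(rho, projector$matrix)
  min(max(p, 0), 1)
}

#' Rank-one projector onto a state
#'
#' Returns the outer product `|psi><psi|`, e.g. the observer-focus projector
#' used in the interaction Hamiltonian.
#'
#' @param state Normalized `qstate`.
#' @param tol Structural tolerance for the normalization check.
#' @return A `qop` satisfying [is_projector()].
#' @export
projector_from_state <- function(state, tol = qcog_tol$structural) {
  stopifnot(inherits(state, "qstate"))
  if (abs(sum(Mod(state$amplitudes)^2) - 1) > tol) {
    qcog_abort("state is not normalized", "qcog_contract_error")
  }
  qop(outer(state$amplitudes, Conj(state$amplitudes)), state$labels)
}

#' Projector onto a single basis state
#' @param labels Basis names.
#' @param which Label (or index) of the basis state.
#' @export
basis_projector <- function(labels, which) {
  idx <- if (is.character(which)) match(which, labels) else as.integer(which)
  if (is.na(idx) || idx < 1L || idx > length(labels)) {
    qcog_abort("basis label/index not found", "qcog_shape_error")
  }
  m <- matrix(0, length(labels), length(labels))
  m[idx, idx] <- 1
  qop(m, labels)
}

# ---- tensor products -------------------------------------------------------

tensor_labels <- function(a, b) {
  as.vector(t(outer(a, b, function(x, y) paste0(x, "⊗", y))))
}

#' Tensor (Kronecker) product of states or operators
#'
#' Both operands must be of the same kind (`qstate` with `qstate`, `qop` with
#' `qop`). Labels of the result are pairs joined with the tensor sign, and
#' dimensions multiply exactly.
#'
#' @param a,b Two `qstate`s or two `qop`s.
#' @return Object of the same kind on the product basis.
#' @export
#' @examples
#' tensor(make_state("B", 1), make_state(c("u", "d"), c(1, 0)))
tensor <- function(a, b) {
  if (inherits(a, "qstate") && inherits(b, "qstate")) {
    structure(list(labels = tensor_labels(a$labels, b$labels),
                   amplitudes = as.vector(kronecker(a$amplitudes, b$amplitudes))),
              class = "qstate")
  } else if (inherits(a, "qop") && inherits(b, "qop")) {
    qop(kronecker(a$matrix, b$matrix), tensor_labels(a$labels, b$labels))
  } else {
    qcog_abort("tensor() operands must both be states or both operators", "qcog_type_error")
  }
}

#' Apply an operator to a state
#' @param op A `qop`.
#' @param state A `qstate` on the same basis.
#' @param normalize Normalize the result (default `FALSE`; result may be
#'   unnormalized, e.g. after non-unitary maps).
#' @return A `qstate` (possibly unnormalized; constructed without the
#'   normalization contract).
#' @export
apply_operator <- function(op, state, normalize = FALSE) {
  check_same_basis(op$labels, state$labels, "operator and state")
  amps <- as.vector(op$matrix %*% state$amplitudes)
  if (normalize) {
    make_state(state$labels, amps, normalize = TRUE)
  } else {
    structure(list(labels = state$labels, amplitudes = amps), class = "qstate")
  }
}

#' Inner product of two states
#' @param a,b `qstate`s on the same basis; returns `<a|b>`.
#' @export
inner_product <- function(a, b) {
  check_same_basis(a$labels, b$labels, "states")
  sum(Conj(a$amplitudes) * b$amplitudes)
}
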