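#' Two-angle quantum-probability model of the conjunction fallacy
#'
#' The Linda-style conjunction model represents a judge's belief state in a
#' two-dimensional Hilbert space spanned by `|B>` ("bank teller") and `|F>`
#' ("feminist"): `|psi> = cos(theta)|B> + sin(theta)|F>`. The conjunction
#' "bank teller and feminist" is its own basis direction
#' `|B_F> = cos(phi)|B> + sin(phi)|F>`. Single-event and conjunction
#' probabilities follow from the Born rule: `P(T) = cos^2(theta)` and
#' `P(T and F) = cos^2(theta - phi)`, so when `phi` is close to `theta` the
#' conjunction can be judged *more* likely than the single event — the
#' conjunction fallacy, produced here by constructive interference.
#'
#' @param theta Belief-weighting angle (bank teller vs feminist).
#' @param phi Conjunction-state mixing angle.
#' @param unit `"radians"` (default, internal unit) or `"degrees"`.
#' @return An object of class `angle_model` with `theta` and `phi` in radians.
#' @export
#' @examples
#' m <- angle_model(60, 50, unit = "degrees")
#' p_single(m)       # 0.25
#' p_conjunction(m)  # ~0.9698
#' fallacy_holds(m)  # TRUE
angle_model <- function(theta, phi, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  if (unit == "degrees") {
    theta <- theta * pi / 180
    phi <- phi * pi / 180
  }
  stopifnot(is.finite(theta), is.finite(phi))
  if (theta < 0 || theta > pi / 2 || phi < 0 || phi > pi / 2) {
    warning("angles outside the canonical range [0, pi/2]; probabilities remain valid",
            call. = FALSE)
  }
  structure(list(theta = theta, phi = phi), class = "angle_model")
}

#' @export
print.angle_model <- function(x, ...) {
  cat(sprintf("<angle_model> theta = %.6g rad (%.4g deg), phi = %.6g rad (%.4g deg)\n",
              x$theta, x$theta * 180 / pi, x$phi, x$phi * 180 / pi))
  invisible(x)
}

#' Belief state and conjunction basis state of the angle model
#'
#' `belief_state()` returns `cos(theta)|B> + sin(theta)|F>`;
#' `conjunction_basis_state()` returns `cos(phi)|B> + sin(phi)|F>`.
#'
#' @param model An [angle_model()].
#' @return A normalized `qstate` over labels `B`, `F`.
#' @export
belief_state <- function(model) {
  structure(list(labels = c("B", "F"),
                 amplitudes = as.complex(c(cos(model$theta), sin(model$theta)))),
            class = "qstate")
}

#' @rdname belief_state
#' @export
conjunction_basis_state <- function(model) {
  structure(list(labels = c("B", "F"),
                 amplitudes = as.complex(c(cos(model$phi), sin(model$phi)))),
            class = "qstate")
}

#' Single-event and conjunction probabilities
#'
#' Closed forms `cos^2(theta)` and `cos^2(theta - phi)`; both agree with the
#' Born-rule evaluation through the Hilbert-space layer (tested to 1e-12).
#'
#' @param model An [angle_model()].
#' @return Probability in `[0, 1]`.
#' @export
p_single <- function(model) cos(model$theta)^2

#' @rdname p_single
#' @export
p_conjunction <- function(model) cos(model$theta - model$phi)^2

#' Does the model predict the conjunction fallacy?
#'
#' `TRUE` iff `p_conjunction(model) > p_single(model)`, which for angles in
#' the canonical range is the condition `|theta - phi| < theta`.
#'
#' @param model An [angle_model()].
#' @return Logical scalar.
#' @export
fallacy_holds <- function(model) {
  if (model$theta <= 0 || model$theta >= pi / 2) {
    warning("fallacy predicate is characterized for theta in (0, pi/2)", call. = FALSE)
  }
  p_conjunction(model) > p_single(model)
}

#' Tabulate the conjunction model over an angle grid
#'
#' Evaluates the model over all combinations of `theta` and `phi` and returns
#' a tibble with one row per pair — the tabular surface used by the scenario
#' writer and by [plot_fallacy_region()].
#'
#' @param theta,phi Numeric vectors of angles.
#' @param unit `"radians"` or `"degrees"`.
#' @return A tibble with columns `theta`, `phi` (radians), `p_single`,
#'   `p_conjunction`, `fallacy`.
#' @export
conjunction_table <- function(theta, phi, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  if (unit == "degrees") {
    theta <- theta * pi / 180
    phi <- phi * pi / 180
  }
  tidyr::expand_grid(theta = theta, phi = phi) |>
    dplyr::mutate(
      p_single = cos(.data$theta)^2,
      p_conjunction = cos(.data$theta - .data$phi)^2,
      fallacy = .data$p_conjunction > .data$p_single
    )
}

#' Reference empirical anchors for the Linda task
#'
#' Frequently cited empirical rates for the Linda conjunction task
#' (single-event judgment near 15%, conjunction near 85%). Shipped as
#' calibration reference constants for demos; they are *cited empirical
#' values*, not model outputs, and no fitting to them is implemented.
#'
#' @return Named numeric vector `c(p_single = 0.15, p_conjunction = 0.85)`.
#' @export
linda_empirical_anchors <- function() {
  c(p_single = 0.15, p_conjunction = 0.85)
}
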