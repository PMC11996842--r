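#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy an evolution result
#'
#' Returns the long per-time, per-state table with amplitudes split into
#' real and imaginary parts (plain columns, CSV-friendly).
#'
#' @param x A `qevolution` tibble.
#' @param ... Unused.
#' @return A tibble with columns `time`, `state`, `re_amp`, `im_amp`,
#'   `raw_p`, `reported_p`, `norm`.
#' @export
tidy.qevolution <- function(x, ...) {
  tibble::tibble(
    time = x$time, state = x$state,
    re_amp = Re(x$amplitude), im_amp = Im(x$amplitude),
    raw_p = x$raw_p, reported_p = x$reported_p, norm = x$norm
  )
}

#' One-row summary of an evolution result
#'
#' @param x A `qevolution` tibble.
#' @param ... Unused.
#' @return A tibble with `n_states`, `n_times`, `t_max`, `final_norm`,
#'   `norm_monotone` (is the total squared amplitude non-increasing).
#' @export
glance.qevolution <- function(x, ...) {
  by_t <- dplyr::distinct(tibble::tibble(time = x$time, norm = x$norm)) |>
    dplyr::arrange(.data$time)
  tibble::tibble(
    n_states = dplyr::n_distinct(x$state),
    n_times = nrow(by_t),
    t_max = max(by_t$time),
    final_norm = by_t$norm[nrow(by_t)],
    norm_monotone = all(diff(by_t$norm) <= 1e-9)
  )
}

#' Tidy / summarize a scenario ranking
#'
#' @param x A `qranking` tibble.
#' @param ... Unused.
#' @return `tidy()`: the ranking as a plain tibble. `glance()`: one row with
#'   the winning state, its probability, the evaluation time, and (for the
#'   prisoner's-dilemma scenario) the sure-thing-principle violation flag.
#' @export
tidy.qranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rank", "state", "probability", "raw_p",
                                 "t_eval", "tied_with_next")])
}

#' @rdname tidy.qranking
#' @export
glance.qranking <- function(x, ...) {
  out <- tibble::tibble(
    top_state = x$state[1],
    top_probability = x$probability[1],
    t_eval = x$t_eval[1],
    any_tie = any(x$tied_with_next)
  )
  stv <- attr(x, "sure_thing_violation")
  if (!is.null(stv)) out$sure_thing_violation <- stv
  out
}

#' Plot probability trajectories of an evolution result
#'
#' One line per cognitive state, reported (clamped, renormalized)
#' probability against time; set `raw = TRUE` for the unclamped model
#' algebra, which can dip below zero for subtracted branches.
#'
#' @param object A `qevolution` tibble.
#' @param raw Plot `raw_p` instead of `reported_p`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qevolution <- function(object, raw = FALSE, ...) {
  ycol <- if (raw) "raw_p" else "reported_p"
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data[[ycol]],
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = if (raw) "raw probability" else "reported probability",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot a scenario ranking
#'
#' @param object A `qranking` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of outcome probabilities at `t_eval`.
#' @export
autoplot.qranking <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$state, -.data$probability),
                                  y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = sprintf("probability at t = %.3g", d$t_eval[1])) +
    ggplot2::theme_minimal()
}

#' Map the conjunction-fallacy region of the angle model
#'
#' Tiles the `(theta, phi)` plane with the fallacy predicate
#' `P(conjunction) > P(single)`, i.e. `|theta - phi| < theta`.
#'
#' @param n Grid resolution per axis.
#' @return A ggplot tile plot.
#' @export
plot_fallacy_region <- function(n = 101) {
  eps <- 1e-6
  grid <- conjunction_table(seq(eps, pi / 2 - eps, length.out = n),
                            seq(0, pi / 2, length.out = n))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$theta * 180 / pi,
                                     y = .data$phi * 180 / pi,
                                     fill = .data$fallacy)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "theta (deg)", y = "phi (deg)", fill = "conjunction\nfallacy") +
    ggplot2::theme_minimal()
}
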