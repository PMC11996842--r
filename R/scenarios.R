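#' Declarative scenario configurations
#'
#' Builds a validated configuration for one of the pre-wired decision tasks:
#'
#' * `"linda_qpt"` — the two-angle conjunction model plus the observer
#'   perturbation layer (the worked-example pipeline);
#' * `"linda_collapse"` — the three-state non-Hermitian collapse model over
#'   `(F, F&BT, BT)`;
#' * `"prisoner_dilemma"` — the three-state model over `(A, A&B, B)` with
#'   collapsed-branch comparisons and the sure-thing-principle flag;
#' * `"two_path_shift"` — a seeded two-outcome session simulator with the
#'   multiplicative probability shift `P[1 + eta*overlap^2]`.
#'
#' Unknown parameter names are rejected (fail-closed validation); omitted
#' parameters take the defaults listed below, which encode the tasks'
#' qualitative constraints: strict alignment ordering `lam[1] > lam[2] >
#' lam[3]` (strongest for the congruent branch) and strict decay ordering
#' `gamma[1] < gamma[2] < gamma[3]` (fastest for the incongruent branch).
#'
#' @param kind Scenario kind (see above).
#' @param ... Named task parameters overriding the defaults.
#' @return Object of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config("linda_collapse")
#' run_linda_collapse(cfg)
scenario_config <- function(kind = c("linda_qpt", "linda_collapse",
                                     "prisoner_dilemma", "two_path_shift"),
                            ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    linda_qpt = list(theta_deg = 60, phi_deg = 50, delta_theta_deg = 5,
                     delta_phi_deg = 2, eta = 0.01, overlap_sq = 0.5),
    linda_collapse = list(labels = c("F", "F&BT", "BT"),
                          lam = c(1.0, 0.6, 0.3),
                          gamma = c(0.05, 0.15, 0.4),
                          a0_magnitude = c(1 / sqrt(2), 0, 1 / sqrt(2)),
                          a0_phase = c(0, 0, 0),
                          t_max = 6, n_steps = 121, t_eval = NULL),
    prisoner_dilemma = list(labels = c("A", "A&B", "B"),
                            lam = c(1.0, 0.6, 0.3),
                            gamma = c(0.1, 0.2, 0.5),
                            gamma_defect = 0.8,
                            a0_magnitude = c(1 / sqrt(2), 0, 1 / sqrt(2)),
                            a0_phase = c(0, 0, 0),
                            t_max = 6, n_steps = 121, t_eval = NULL),
    two_path_shift = list(baseline = 0.5, eta = 0.01, overlap_sq = 0.5,
                          n_trials = 1e6, seed = 1)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    qcog_abort(paste0("unknown parameter(s) for ", kind, ": ",
                      paste(unknown, collapse = ", ")),
               "qcog_schema_error")
  }
  params <- utils::modifyList(defaults, override)
  if (kind %in% c("linda_collapse", "prisoner_dilemma")) {
    if (!(params$lam[1] > params$lam[2] && params$lam[2] > params$lam[3])) {
      qcog_abort("scenario requires strict alignment ordering lam[1] > lam[2] > lam[3]",
                 "qcog_config_error")
    }
    if (!(params$gamma[1] < params$gamma[2] && params$gamma[2] < params$gamma[3])) {
      qcog_abort(paste("scenario requires strict decay ordering gamma[1] < gamma[2] < gamma[3]:",
                       "the incongruent branch decays fastest"),
                 "qcog_config_error")
    }
  }
  structure(list(kind = kind, parameters = params), class = "scenario_config")
}

# internal: build the nh_system of a 3-state scenario config
scenario_system <- function(params) {
  nh_system(params$labels, params$lam, params$gamma,
            params$a0_magnitude * exp(1i * params$a0_phase))
}

# internal: pick the evaluation time (max separation of top two outcomes)
pick_t_eval <- function(traj, times) {
  sep <- traj |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(sep = {
      p <- sort(.data$reported_p, decreasing = TRUE)
      p[1] - p[2]
    }, .groups = "drop")
  sep$time[which.max(sep$sep)]
}

# internal: ranking tibble at a given time, lexicographic tie-break
make_ranking <- function(traj, t_eval, tie_tol = 1e-9) {
  at_t <- traj |>
    dplyr::filter(.data$time == t_eval) |>
    dplyr::arrange(dplyr::desc(.data$reported_p), .data$state)
  out <- tibble::tibble(
    rank = seq_len(nrow(at_t)),
    state = at_t$state,
    probability = at_t$reported_p,
    raw_p = at_t$raw_p,
    t_eval = t_eval,
    tied_with_next = c(abs(diff(at_t$reported_p)) <= tie_tol, FALSE)
  )
  class(out) <- c("qranking", class(out))
  out
}

#' Run the Linda three-state collapse scenario
#'
#' Evolves the `(F, F&BT, BT)` system under the diagonal non-Hermitian
#' generator, computes interference-aware probabilities, and ranks the
#' outcomes at `t_eval` (default: the time on the grid maximizing the
#' separation between the top two reported probabilities, since "after
#' sufficient time" is otherwise unquantified). With the shipped defaults —
#' congruent branch decaying slowest — the ranking is `F, F&BT, BT`. Ties
#' are broken lexicographically by label and reported explicitly.
#'
#' @param cfg A `scenario_config` of kind `"linda_collapse"`.
#' @return A `qranking` tibble; the full trajectory is attached as
#'   `attr(, "trajectory")`.
#' @export
run_linda_collapse <- function(cfg = scenario_config("linda_collapse")) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$kind == "linda_collapse")
  p <- cfg$parameters
  sys <- scenario_system(p)
  times <- seq(0, p$t_max, length.out = p$n_steps)
  traj <- probabilities_with_interference(sys, times)
  t_eval <- if (is.null(p$t_eval)) pick_t_eval(traj, times) else p$t_eval
  ranking <- make_ranking(traj, t_eval)
  attr(ranking, "trajectory") <- traj
  ranking
}

#' Run the prisoner's-dilemma sure-thing-principle scenario
#'
#' Compares the cooperation probability of player A under three conditions:
#'
#' * **unknown** opponent — superposition of cooperate/defect, so
#'   `P(A_unknown) = |a1(t)|^2 + P(A&B)` (interference-boosted);
#' * **known cooperation** — the state collapses onto `|A>` and decays under
#'   its own rate with no interference: `P(A_cooperate) = |a1(t)|^2`;
#' * **known defection** — collapse dynamics favor `|B>`, i.e. the
#'   cooperation amplitude decays at the faster `gamma_defect`:
#'   `P(A_defect) = |a1(t)|^2` under that rate.
#'
#' The sure-thing-principle violation flag is
#' `P(A_unknown) > max(P(A_cooperate), P(A_defect))`; with the defaults the
#' ordering is unknown > cooperate > defect for every `t > 0`.
#'
#' @param cfg A `scenario_config` of kind `"prisoner_dilemma"`.
#' @return A `qranking` tibble over the three conditions with attributes
#'   `trajectory` (condition probabilities over time) and
#'   `sure_thing_violation` (logical).
#' @export
run_prisoner_dilemma <- function(cfg = scenario_config("prisoner_dilemma")) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$kind == "prisoner_dilemma")
  p <- cfg$parameters
  sys <- scenario_system(p)
  times <- seq(0, p$t_max, length.out = p$n_steps)
  traj3 <- probabilities_with_interference(sys, times)
  wide <- traj3 |>
    dplyr::select("time", "state", "raw_p") |>
    tidyr::pivot_wider(names_from = "state", values_from = "raw_p")
  p_conj <- pmax(wide[[p$labels[2]]], 0)
  p_a <- Mod(sys$a0[1])^2 * exp(-2 * sys$gamma[1] * times)
  p_a_defect <- Mod(sys$a0[1])^2 * exp(-2 * p$gamma_defect * times)
  cond <- tibble::tibble(
    time = rep(times, 3),
    state = rep(c("A_unknown", "A_cooperate", "A_defect"), each = length(times)),
    raw_p = c(p_a + p_conj, p_a, p_a_defect),
    reported_p = c(p_a + p_conj, p_a, p_a_defect)
  )
  t_eval <- if (is.null(p$t_eval)) {
    tt <- times[times > 0]
    sep <- vapply(tt, function(s) {
      v <- sort(cond$raw_p[cond$time == s], decreasing = TRUE)
      v[1] - v[2]
    }, numeric(1))
    tt[which.max(sep)]
  } else p$t_eval
  at_t <- cond |> dplyr::filter(.data$time == t_eval) |>
    dplyr::arrange(dplyr::desc(.data$raw_p), .data$state)
  ranking <- tibble::tibble(
    rank = seq_len(nrow(at_t)),
    state = at_t$state,
    probability = at_t$raw_p,
    raw_p = at_t$raw_p,
    t_eval = t_eval,
    tied_with_next = c(abs(diff(at_t$raw_p)) <= 1e-9, FALSE)
  )
  class(ranking) <- c("qranking", class(ranking))
  p_u <- at_t$raw_p[at_t$state == "A_unknown"]
  attr(ranking, "trajectory") <- cond
  attr(ranking, "sure_thing_violation") <-
    p_u > max(at_t$raw_p[at_t$state != "A_unknown"])
  ranking
}

#' Run a two-path probability-shift session
#'
#' Simulates a focused-intent two-outcome experiment: the focused-path
#' probability is shifted multiplicatively,
#' `p_shifted = baseline * (1 + eta * overlap_sq)`, and `n_trials` seeded
#' Bernoulli trials are drawn at that probability. Reports the analytic
#' shifted probability, the observed frequency, and the z-score of the
#' observed count against the *baseline* null. Fully deterministic given
#' `seed`.
#'
#' @param cfg A `scenario_config` of kind `"two_path_shift"`.
#' @return A one-row tibble: `baseline`, `eta`, `overlap_sq`, `p_shifted`,
#'   `n_trials`, `observed_freq`, `z_vs_baseline`, `seed`.
#' @export
run_two_path_shift <- function(cfg = scenario_config("two_path_shift")) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$kind == "two_path_shift")
  p <- cfg$parameters
  if (p$n_trials <= 0) qcog_abort("n_trials must be positive", "qcog_config_error")
  ctx <- observer_context_from_overlap(p$overlap_sq, p$eta)
  p_shifted <- modified_probability(p$baseline, ctx)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(p$seed)
  hits <- stats::rbinom(1, p$n_trials, p_shifted)
  obs <- hits / p$n_trials
  z <- (hits - p$n_trials * p$baseline) /
    sqrt(p$n_trials * p$baseline * (1 - p$baseline))
  tibble::tibble(baseline = p$baseline, eta = p$eta, overlap_sq = p$overlap_sq,
                 p_shifted = p_shifted, n_trials = p$n_trials,
                 observed_freq = obs, z_vs_baseline = z, seed = p$seed)
}

#' The worked Linda pipeline in one table
#'
#' Recomputes the five headline numbers of the two-angle Linda model with
#' the default configuration (theta 60 deg, phi 50 deg, shifts 5 and 2 deg,
#' eta 0.01, squared overlap 0.5): the single-event probability, the
#' conjunction probability, the perturbed angle difference, the exact
#' perturbed conjunction probability, the influence factor g, and the
#' combined probability.
#'
#' @param cfg A `scenario_config` of kind `"linda_qpt"`.
#' @return A tibble with columns `quantity`, `value`.
#' @export
#' @examples
#' worked_examples()
worked_examples <- function(cfg = scenario_config("linda_qpt")) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$kind == "linda_qpt")
  p <- cfg$parameters
  m <- angle_model(p$theta_deg, p$phi_deg, unit = "degrees")
  pert <- perturbation_params(p$delta_theta_deg, p$delta_phi_deg, unit = "degrees")
  ctx <- observer_context_from_overlap(p$overlap_sq, p$eta)
  tibble::tibble(
    quantity = c("p_single", "p_conjunction", "delta_prime_deg",
                 "p_conjunction_perturbed", "g_factor", "p_combined"),
    value = c(
      p_single(m),
      p_conjunction(m),
      (p$theta_deg + p$delta_theta_deg) - (p$phi_deg + p$delta_phi_deg),
      exact_perturbed_conjunction(m, pert),
      conscious_influence_factor(ctx),
      combined_conjunction_probability(m, pert, ctx)
    )
  )
}

#' Sweep a scenario parameter
#'
#' Re-runs the worked Linda pipeline across a grid of one scalar parameter
#' (e.g. `eta`) and returns the stacked results, one `worked_examples()`
#' table per value.
#'
#' @param param Name of a `linda_qpt` parameter.
#' @param values Numeric vector of values to sweep.
#' @param cfg Base configuration.
#' @return A tibble with columns `param`, `value_of_param`, `quantity`,
#'   `value`.
#' @export
sweep_parameter <- function(param, values, cfg = scenario_config("linda_qpt")) {
  stopifnot(param %in% names(cfg$parameters))
  purrr::map_dfr(values, function(v) {
    args <- stats::setNames(list(v), param)
    cfg2 <- do.call(scenario_config, c(list(kind = cfg$kind), utils::modifyList(cfg$parameters, args)))
    worked_examples(cfg2) |>
      dplyr::mutate(param = param, value_of_param = v, .before = 1)
  })
}
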