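# shared helpers for the suite: tiny constructors used across files

bf <- c("B", "F")

state_bf <- function(a, b) make_state(bf, c(a, b), normalize = TRUE)

# Linda worked-example configuration (angles in degrees as printed)
linda_model <- function() angle_model(60, 50, unit = "degrees")
linda_pert <- function() perturbation_params(5, 2, unit = "degrees")
linda_ctx <- function() observer_context_from_overlap(0.5, eta = 0.01)

# diagonal non-Hermitian system on n states with given rates
diag_system <- function(lam, gamma, a0 = NULL) {
  n <- length(lam)
  if (is.null(a0)) a0 <- rep(1, n) / sqrt(n)
  nh_system(paste0("s", seq_len(n)), lam, gamma, a0)
}

# generator matrix of a diagonal system, as a qop
diag_generator <- function(sys) {
  qop(diag(sys$lam - 1i * sys$gamma, length(sys$lam)), sys$labels)
}
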