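test_that("kraus instruments validate completeness", {
  labs <- c("B", "F")
  ident <- kraus_instrument(list(qop_identity(labs)))
  expect_s3_class(ident, "kraus_instrument")
  # projective instrument onto the basis is complete
  proj <- kraus_instrument(list(basis_projector(labs, "B"), basis_projector(labs, "F")))
  expect_s3_class(proj, "kraus_instrument")
  # a lone projector is not complete unless flagged subnormalized
  expect_error(kraus_instrument(list(basis_projector(labs, "B"))),
               class = "qcog_contract_error")
  sub <- kraus_instrument(list(basis_projector(labs, "B")), subnormalized = TRUE)
  expect_true(sub$subnormalized)
  # random CPTP fixtures satisfy sum K'K = I within 1e-8
  for (seed in 1:10) {
    inst <- generate_fixture("cptp", 3, seed = seed)
    comp <- Reduce(`+`, lapply(inst$operators,
                               function(k) Conj(t(k$matrix)) %*% k$matrix))
    expect_lt(max(Mod(comp - diag(3))), 1e-8)
  }
})

test_that("context channels preserve density-operator validity", {
  for (seed in 1:10) {
    psi <- generate_fixture("state", 3, seed = seed)
    rho <- density_from_state(psi)
    ctx <- context_map(generate_fixture("cptp", 3, seed = seed + 200))
    rho2 <- apply_context(rho, ctx)
    expect_true(is_hermitian(rho2, 1e-9))
    expect_true(is_positive_semidefinite(rho2, 1e-8))
    expect_equal(Re(sum(diag(rho2$matrix))), 1, tolerance = 1e-9)
  }
})

test_that("identity context reduces to the state unchanged; dephasing kills coherences", {
  rho <- density_from_state(state_bf(1, 1))
  expect_identical(apply_context(rho, identity_context(bf))$matrix, rho$matrix)

  dephase <- context_map(kraus_instrument(
    list(basis_projector(bf, "B"), basis_projector(bf, "F"))), "full dephasing")
  rho_d <- apply_context(rho, dephase)
  expect_equal(rho_d$matrix[1, 2], 0 + 0i)
  expect_equal(diag(rho_d$matrix), diag(rho$matrix), ignore_attr = TRUE)
})

test_that("contextual probabilities: Born consistency, completeness, spectral oracle", {
  # identity context on the Linda state: the worked 0.25
  rho <- density_from_state(belief_state(angle_model(pi / 3, 0)))
  probs <- contextual_probability(rho, list(basis_projector(bf, "B"),
                                            basis_projector(bf, "F")))
  expect_equal(probs[1], 0.25, tolerance = 1e-12)
  expect_equal(sum(probs), 1, tolerance = 1e-12)

  # identity context is bit-identical to the pure-state Born rule
  for (seed in 1:10) {
    psi <- generate_fixture("state", 3, seed = seed)
    u <- generate_fixture("unitary", 3, seed = seed + 300)
    projectors <- lapply(1:3, function(i) {
      projector_from_state(make_state(psi$labels, u$matrix[, i]))
    })
    expect_identical(
      contextual_probability(density_from_state(psi), projectors),
      vapply(projectors, function(p) born_probability(psi, p), numeric(1))
    )
  }

  # against an eigen-decomposition brute force under a random context
  for (seed in 1:5) {
    psi <- generate_fixture("state", 3, seed = seed + 21)
    rho <- density_from_state(psi)
    ctx <- context_map(generate_fixture("cptp", 3, seed = seed + 400))
    u <- generate_fixture("unitary", 3, seed = seed + 500)
    projectors <- lapply(1:3, function(i) {
      projector_from_state(make_state(psi$labels, u$matrix[, i]))
    })
    got <- contextual_probability(rho, projectors, ctx)
    rho2 <- apply_context(rho, ctx)$matrix
    es <- eigen(rho2)
    oracle <- vapply(projectors, function(p) {
      sum(vapply(seq_along(es$values), function(k) {
        v <- es$vectors[, k]
        Re(es$values[k]) * Re(Conj(v) %*% p$matrix %*% v)
      }, numeric(1)))
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_equal(sum(got), 1, tolerance = 1e-8)
  }

  # basis mismatch and incomplete projector sets are rejected
  rho_bf <- density_from_state(state_bf(1, 0))
  expect_error(contextual_probability(rho_bf,
                                      list(basis_projector(c("x", "y"), 1),
                                           basis_projector(c("x", "y"), 2))),
               class = "qcog_shape_error")
  expect_error(contextual_probability(rho_bf, list(basis_projector(bf, "B"))),
               class = "qcog_normalization_error")
})

test_that("instrument update reproduces textbook collapse and the worked value", {
  rho <- density_from_state(belief_state(angle_model(pi / 3, 0)))
  upd <- instrument_update(rho, basis_projector(bf, "B"))
  expect_equal(upd$probability, 0.25, tolerance = 1e-12)
  expect_equal(upd$state$matrix, basis_projector(bf, "B")$matrix,
               tolerance = 1e-12, ignore_attr = TRUE)

  # M = I: state unchanged, probability 1
  upd_i <- instrument_update(rho, qop_identity(bf))
  expect_equal(upd_i$probability, 1)
  expect_equal(upd_i$state$matrix, rho$matrix, tolerance = 1e-14, ignore_attr = TRUE)

  # zero-support outcome raises an explicit error, not NaN
  rho_b <- density_from_state(make_state(bf, c(1, 0)))
  expect_error(instrument_update(rho_b, basis_projector(bf, "F")),
               class = "qcog_zero_support_error")
})

test_that("averaging instrument posteriors recovers the channel (total probability)", {
  for (seed in 1:5) {
    psi <- generate_fixture("state", 3, seed = seed + 31)
    rho <- density_from_state(psi)
    inst <- generate_fixture("cptp", 3, seed = seed + 600, n_kraus = 3)
    mix <- matrix(0 + 0i, 3, 3)
    for (k in inst$operators) {
      up <- instrument_update(rho, k)
      mix <- mix + up$probability * up$state$matrix
    }
    chan <- apply_context(rho, context_map(inst))
    expect_equal(mix, chan$matrix, tolerance = 1e-9, ignore_attr = TRUE)
    probs <- vapply(inst$operators, function(k) instrument_update(rho, k)$probability,
                    numeric(1))
    expect_equal(sum(probs), 1, tolerance = 1e-8)
  }
})

test_that("context observables are unitary conjugations", {
  q <- qop(diag(c(1, -1)), bf)
  u <- generate_fixture("unitary", 2, seed = 9)
  u <- qop(u$matrix, bf)
  a_con <- context_observable(q, u)
  expect_true(is_hermitian(a_con, 1e-10))
  expect_equal(sort(Re(eigen(a_con$matrix, only.values = TRUE)$values)), c(-1, 1),
               tolerance = 1e-10)
  expect_error(context_observable(q, qop(matrix(c(1, 0, 0, 2), 2), bf)),
               class = "qcog_contract_error")
})

test_that("mixture update applies the printed (d+1)/d rule plus normalization", {
  # near-identity response in the large-d limit: q approaches p
  p <- c(0.2, 0.3, 0.5)
  r <- diag(3)
  upd <- qbist_mixture_update(p, r, d = 1e9)
  expect_equal(upd$q_literal, p, tolerance = 1e-8)

  # uniform p and r: literal output is uniform scaled by (d+1)/d
  d <- 4
  upd_u <- qbist_mixture_update(rep(1 / 4, 4), matrix(1 / 4, 4, 4), d = d)
  expect_equal(upd_u$q_literal, rep((d + 1) / d / 4, 4), tolerance = 1e-12)
  expect_equal(sum(upd_u$q_normalized), 1, tolerance = 1e-12)

  # normalized variant always sums to 1
  set.seed(5)
  for (k in 1:5) {
    p <- stats::runif(4); p <- p / sum(p)
    r <- matrix(stats::runif(16), 4); r <- r / rowSums(r)
    expect_equal(sum(qbist_mixture_update(p, r, 4)$q_normalized), 1, tolerance = 1e-12)
  }
  expect_error(qbist_mixture_update(c(0.5, 0.6), diag(2), 2),
               class = "qcog_contract_error")
})

test_that("collapse propagator absorbed into Kraus operators matches the engine", {
  # diagonal system: Tr(rho M_i' M_i) == |a_i(t)|^2 from the collapse module
  sys <- diag_system(c(0.9, 0.5, 0.2), c(0.1, 0.3, 0.7))
  h <- qop(diag(sys$lam, 3), sys$labels)
  gam <- qop(diag(sys$gamma, 3), sys$labels)
  rho <- density_from_state(make_state(sys$labels, sys$a0))
  for (t_end in c(0.5, 1.5, 3)) {
    inst <- collapse_instrument(h, gam, t_end)
    probs <- vapply(inst$operators, function(m) {
      Re(sum(diag(Conj(t(m$matrix)) %*% m$matrix %*% rho$matrix)))
    }, numeric(1))
    an <- analytic_amplitudes(sys, t_end)
    expect_equal(probs, an$raw_p, tolerance = 1e-10)
  }

  # non-commuting case: instrument equals projector slices of the propagator,
  # so probabilities match the evolve() engine populations
  h2 <- generate_fixture("hermitian", 3, seed = 77)
  g2 <- generate_fixture("psd", 3, seed = 78)
  g2 <- qop(g2$matrix, h2$labels)
  psi <- generate_fixture("state", 3, seed = 79)
  psi <- make_state(h2$labels, psi$amplitudes)
  inst <- collapse_instrument(h2, g2, 1.2)
  probs <- vapply(inst$operators, function(m) {
    rho <- density_from_state(psi)
    Re(sum(diag(Conj(t(m$matrix)) %*% m$matrix %*% rho$matrix)))
  }, numeric(1))
  ev <- evolve(qop(h2$matrix - 1i * g2$matrix, h2$labels), psi, 1.2)
  expect_equal(probs, ev$raw_p, tolerance = 1e-9)
})
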