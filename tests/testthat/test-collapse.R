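test_that("complex matrix exponential matches an eigendecomposition oracle", {
  for (seed in 1:10) {
    h <- generate_fixture("hermitian", 4, seed = seed)
    g <- generate_fixture("psd", 4, seed = seed + 100)
    m <- -1i * (h$matrix - 1i * g$matrix)
    es <- eigen(m)              # independent oracle: V exp(D) V^-1
    oracle <- es$vectors %*% diag(exp(es$values)) %*% solve(es$vectors)
    expect_equal(expm_c(m), oracle, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # large-norm scaling path
  big <- 50 * generate_fixture("hermitian", 3, seed = 7)$matrix
  es <- eigen(big, symmetric = TRUE)
  oracle <- es$vectors %*% diag(exp(es$values)) %*% Conj(t(es$vectors))
  expect_equal(expm_c(big), oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("total Hamiltonian assembles with the collapse term in the right slot", {
  labs_s <- c("F", "BT")
  labs_o <- c("o1", "o2")
  h_sys <- qop(diag(c(0.4, 0.9)), labs_s)
  gam <- qop(diag(c(0, 0.3)), labs_s)
  h_obs <- qop(diag(c(0.1, 0.2)), labs_o)

  # unitary limit: Gamma = 0, H_int = 0 gives a Hermitian total
  tot0 <- build_total_hamiltonian(h_sys, qop(diag(0, 2), labs_s), h_obs)
  expect_true(is_hermitian(tot0))

  # all-diagonal inputs: entries are (lam_i - 1i*gamma_i) + mu_j
  tot <- build_total_hamiltonian(h_sys, gam, h_obs)
  d <- diag(tot$matrix)
  expected <- as.vector(t(outer(c(0.4, 0.9 - 0.3i), c(0.1, 0.2), `+`)))
  expect_equal(d, expected, ignore_attr = TRUE, tolerance = 1e-15)

  # anti-Hermitian part is exactly -1i * (Gamma (x) I) for random PSD Gamma
  for (seed in 1:5) {
    h <- generate_fixture("hermitian", 3, seed = seed)
    g <- generate_fixture("psd", 3, seed = seed + 10)
    ho <- generate_fixture("hermitian", 2, seed = seed + 20)
    g <- qop(g$matrix, h$labels)
    tot <- build_total_hamiltonian(h, g, ho)
    anti <- (tot$matrix - Conj(t(tot$matrix))) / 2
    expect_equal(anti, -1i * kronecker(g$matrix, diag(2)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  bad_gamma <- qop(diag(c(-0.1, 0.2)), labs_s)
  expect_error(build_total_hamiltonian(h_sys, bad_gamma, h_obs),
               class = "qcog_contract_error")
})

test_that("targeted collapse operator protects the target and drives it to 1", {
  expect_equal(diag(build_targeted_collapse_operator(2, 1, 1)$matrix),
               c(0, 1) + 0i, ignore_attr = TRUE)
  expect_equal(diag(build_targeted_collapse_operator(3, 3, 0.5)$matrix),
               c(0.5, 0.5, 0) + 0i, ignore_attr = TRUE)
  expect_true(is_positive_semidefinite(build_targeted_collapse_operator(4, 2, 0.3)))
  expect_error(build_targeted_collapse_operator(3, 5, 1), class = "qcog_shape_error")

  # evolution under -1i*Gamma alone: reported target probability -> 1
  gam <- build_targeted_collapse_operator(3, 2, 1.2)
  psi0 <- make_state(gam$labels, c(1, 1, 1), normalize = TRUE)
  h <- qop(-1i * gam$matrix, gam$labels)
  res <- evolve(h, psi0, c(0, 20))
  final <- res[res$time == 20, ]
  expect_equal(final$reported_p[final$state == gam$labels[2]], 1, tolerance = 1e-8)
})

test_that("analytic amplitudes follow the closed form and the expm oracle", {
  # lam = gamma = 0: amplitudes constant
  sys0 <- diag_system(c(0, 0), c(0, 0))
  r0 <- analytic_amplitudes(sys0, c(0, 1, 5))
  expect_true(all(Mod(r0$amplitude - rep(sys0$a0, each = 3)) < 1e-14))

  # gamma = 1, t = ln 2: magnitudes halve
  sys1 <- diag_system(c(0.3, 0.8), c(1, 1))
  r1 <- analytic_amplitudes(sys1, log(2))
  expect_equal(Mod(r1$amplitude), Mod(sys1$a0) / 2, tolerance = 1e-12)

  # random diagonal systems: closed form == matrix-exponential evolution to 1e-10
  set.seed(11)
  for (k in 1:25) {
    n <- sample(2:4, 1)
    sys <- diag_system(stats::runif(n, -1, 1), stats::runif(n, 0, 1))
    times <- c(0, sort(stats::runif(3, 0, 4)))
    an <- analytic_amplitudes(sys, times)
    ex <- evolve(diag_generator(sys),
                 make_state(sys$labels, sys$a0), times)
    expect_equal(an$amplitude, ex$amplitude, tolerance = 1e-10)
    expect_equal(an$raw_p, ex$raw_p, tolerance = 1e-10)
  }
})

test_that("evolve conserves norm for Hermitian generators and is identity at H = 0", {
  psi0 <- generate_fixture("state", 3, seed = 3)
  flat <- qop(matrix(0, 3, 3), psi0$labels)
  res <- evolve(flat, psi0, c(0, 2, 7))
  expect_true(all(Mod(res$amplitude - rep(psi0$amplitudes, each = 3)) < 1e-14))

  for (seed in 1:10) {
    h <- generate_fixture("hermitian", 4, seed = seed)
    psi <- generate_fixture("state", 4, seed = seed + 500)
    psi <- make_state(h$labels, psi$amplitudes)
    res <- evolve(h, psi, seq(0, 5, length.out = 6))
    expect_true(all(abs(res$norm - 1) < 1e-9))
  }
})

test_that("norm decays monotonically when the anti-Hermitian part is -1i*Gamma (PSD)", {
  for (seed in 1:20) {
    h <- generate_fixture("hermitian", 3, seed = seed)
    g <- generate_fixture("psd", 3, seed = seed + 40)
    gen <- qop(h$matrix - 1i * g$matrix, h$labels)
    psi <- generate_fixture("state", 3, seed = seed + 80)
    psi <- make_state(h$labels, psi$amplitudes)
    res <- evolve(gen, psi, seq(0, 3, length.out = 8))
    norms <- unique(tibble::tibble(t = res$time, n = res$norm))$n
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("decay is irreversible: no later time reproduces the initial distribution", {
  sys <- diag_system(c(0.5, 0.2, 0.1), c(0.05, 0.2, 0.6))
  res <- analytic_amplitudes(sys, seq(0.1, 8, length.out = 40))
  p0 <- Mod(sys$a0)^2
  by_time <- split(res$reported_p, res$time)
  revisits <- vapply(by_time, function(p) max(abs(p - p0)) < 1e-6, logical(1))
  expect_false(any(revisits))
})

test_that("conjunction amplitude combines branches with interference", {
  expect_equal(conjunction_amplitude(1 / sqrt(2) + 0i, 1 / sqrt(2) + 0i), 1 + 0i,
               tolerance = 1e-15)
  expect_equal(conjunction_amplitude(0.3 + 0.1i, -0.3 - 0.1i), 0 + 0i)
  set.seed(4)
  for (k in 1:20) {
    a1 <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
    a3 <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
    lhs <- Mod(conjunction_amplitude(a1, a3))^2
    rhs <- (Mod(a1)^2 + Mod(a3)^2 + 2 * Re(a1 * Conj(a3))) / 2
    expect_lt(abs(lhs - rhs), 1e-12)
  }
})

test_that("interference probabilities reproduce the three-state model algebra", {
  labs <- c("F", "F&BT", "BT")
  # t = 0, equal branches, no dynamics: full constructive interference
  sys <- nh_system(labs, c(0, 0, 0), c(0, 0, 0), c(1, 0, 1) / sqrt(2))
  r <- probabilities_with_interference(sys, 0)
  expect_equal(r$raw_p[r$state == "F&BT"], 1, tolerance = 1e-12)
  # P(BT) subtraction: raw can be negative, reported clamps to zero
  expect_equal(r$raw_p[r$state == "BT"], 0.5 - 1, tolerance = 1e-12)
  expect_equal(r$reported_p[r$state == "BT"], 0)
  expect_equal(sum(r$reported_p), 1, tolerance = 1e-12)

  # dlam = dgam = 0: cross term is a pure e^{-2 gamma t} envelope
  sys_eq <- nh_system(labs, c(0.4, 0.4, 0.4), c(0.3, 0.3, 0.3), c(1, 0, 1) / sqrt(2))
  times <- seq(0, 3, length.out = 7)
  r_eq <- probabilities_with_interference(sys_eq, times)
  p_conj <- r_eq$raw_p[r_eq$state == "F&BT"]
  a0 <- sys_eq$a0
  envelope <- (Mod(a0[1])^2 + Mod(a0[3])^2 + 2 * Re(a0[1] * Conj(a0[3]))) / 2 *
    exp(-2 * 0.3 * times)
  expect_equal(p_conj, envelope, tolerance = 1e-12)

  # asymmetric decay: the slow branch dominates at long times
  sys_as <- nh_system(labs, c(1, 0.6, 0.3), c(0.05, 0.15, 0.4), c(1, 0, 1) / sqrt(2))
  r_as <- probabilities_with_interference(sys_as, 12)
  expect_gt(r_as$raw_p[r_as$state == "F"], r_as$raw_p[r_as$state == "F&BT"])
  expect_gt(r_as$raw_p[r_as$state == "F"], r_as$raw_p[r_as$state == "BT"])
})

test_that("zeno suppression ratio is 1 at gamma 0, decreasing in gamma, -> 0", {
  mk <- function(g) nh_system(c("a", "b", "c"), c(0, 0, 0), c(0, g, g),
                              c(1, 1, 1) / sqrt(3))
  expect_equal(zeno_suppression_ratio(mk(0), 2), 1)
  expect_lt(zeno_suppression_ratio(mk(2), 2), zeno_suppression_ratio(mk(1), 2))
  expect_lt(zeno_suppression_ratio(mk(5), 20), 1e-8)
})
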