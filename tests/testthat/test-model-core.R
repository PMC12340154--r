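# Core stochastic model: transfer function, drift field, OU couplings and
# the Euler-Maruyama integrator.

test_that("transfer function is continuous through its removable singularity", {
  a <- 270; b <- 108; d <- 0.154
  # at a x = b the limit is 1/d
  expect_equal(transfer_function(b / a, a = a, b = b, d = d), 1 / d,
               tolerance = 1e-9)
  # approaching from both sides converges to the same value
  eps <- 10^-(4:8)
  left <- transfer_function(b / a - eps, a = a, b = b, d = d)
  right <- transfer_function(b / a + eps, a = a, b = b, d = d)
  expect_equal(tail(left, 1), 1 / d, tolerance = 1e-6)
  expect_equal(tail(right, 1), 1 / d, tolerance = 1e-6)
  # far above threshold the exponential vanishes: H ~ a x - b
  expect_equal(transfer_function(1, a = a, b = b, d = d), a * 1 - b,
               tolerance = 1e-6)
  # at zero input the rate is effectively zero
  expect_lt(transfer_function(0, a = a, b = b, d = d), 1e-4)
  expect_gt(transfer_function(0, a = a, b = b, d = d), 0)
  expect_error(transfer_function(Inf), "finite")
  expect_error(transfer_function(c(0.1, NA)), "finite")
})

test_that("drift field matches its closed form and symmetry", {
  p <- two_region_static_params(0)
  # S = 0, all couplings 0: dS/dt = gamma * H(I_0) for every region
  expect_equal(drift_field(c(0, 0), matrix(0, 2, 2), p),
               rep(p$gamma * transfer_function(p$I_0, p), 2))
  expect_true(all(drift_field(c(0, 0), matrix(0, 2, 2), p) >= 0))
  # symmetric configuration gives symmetric drift
  p2 <- two_region_static_params(0.3)
  d <- drift_field(c(0.4, 0.4), p2$C, p2)
  expect_equal(d[1], d[2])
  expect_error(drift_field(c(0.1, 0.2, 0.3), matrix(0, 2, 2), p),
               "dimension mismatch")
})

test_that("drift field vanishes at located equilibria", {
  p <- bistable_two_region_params()
  eq <- find_equilibria(p)
  for (i in seq_len(nrow(eq))) {
    expect_lt(max(abs(drift_field(as.numeric(eq[i, 1:2]), p$C, p))), 1e-8)
  }
})

test_that("OU step keeps set point, relaxes exponentially, and has the right stationary moments", {
  # eta = 0, sigma = 0: invariant
  x <- 0.3
  for (i in 1:100) x <- step_ou(x, 0.2, 0, 0, 0.01)
  expect_identical(x, 0.3)
  # deterministic relaxation: c(t) = C + (c0 - C) exp(-eta t)
  x <- 0.5; dt <- 1e-3
  for (i in seq_len(20 / dt)) x <- step_ou(x, 0.2, 0.05, 0, dt, noise_draw = 0)
  expect_equal(x, 0.2 + 0.3 * exp(-1), tolerance = 1e-3)
  # stationary variance sigma^2 / (2 eta) within 10%
  eta <- 0.05; sig <- 0.25; dt <- 0.01
  n_steps <- 4000 / dt   # 200 / eta seconds
  set.seed(42)
  draws <- rnorm(n_steps)
  ch <- numeric(n_steps); x <- 0.2
  for (i in seq_len(n_steps)) {
    x <- step_ou(x, 0.2, eta, sig, dt, noise_draw = draws[i])
    ch[i] <- x
  }
  expect_equal(var(ch), sig^2 / (2 * eta), tolerance = 0.1)
  expect_error(step_ou(0.1, 0.1, -0.1, 0.1, 0.01), "eta")
  expect_error(step_ou(0.1, 0.1, 0.1, -0.1, 0.01), "sigma")
  expect_error(step_ou(0.1, 0.1, 0.1, 0.1, 0), "dt")
})

test_that("simulation is seed-deterministic and stays on a stable equilibrium without noise", {
  p <- bistable_two_region_params()
  cfg <- simulation_config(dt = 1e-3, duration = 30, burn_in = 5, seed = 7)
  a <- simulate_circuit(p, config = cfg)
  b <- simulate_circuit(p, config = cfg)
  expect_identical(a$S, b$S)
  expect_identical(a$C_tilde, b$C_tilde)

  # noise-free start on a stable equilibrium stays there
  pq <- bistable_two_region_params(sigma_coupling = 0, sigma_node = 0)
  eq <- find_equilibria(pq)
  s_star <- as.numeric(eq[eq$stable, 1:2][1, ])
  cfg0 <- simulation_config(dt = 1e-3, duration = 10, burn_in = 0, seed = 1)
  tr <- simulate_circuit(pq, config = cfg0, S0 = s_star)
  expect_lt(max(abs(sweep(tr$S, 2, s_star))), 1e-6)
})

test_that("gating stays in [0, 1] and noise occupies both bistable branches", {
  p <- bistable_two_region_params()
  cfg <- simulation_config(dt = 1e-3, duration = 300, burn_in = 20, seed = 3)
  tr <- simulate_circuit(p, config = cfg)
  expect_true(all(tr$S >= 0 & tr$S <= 1))
  # bimodality: both low and high branches visited for a meaningful fraction
  frac_high <- mean(tr$S[, 1] > 0.5)
  expect_gt(frac_high, 0.05)
  expect_lt(frac_high, 0.95)
})

test_that("halving the step under a shared noise path barely changes the trajectory", {
  p <- bistable_two_region_params()
  dt <- 2e-3; duration <- 60
  n_coarse <- round(duration / dt)
  set.seed(99)
  path <- matrix(rnorm(n_coarse * 3), n_coarse, 3)  # 2 regions + 1 dyn edge
  cfg1 <- simulation_config(dt = dt, duration = duration, burn_in = 10,
                            record_dt = 0.01)
  cfg2 <- simulation_config(dt = dt / 2, duration = duration, burn_in = 10,
                            record_dt = 0.01)
  tr1 <- simulate_circuit(p, config = cfg1, noise_path = path, refine = 1L)
  tr2 <- simulate_circuit(p, config = cfg2, noise_path = path, refine = 2L)
  m1 <- colMeans(tr1$S); m2 <- colMeans(tr2$S)
  expect_lt(max(abs(m1 - m2) / pmax(abs(m1), 1e-3)), 0.01)
})

test_that("zero volatility reduces to the static-coupling model", {
  # with sigma_12 = 0 (and eta > 0) the dynamic coupling relaxes to its mean,
  # so long-run statistics match the static model within Monte-Carlo error
  topo_dyn <- two_region_topology(dynamic = TRUE)
  topo_sta <- two_region_topology(dynamic = FALSE)
  p_dyn <- model_parameters(topo_dyn, C = c(C_12 = 0.05, C_21 = 0.3),
                            eta = c(C_12 = 0.05), sigma_coupling = c(C_12 = 0))
  p_sta <- model_parameters(topo_sta, C = c(C_12 = 0.05, C_21 = 0.3))
  cfg <- function(seed) simulation_config(dt = 1e-3, duration = 120,
                                          burn_in = 20, seed = seed)
  m_dyn <- colMeans(simulate_circuit(p_dyn, config = cfg(5))$S)
  m_sta <- colMeans(simulate_circuit(p_sta, config = cfg(5))$S)
  expect_equal(m_dyn, m_sta, tolerance = 0.05)
})
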