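# Deterministic skeleton analysis and stochastic regime maps.

test_that("equilibrium finder matches the brute-force sign-change scan", {
  cases <- list(
    list(c12 = -0.3, c21 = 0.0, n_eq = 1, n_stable = 1),   # inhibition
    list(c12 = 0.25, c21 = 0.25, n_eq = 3, n_stable = 2),  # bistable window
    list(c12 = 0.45, c21 = 0.45, n_eq = 1, n_stable = 1)   # strong excitation
  )
  for (cs in cases) {
    p <- two_region_static_params(cs$c12, cs$c21)
    eq <- find_equilibria(p)
    expect_equal(nrow(eq), cs$n_eq)
    expect_equal(sum(eq$stable), cs$n_stable)
    expect_equal(brute_force_equilibria_2d(p), cs$n_eq)
    expect_true(all(eq$residual < 1e-8))
  }
})

test_that("regimes are classified as in the single-circuit stability analysis", {
  expect_equal(classify_regime(two_region_static_params(-0.3, 0)),
               "monostable-low")
  expect_equal(classify_regime(two_region_static_params(0.45)),
               "monostable-high")
  expect_equal(classify_regime(two_region_static_params(0.25)), "bistable")
})

test_that("coupling sweep finds exactly two saddle-node folds around the bistable window", {
  p <- two_region_static_params(0.25)
  bs <- bifurcation_scan(p, edge = "C_12", grid = seq(-0.5, 0.5, by = 0.05))
  expect_equal(nrow(bs$folds), 2)
  expect_equal(sum(abs(bs$folds$count_change)), 4)  # enter and leave: +2, -2
  # counts change only at the folds; stable branch varies continuously
  expect_true(all(bs$counts %in% c(1, 3)))
  inside <- bs$grid > max(bs$folds$location[1], min(bs$grid)) &
    bs$grid < bs$folds$location[2]
  expect_true(all(bs$counts[inside][-1] == 3 | !inside[inside][-1]))
  # monostable configuration: no folds anywhere in the sweep
  p_mono <- two_region_static_params(0.25, 0)
  bs0 <- bifurcation_scan(p_mono, edge = "C_12",
                          grid = seq(-0.5, 0.05, by = 0.05))
  expect_equal(nrow(bs0$folds), 0)
})

test_that("stable branches vary continuously between folds", {
  p <- two_region_static_params(0.25)
  bs <- bifurcation_scan(p, edge = "C_12", grid = seq(0.1, 0.45, by = 0.01))
  low_branch <- vapply(bs$equilibria, function(eq) {
    st <- eq[eq$stable, , drop = FALSE]
    min(st$S_Frontal)
  }, numeric(1))
  expect_lt(max(abs(diff(low_branch))), 0.05)
})

test_that("transition rate counts genuine sign reversals per minute", {
  expect_equal(transition_rate(rep(2.5, 1000), 0.1), 0)
  # sinusoid: two crossings per period
  t <- seq(0, 60, by = 1e-3)
  r <- transition_rate(sin(2 * pi * t), 1e-3)
  expect_equal(r, 120, tolerance = 0.02)
  # alternating signs at 1 Hz for 60 s: 59 changes in 60 samples
  expect_equal(transition_rate(rep(c(1, -1), 30), 1), 59)
  # zeros inherit the previous sign: +1, 0, -1 is one crossing, not two
  # (4 samples at 15 s spacing span one minute)
  expect_equal(transition_rate(c(1, 0, -1, -1), 15), 1)
  expect_warning(r0 <- transition_rate(rep(0, 10), 1), "constant-zero")
  expect_equal(r0, 0)
  expect_error(transition_rate(1, 1), "at least 2")
})

test_that("noise maps: constant coupling never crosses zero and transitions grow with drift and volatility", {
  p <- bistable_two_region_params()
  maps <- sweep_noise_maps(p, eta_grid = c(0.05, 0.1),
                           sigma_grid = c(0, 0.2, 0.4),
                           config = simulation_config(dt = 1e-3,
                                                      duration = 140,
                                                      burn_in = 20),
                           seed = 21)
  # zero volatility: constant coupling, no zero crossings
  expect_true(all(maps$rate[, 1] == 0))
  expect_true(all(is.finite(maps$fc)) && all(abs(maps$fc) <= 1))
  # transition rate increases along the jointly increasing diagonal
  expect_true(all(diff(c(maps$rate[1, 1], maps$rate[1, 2], maps$rate[2, 3])) > 0))
})
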