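# Digital-twin pairing and the symptom-association analyses.

test_that("twin pairing is an exact nearest-neighbour search with index tie-breaks", {
  set.seed(1)
  lib <- matrix(runif(60, -1, 1), 10, 6)
  theta <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  subj <- lib[4, , drop = FALSE]
  tp <- pair_twins(subj, lib, theta)
  expect_equal(tp$pairs$sim_index, 4)
  expect_equal(tp$pairs$distance, 0)
  expect_equal(tp$theta[1, ], theta[4, ])

  # brute-force oracle on random subjects
  subs <- matrix(runif(30, -1, 1), 5, 6)
  tp2 <- pair_twins(subs, lib)
  for (i in 1:5) {
    d <- apply(lib, 1, function(r) sqrt(sum((r - subs[i, ])^2)))
    expect_equal(tp2$pairs$sim_index[i], which.min(d))
    expect_equal(tp2$pairs$distance[i], min(d))
  }

  # duplicated nearest entries: lowest index wins
  lib_dup <- rbind(lib, lib[4, ])
  tp3 <- pair_twins(subj, lib_dup)
  expect_equal(tp3$pairs$sim_index, 4)
  expect_error(pair_twins(subj, lib[0, ]), "empty")
})

test_that("pairing is idempotent and growing the library never hurts", {
  set.seed(2)
  lib_small <- matrix(runif(120, -1, 1), 20, 6)
  lib_big <- rbind(lib_small, matrix(runif(120, -1, 1), 20, 6))
  subs <- matrix(runif(48, -1, 1), 8, 6)
  d_small <- pair_twins(subs, lib_small)$pairs$distance
  d_big <- pair_twins(subs, lib_big)$pairs$distance
  expect_true(all(d_big <= d_small + 1e-12))
  # a subject already at distance 0 keeps its twin
  hit <- pair_twins(lib_small[7, , drop = FALSE], lib_small)
  expect_equal(hit$pairs$sim_index, 1 * 7)
  expect_equal(pair_twins(lib_small[hit$pairs$sim_index, , drop = FALSE],
                          lib_small)$pairs$sim_index, 7)
})

test_that("twin parameter changes are tested by a paired signed-rank that matches brute force", {
  set.seed(3)
  lib <- matrix(runif(600, -1, 1), 100, 6)
  theta <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  subs <- matrix(runif(60, -1, 1), 10, 6)
  pre <- pair_twins(subs, lib, theta)
  # identical sessions: all-zero change, reported as no-change
  ch0 <- twin_parameter_change(pre, pre)
  expect_true(all(ch0$delta == 0))
  expect_true(all(ch0$tests$no_change))

  # signed-rank statistic equals the brute-force computation (n <= 10)
  subs_post <- subs + matrix(rnorm(60, 0, 0.2), 10, 6)
  post <- pair_twins(subs_post, lib, theta)
  ch <- twin_parameter_change(pre, post)
  for (p in c("a", "b", "c")) {
    expect_equal(ch$tests$V[ch$tests$parameter == p],
                 brute_force_signed_rank(ch$delta[, p]))
  }
})

test_that("a planted uniform parameter shift is detected in the twins", {
  set.seed(4)
  n_lib <- 4000; n_sub <- 48
  theta <- cbind(a = runif(n_lib, -0.5, 0.5), b = runif(n_lib, -0.5, 0.5),
                 c = runif(n_lib, -0.5, 0.5))
  # FC library depends monotonically on the parameters
  lib <- cbind(theta[, "a"], 0.5 * theta[, "b"], 0.3 * theta[, "c"],
               0.2 * theta[, "a"] + 0.1 * theta[, "b"],
               0.4 * theta[, "c"], 0.25 * theta[, "b"]) +
    matrix(rnorm(n_lib * 6, 0, 0.01), n_lib)
  th_true <- cbind(a = runif(n_sub, -0.3, 0.2), b = runif(n_sub, -0.25, 0.25),
                   c = runif(n_sub, -0.25, 0.25))
  mkfc <- function(th) cbind(th[, "a"], 0.5 * th[, "b"], 0.3 * th[, "c"],
                             0.2 * th[, "a"] + 0.1 * th[, "b"],
                             0.4 * th[, "c"], 0.25 * th[, "b"])
  th_post <- th_true; th_post[, "a"] <- th_post[, "a"] + 0.1
  pre <- pair_twins(mkfc(th_true), lib, theta)
  post <- pair_twins(mkfc(th_post), lib, theta)
  ch <- twin_parameter_change(pre, post)
  p_a <- ch$tests$p_fwe[ch$tests$parameter == "a"]
  p_other <- ch$tests$p_fwe[ch$tests$parameter != "a"]
  expect_lt(p_a, 0.05)
  expect_true(all(p_other > 0.05))
  expect_gt(ch$tests$median_delta[ch$tests$parameter == "a"], 0.05)
})

test_that("symptom association is an uncentred per-parameter dot product", {
  dz <- matrix(c(1, 1, 1, -1, 0.5, 2), 2, 3,
               dimnames = list(NULL, c("p", "q", "r")))
  dy <- c(1, 1)
  got <- symptom_association(dz, dy)
  expect_equal(unname(got["p"]), 2)
  expect_equal(unname(got["q"]), 0)
  dz2 <- matrix(c(0.5, 2), 2, 1, dimnames = list(NULL, "s"))
  expect_equal(unname(symptom_association(dz2, c(2, 1))), 3)
  expect_error(symptom_association(dz, c(1, 2, 3)), "mismatch")
})

test_that("FC-symptom correlation reports r, p and a bootstrap CI", {
  x <- seq(-1, 1, length.out = 20)
  res <- fc_symptom_correlation(x, 3 * x + 2, n_boot = 200, seed = 1)
  expect_equal(res$r, 1)
  # affine rescaling leaves r unchanged
  res2 <- fc_symptom_correlation(10 * x - 4, 3 * x + 2, n_boot = 200, seed = 1)
  expect_equal(res2$r, res$r)
  # planted correlation 0.35 at n = 48: estimate covered by the bootstrap CI
  # in nearly all seeded replicates
  cover <- 0
  for (s in 1:10) {
    set.seed(s)
    u <- rnorm(48)
    y <- generate_longitudinal_symptoms(u, target_r = 0.35, seed = s + 100)
    res3 <- fc_symptom_correlation(u, y, n_boot = 400, seed = s)
    cover <- cover + (res3$ci[1] <= 0.35 && 0.35 <= res3$ci[2])
  }
  expect_gte(cover, 9)
  expect_error(fc_symptom_correlation(rep(1, 10), rnorm(10)), "variance")
})
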