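# Virtual-intervention enumeration, cohort machinery, AUC scoring and
# contribution analysis.

test_that("intervention enumeration matches the binomial sums", {
  p11 <- paste0("p", 1:11)
  ivs <- enumerate_interventions(p11, 6)
  expect_length(ivs, sum(choose(11, 1:6)))
  expect_length(ivs, 1485)
  expect_length(enumerate_interventions(p11, 1), 11)
  expect_length(enumerate_interventions(c("a", "b", "c"), 2), 6)
  # closed-form count holds across (p, k)
  for (p in c(4, 7, 12)) {
    for (k in c(1, 3, min(p, 6))) {
      expect_length(enumerate_interventions(paste0("x", seq_len(p)), k),
                    sum(choose(p, seq_len(k))))
    }
  }
  # deterministic order: by size then lexicographic
  expect_equal(ivs[[1]], "p1")
  sizes <- lengths(ivs)
  expect_true(!is.unsorted(sizes))
  expect_error(enumerate_interventions(character(0)), "empty")
  expect_error(enumerate_interventions(c("a", "b"), 3), "exceed")
})

test_that("virtual cohorts partition subjects disjointly with the configured sizes", {
  topo <- canonical_topology()
  priors <- canonical_priors(topo)
  ens <- posterior_ensemble(sample_prior(priors, 200, seed = 1), priors)
  runner <- linear_fc_runner()
  cohorts <- build_virtual_cohorts(ens, function(th, sd) runner(th, sd),
                                   n_subjects = 100, cohort_size = 50,
                                   seed = 2)
  expect_length(cohorts, 2)
  expect_true(all(vapply(cohorts, function(co) nrow(co$fc), integer(1)) == 50))
  ids <- unlist(lapply(cohorts, `[[`, "subject_ids"))
  expect_false(anyDuplicated(ids) > 0)
  expect_length(ids, 100)
  expect_error(build_virtual_cohorts(ens, runner, 101, 50, seed = 1),
               "divisible")
})

test_that("applying an intervention draws targets from the control posterior", {
  topo <- canonical_topology()
  priors <- canonical_priors(topo)
  # separate the groups sharply on C_OA so provenance is visible
  th_ocd <- sample_prior(priors, 300, seed = 3)
  th_hc <- sample_prior(priors, 300, seed = 4)
  th_ocd[, "C_OA"] <- runif(300, 0.3, 0.5)
  th_hc[, "C_OA"] <- runif(300, -0.5, -0.3)
  ocd <- posterior_ensemble(th_ocd, priors)
  hc <- posterior_ensemble(th_hc, priors)
  runner <- linear_fc_runner()
  post <- apply_intervention(ocd, hc, "C_OA", function(th, sd) runner(th, sd),
                            n_subjects = 40, cohort_size = 20, seed = 5)
  post_coa <- do.call(rbind, lapply(post, `[[`, "theta"))[, "C_OA"]
  expect_true(all(post_coa < 0))  # drawn from the control side
  # non-targeted parameters stay within the patient ensemble's support
  post_cao <- do.call(rbind, lapply(post, `[[`, "theta"))[, "C_AO"]
  rng <- range(th_ocd[, "C_AO"])
  bw <- 4 * ocd$bandwidths[["C_AO"]]
  expect_true(all(post_cao > rng[1] - bw & post_cao < rng[2] + bw))
  expect_error(apply_intervention(ocd, hc, character(0), runner, 40, 20),
               "at least one")
  expect_error(apply_intervention(ocd, hc, "nope", runner, 40, 20), "absent")
})

test_that("intervention outcomes scale the U statistic into an AUC with half ties", {
  labs <- canonical_edge_order(c("OFC", "LPFC", "NAcc", "dPut"))
  mk <- function(shift, n = 3, seed = 1) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      fc_cohort(matrix(runif(30, -0.2, 0.2) + shift, 5, 6,
                       dimnames = list(NULL, labs)), paste0("c", i))
    })
  }
  hc <- mk(0, seed = 1)
  ocd_far <- mk(0.8, seed = 2)
  post_near <- mk(0.05, seed = 3)
  oc <- intervention_outcome(post_near, ocd_far, hc)
  expect_equal(oc$n1, 9)  # 3 x 3 cohort pairs
  expect_equal(oc$auc, 1)  # every post distance below every baseline distance
  expect_lt(oc$p, 0.01)
  # identical post and baseline: AUC = 0.5
  oc2 <- intervention_outcome(ocd_far, ocd_far, hc)
  expect_equal(oc2$auc, 0.5)
  expect_error(intervention_outcome(post_near[1], ocd_far, hc), "at least 2")
})

test_that("AUC equals brute-force pair counting, including ties", {
  # hand example: post = [1, 2], baseline = [2, 3] -> U = 3.5, AUC = 0.875
  expect_equal(brute_force_auc_less(c(1, 2), c(2, 3)), 0.875)
  set.seed(20)
  for (rep in 1:10) {
    x <- sample(1:6, sample(3:50, 1), replace = TRUE)
    y <- sample(1:6, sample(3:50, 1), replace = TRUE)
    expect_equal(fsdyn:::auc_less(x, y), brute_force_auc_less(x, y))
  }
})

test_that("null statistics sit near 0.5 for exchangeable cohort sets", {
  topo <- canonical_topology()
  priors <- canonical_priors(topo)
  ens <- posterior_ensemble(sample_prior(priors, 300, seed = 6), priors)
  runner <- linear_fc_runner()
  mk <- function(seed) build_virtual_cohorts(ens, function(th, sd) runner(th, sd),
                                             n_subjects = 200, cohort_size = 20,
                                             seed = seed)
  hc_a <- mk(11); hc_b <- mk(12); ocd_a <- mk(13); ocd_b <- mk(14)
  nulls <- null_statistics(hc_a, hc_b, ocd_a, ocd_b)
  expect_gte(nulls$hc_null$auc, 0); expect_lte(nulls$hc_null$auc, 1)
  expect_gte(nulls$ocd_null$auc, 0); expect_lte(nulls$ocd_null$auc, 1)
  # all four sets come from the same ensemble: no systematic shift
  expect_equal(nulls$ocd_null$auc, 0.5, tolerance = 0.25)
  # determinism under identical seeds
  nulls2 <- null_statistics(hc_a, hc_b, ocd_a, ocd_b)
  expect_identical(nulls$ocd_null$auc, nulls2$ocd_null$auc)
})

test_that("contribution scores isolate targeted parameters with the right sign", {
  topo <- canonical_topology()
  priors <- canonical_priors(topo)
  runner <- linear_fc_runner(noise_sd = 0.01)
  # patients: high C_OA; controls: low C_OA -> the linear map moves the first
  # edge, so permuting C_OA improves the distance and C_OA decreases
  th_ocd <- sample_prior(priors, 300, seed = 7)
  th_hc <- th_ocd
  th_ocd[, "C_OA"] <- runif(300, 0.35, 0.45)
  th_hc[, "C_OA"] <- runif(300, -0.1, 0.0)
  ocd <- posterior_ensemble(th_ocd, priors)
  hc <- posterior_ensemble(th_hc, priors)
  mk <- function(ens, seed) {
    build_virtual_cohorts(ens, function(th, sd) runner(th, sd),
                          n_subjects = 100, cohort_size = 20, seed = seed)
  }
  hc_base <- mk(hc, 21); ocd_base <- mk(ocd, 22)
  ivs <- list("C_OA", "C_PA")
  posts <- lapply(seq_along(ivs), function(k) {
    apply_intervention(ocd, hc, ivs[[k]], function(th, sd) runner(th, sd),
                       n_subjects = 100, cohort_size = 20, seed = 30 + k)
  })
  outs <- lapply(posts, intervention_outcome, ocd_base, hc_base)
  cs <- contribution_scores(outs, ivs, posts, ocd_base, hc_base, alpha = 0.05)
  # the effective intervention is significant and its parameter decreased
  # while FC improved: negative association of "increase" with improvement
  expect_true(cs$significant[1])
  expect_lt(cs$scores[["C_OA"]], 0)
  # untargeted parameters score exactly zero
  untouched <- setdiff(names(cs$scores), c("C_OA", "C_PA"))
  expect_true(all(cs$scores[untouched] == 0))
})
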