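# Combinatorial virtual interventions: permute subsets of parameters from the
# patient posterior to the control posterior, re-simulate virtual cohorts, and
# score the shift towards control functional connectivity.

#' Enumerate virtual interventions
#'
#' All non-empty subsets of up to `max_targets` parameters, in deterministic
#' order (by subset size, then lexicographic). With 11 significant parameters
#' and up to 6 targets this yields 1485 interventions.
#'
#' @param param_names character vector of candidate target parameters.
#' @param max_targets largest subset size (default 6).
#' @return list of character vectors.
#' @export
enumerate_interventions <- function(param_names, max_targets = 6) {
  if (!length(param_names)) stop("empty parameter list")
  if (max_targets > length(param_names)) {
    stop("max_targets cannot exceed the number of parameters")
  }
  sorted <- sort(param_names)
  out <- list()
  for (k in seq_len(max_targets)) {
    subs <- utils::combn(sorted, k, simplify = FALSE)
    out <- c(out, subs)
  }
  out
}

#' Build virtual cohorts from a posterior ensemble
#'
#' Draws one parameter vector per virtual subject from the ensemble's kernel
#' density ([sample_posterior()]), simulates that subject's FC with
#' `model_runner`, and partitions the subjects disjointly into cohorts
#' (default scheme: 1000 subjects into 20 cohorts of 50). Failed simulations
#' are redrawn (and counted).
#'
#' @param ensemble a `posterior_ensemble`.
#' @param model_runner `function(theta, seed)` returning one FC vector (or a
#'   1-row matrix).
#' @param n_subjects total virtual subjects (must be divisible by
#'   `cohort_size`).
#' @param cohort_size subjects per cohort (default 50).
#' @param seed base seed.
#' @param label cohort label prefix.
#' @param theta optional pre-drawn parameter matrix (`n_subjects` rows),
#'   bypassing the posterior sampling (used by [apply_intervention()]).
#' @return list of [fc_cohort()]s; attribute `n_redrawn` counts redraws.
#' @export
build_virtual_cohorts <- function(ensemble, model_runner, n_subjects = 1000,
                                  cohort_size = 50, seed = 1L,
                                  label = "virtual", theta = NULL) {
  if (n_subjects %% cohort_size != 0) {
    stop("n_subjects must be divisible by cohort_size")
  }
  if (is.null(theta)) {
    theta <- sample_posterior(ensemble, n_subjects, seed = seed)
  }
  stopifnot(nrow(theta) == n_subjects)
  fc <- NULL
  n_redrawn <- 0L
  for (i in seq_len(n_subjects)) {
    row <- NULL
    tries <- 0L
    th <- theta[i, ]
    while (is.null(row)) {
      sim_seed <- (seed + 13L * i + 1000003L * tries) %% 2147483647L
      row <- tryCatch(model_runner(th, sim_seed), error = function(e) NULL)
      if (is.null(row)) {
        tries <- tries + 1L
        n_redrawn <- n_redrawn + 1L
        if (tries > 20L) stop("simulation failed repeatedly for subject ", i)
        th <- drop(sample_posterior(ensemble, 1, seed = sim_seed))
        theta[i, ] <- th
      }
    }
    row <- if (is.matrix(row)) row[1, ] else row
    if (is.null(fc)) {
      fc <- matrix(NA_real_, n_subjects, length(row),
                   dimnames = list(NULL, names(row)))
    }
    fc[i, ] <- row
  }
  n_cohorts <- n_subjects / cohort_size
  groups <- rep(seq_len(n_cohorts), each = cohort_size)
  out <- lapply(seq_len(n_cohorts), function(g) {
    idx <- which(groups == g)
    fc_cohort(fc[idx, , drop = FALSE], label = paste0(label, "-", g),
              theta = theta[idx, , drop = FALSE], subject_ids = idx)
  })
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Simulate cohorts under a virtual intervention
#'
#' For every virtual subject, the targeted parameters are drawn from the
#' control (healthy) posterior while all remaining parameters are drawn from
#' the patient posterior; cohorts are then built as in
#' [build_virtual_cohorts()].
#'
#' @param ocd,hc `posterior_ensemble`s for the patient and control groups
#'   (same parameter sets).
#' @param iv character vector of targeted parameter names (non-empty).
#' @inheritParams build_virtual_cohorts
#' @return list of [fc_cohort()]s.
#' @export
apply_intervention <- function(ocd, hc, iv, model_runner, n_subjects = 1000,
                               cohort_size = 50, seed = 1L) {
  if (!length(iv)) stop("intervention must target at least one parameter")
  miss <- setdiff(iv, colnames(ocd$theta))
  if (length(miss)) stop("target(s) absent from ensembles: ",
                         paste(miss, collapse = ", "))
  if (!identical(colnames(ocd$theta), colnames(hc$theta))) {
    stop("ensembles must cover the same parameters")
  }
  theta <- sample_posterior(ocd, n_subjects, seed = seed)
  theta_hc <- sample_posterior(hc, n_subjects, seed = seed + 1L, params = iv)
  theta[, iv] <- theta_hc
  build_virtual_cohorts(ocd, model_runner, n_subjects, cohort_size,
                        seed = seed + 2L, label = "intervention",
                        theta = theta)
}

all_pair_distances <- function(cohorts_a, cohorts_b) {
  d <- matrix(NA_real_, length(cohorts_a), length(cohorts_b))
  for (i in seq_along(cohorts_a)) {
    for (j in seq_along(cohorts_b)) {
      d[i, j] <- cohort_distance(cohorts_a[[i]], cohorts_b[[j]])
    }
  }
  d
}

auc_less <- function(x, y) {
  # probability that a value of x is below a value of y, ties counted half
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  U_greater <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs x > y (+ties/2)
  (n1 * n2 - U_greater) / (n1 * n2)
}

#' Score one virtual intervention
#'
#' Computes the two distance samples (all cohort pairs, so 400 values for
#' 20 + 20 cohorts): `d(post, baseline_hc)` between the post-intervention and
#' control baseline cohorts, and `d(baseline_OCD, baseline_hc)` between the
#' patient and control baselines. A one-sided Mann-Whitney U test quantifies
#' whether the intervention moved the cohorts closer to the controls; the
#' scaled statistic `AUC = U / (n1 n2)` (ties counted one half) is the
#' probability that the intervention improves FC.
#'
#' @param post_cohorts,ocd_baseline_cohorts,hc_baseline_cohorts lists of
#'   [fc_cohort()]s (at least 2 each) sharing the edge ordering.
#' @return object of class `intervention_outcome`: `auc`, `p` (one-sided),
#'   `U`, `n1`, `n2`, and the two distance samples.
#' @export
intervention_outcome <- function(post_cohorts, ocd_baseline_cohorts,
                                 hc_baseline_cohorts) {
  if (length(post_cohorts) < 2 || length(ocd_baseline_cohorts) < 2 ||
      length(hc_baseline_cohorts) < 2) {
    stop("need at least 2 cohorts in every list")
  }
  d_post <- as.numeric(all_pair_distances(post_cohorts, hc_baseline_cohorts))
  d_base <- as.numeric(all_pair_distances(ocd_baseline_cohorts,
                                          hc_baseline_cohorts))
  wt <- stats::wilcox.test(d_post, d_base, alternative = "less",
                           exact = FALSE, correct = TRUE)
  auc <- auc_less(d_post, d_base)
  structure(list(auc = auc, p = wt$p.value,
                 U = auc * length(d_post) * length(d_base),
                 n1 = length(d_post), n2 = length(d_base),
                 d_post = d_post, d_baseline = d_base),
            class = "intervention_outcome")
}

#' @export
print.intervention_outcome <- function(x, ...) {
  cat(sprintf("Intervention outcome: AUC = %.3f (n1 = %d, n2 = %d), one-sided p = %.3g\n",
              x$auc, x$n1, x$n2, x$p))
  invisible(x)
}

#' Null statistics for the intervention analysis
#'
#' Quantifies how far patients sit from controls at baseline relative to the
#' variability within each group: independent replicate cohort sets are
#' compared against the patient-control baseline distances exactly as an
#' intervention would be. Control-vs-control distances give the control null
#' AUC; patient-vs-patient (replicate) distances give the patient null AUC.
#'
#' @param hc_cohorts_a,hc_cohorts_b independent control cohort sets.
#' @param ocd_cohorts_a,ocd_cohorts_b independent patient cohort sets.
#' @param hc_reference control cohort set used as the common reference
#'   (defaults to `hc_cohorts_a`).
#' @return list with `hc_null` and `ocd_null` [intervention_outcome()]s.
#' @export
null_statistics <- function(hc_cohorts_a, hc_cohorts_b, ocd_cohorts_a,
                            ocd_cohorts_b, hc_reference = hc_cohorts_a) {
  list(hc_null = intervention_outcome(hc_cohorts_b, ocd_cohorts_a,
                                      hc_reference),
       ocd_null = intervention_outcome(ocd_cohorts_b, ocd_cohorts_a,
                                       hc_reference))
}

#' Parameter contribution scores across significant interventions
#'
#' For every statistically significant intervention, parameter values are
#' z-scored against the patient baseline distribution, cohort-mean changes
#' between all pre/post cohort pairings (20 x 20 = 400) are paired with the
#' FC improvement of the same pairing (mean baseline distance to controls
#' minus mean post-intervention distance), and the per-parameter dot product
#' of these two 400-vectors is accumulated over the interventions that target
#' the parameter. Positive scores associate an increase of the parameter with
#' improved FC. Parameters never targeted score 0.
#'
#' @param outcomes list of [intervention_outcome()]s.
#' @param interventions list of target-name vectors matching `outcomes`.
#' @param post_cohort_sets list (per intervention) of post cohort lists.
#' @param ocd_baseline_cohorts patient baseline cohorts (with `theta`).
#' @param hc_baseline_cohorts control baseline cohorts.
#' @param alpha significance level on the FWE-corrected p-values.
#' @param method multiplicity correction across interventions.
#' @return list of class `contribution_scores`: `scores` (named vector),
#'   `significant` (logical per intervention), `p_fwe`.
#' @export
contribution_scores <- function(outcomes, interventions, post_cohort_sets,
                                ocd_baseline_cohorts, hc_baseline_cohorts,
                                alpha = 0.05, method = "bonferroni") {
  stopifnot(length(outcomes) == length(interventions),
            length(outcomes) == length(post_cohort_sets))
  p_fwe <- stats::p.adjust(vapply(outcomes, `[[`, numeric(1), "p"),
                           method = method)
  sig <- p_fwe < alpha
  base_theta <- do.call(rbind, lapply(ocd_baseline_cohorts, `[[`, "theta"))
  if (is.null(base_theta)) stop("baseline cohorts must carry theta")
  mu <- colMeans(base_theta)
  sd0 <- apply(base_theta, 2, stats::sd)
  if (any(sd0 == 0)) {
    stop("zero baseline SD for parameter(s): ",
         paste(colnames(base_theta)[sd0 == 0], collapse = ", "),
         "; z-scoring undefined")
  }
  zmeans <- function(cohorts) {
    t(vapply(cohorts, function(co) {
      colMeans(sweep(sweep(co$theta, 2, mu), 2, sd0, "/"))
    }, numeric(length(mu))))
  }
  pre_z <- zmeans(ocd_baseline_cohorts)              # n_pre x p
  d_base_mat <- all_pair_distances(ocd_baseline_cohorts, hc_baseline_cohorts)
  pre_d <- rowMeans(d_base_mat)
  scores <- stats::setNames(rep(0, length(mu)), names(mu))
  for (k in which(sig)) {
    post <- post_cohort_sets[[k]]
    post_z <- zmeans(post)
    post_d <- rowMeans(all_pair_distances(post, hc_baseline_cohorts))
    np <- nrow(pre_z); nq <- nrow(post_z)
    # all (pre i, post j) pairings
    dz <- pre_z[rep(seq_len(np), times = nq), , drop = FALSE] -
      post_z[rep(seq_len(nq), each = np), , drop = FALSE]
    imp <- pre_d[rep(seq_len(np), times = nq)] -
      post_d[rep(seq_len(nq), each = np)]
    contrib <- colSums(dz * imp)
    tgt <- interventions[[k]]
    # sign convention: dz = pre - post; a parameter that increased post-
    # intervention has negative dz, so flip the sign to read "increase
    # associated with improvement" as positive.
    scores[tgt] <- scores[tgt] - contrib[tgt]
  }
  structure(list(scores = scores, significant = sig, p_fwe = p_fwe),
            class = "contribution_scores")
}
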