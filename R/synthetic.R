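# Synthetic-data generator: ground-truth parameter populations for a
# control-like and a patient-like group, FC datasets with hidden parameters,
# and longitudinal symptom changes, so that every pipeline stage can be
# exercised without the clinical dataset.

#' Ground-truth group specification
#'
#' Per-parameter truncated-normal distributions inside the prior bounds.
#' The preset locations are the fitted group posterior medians of the
#' four-region circuit: the patient-like (`"OCD-like"`) group has increased
#' bidirectional ventral coupling (C_OA 0.36, C_AO 0.34), reduced dorsal
#' coupling (C_LP 0.05, C_PL 0.10), reduced cortico-cortical coupling
#' (C_OL 0.22), loss of the negative striato-striatal coupling (C_AP 0.02),
#' lower drift (eta 0.04) and higher volatility (sigma_OA 0.27,
#' sigma_LP 0.26) than the control-like group (C_OA -0.03, C_AO 0.11,
#' C_LP 0.21, C_PL 0.34, C_OL 0.30, C_AP -0.26, eta 0.05, volatilities
#' 0.24). Parameters without a reported group difference (C_LO, C_PA, global
#' sigma) sit at the same mid-prior location in both groups. Scales default
#' to 10% of each prior width.
#'
#' @param preset `"control-like"` or `"OCD-like"`.
#' @param topology the circuit (default [canonical_topology()]).
#' @param scale_frac spread as a fraction of each prior width (default 0.1).
#' @return data.frame of class `group_spec` with columns `name`, `location`,
#'   `scale`, `lower`, `upper`, plus attribute `label`.
#' @export
make_group_spec <- function(preset = c("control-like", "OCD-like"),
                            topology = canonical_topology(),
                            scale_frac = 0.1) {
  preset <- match.arg(preset)
  priors <- canonical_priors(topology)
  loc <- (priors$lower + priors$upper) / 2
  names(loc) <- priors$name
  medians <- if (preset == "OCD-like") {
    c(C_OA = 0.36, C_AO = 0.34, C_LP = 0.05, C_PL = 0.10, C_OL = 0.22,
      C_AP = 0.02, eta_OA = 0.04, eta_LP = 0.04, sigma_OA = 0.27,
      sigma_LP = 0.26)
  } else {
    c(C_OA = -0.03, C_AO = 0.11, C_LP = 0.21, C_PL = 0.34, C_OL = 0.30,
      C_AP = -0.26, eta_OA = 0.05, eta_LP = 0.05, sigma_OA = 0.24,
      sigma_LP = 0.24)
  }
  use <- intersect(names(medians), names(loc))
  loc[use] <- medians[use]
  spec <- data.frame(name = priors$name, location = unname(loc),
                     scale = scale_frac * (priors$upper - priors$lower),
                     lower = priors$lower, upper = priors$upper,
                     stringsAsFactors = FALSE)
  if (any(spec$location < spec$lower | spec$location > spec$upper)) {
    stop("group locations must lie inside the prior bounds")
  }
  structure(spec, class = c("group_spec", "data.frame"), label = preset)
}

#' Draw ground-truth parameters for a group
#'
#' Truncated-normal draws (inverse-CDF sampling) within the prior bounds.
#'
#' @param spec a [make_group_spec()] result.
#' @param n number of subjects.
#' @param seed integer seed.
#' @return matrix `n x p` with parameter names.
#' @export
sample_group_theta <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n, nrow(spec), dimnames = list(NULL, spec$name))
  for (j in seq_len(nrow(spec))) {
    if (spec$scale[j] == 0) { out[, j] <- spec$location[j]; next }
    plo <- stats::pnorm(spec$lower[j], spec$location[j], spec$scale[j])
    phi <- stats::pnorm(spec$upper[j], spec$location[j], spec$scale[j])
    u <- stats::runif(n, plo, phi)
    out[, j] <- stats::qnorm(u, spec$location[j], spec$scale[j])
  }
  out
}

#' Analytic FC surrogate from a linearised model
#'
#' A fast coupling-to-correlation map used in unit tests where the full
#' stochastic simulation would dominate the runtime: the drift field is
#' linearised at its low-activity equilibrium (dynamic couplings frozen at
#' their means), the stationary covariance of the resulting
#' Ornstein-Uhlenbeck system is obtained from the Lyapunov equation, and
#' pairwise correlations are read off in canonical edge order. Coupling
#' volatility is not represented; acceptance-level analyses use the full
#' simulator instead.
#'
#' @param theta named parameter vector (see [params_from_theta()]).
#' @param topology the circuit.
#' @return named FC vector.
#' @export
surrogate_fc <- function(theta, topology = canonical_topology()) {
  params <- params_from_theta(topology, theta)
  n <- length(topology$regions)
  M <- skeleton_matrix(params)
  # relax the deterministic flow to a stable equilibrium (forward Euler,
  # stable for steps below 2/|lambda|; near a fold the slow mode needs more
  # time, hence the adaptive rounds), then polish by Newton; depending on
  # the couplings the attracting state may be low- or high-activity
  S <- rep(0.1, n)
  euler <- function(S) pmin(pmax(S + 0.02 * as.numeric(
    -S / params$tau_S +
      (1 - S) * params$gamma * h_and_deriv(M %*% S + params$I_0, params)$H
  ), 0), 1)
  for (round in 1:12) {
    for (k in 1:500) S <- euler(S)
    if (max(abs(drift_field(S, params$C, params))) < 1e-6) break
  }
  root <- newton_batch(matrix(S, 1), M, params, maxit = 40)
  db <- drift_batch(root, M, params)
  if (max(abs(db$D)) > 1e-7) {
    stop("surrogate: no equilibrium found for these parameters")
  }
  S_star <- pmin(pmax(root[1, ], 0), 1)
  J <- drift_jacobian(S_star, M, params)
  if (max(Re(eigen(J, only.values = TRUE)$values)) >= -1e-8) {
    stop("surrogate: linearisation point is not strictly stable")
  }
  Q <- diag(params$sigma_node^2, n)
  # vec(Sigma) solves (J (x) I + I (x) J) vec(Sigma) = -vec(Q)
  A <- kronecker(J, diag(n)) + kronecker(diag(n), J)
  Sigma <- matrix(solve(A, -as.numeric(Q)), n, n)
  Sigma <- (Sigma + t(Sigma)) / 2
  D <- 1 / sqrt(diag(Sigma))
  R <- Sigma * (D %o% D)
  dimnames(R) <- list(topology$regions, topology$regions)
  idx <- fc_pair_indices(topology$regions)
  labs <- canonical_edge_order(topology$regions)
  stats::setNames(vapply(seq_len(nrow(idx)),
                         function(k) R[idx[k, 1], idx[k, 2]], numeric(1)),
                  labs)
}

#' Generate a synthetic FC dataset
#'
#' Draws hidden ground-truth parameters per subject, maps each to an FC
#' vector (full stochastic simulation through a `model_runner`, or the
#' analytic [surrogate_fc()] when `model_runner = "surrogate"`), adds
#' Gaussian measurement noise and clips to `[-1, 1]`. The hidden parameters
#' are returned for recovery experiments.
#'
#' @param spec a [make_group_spec()].
#' @param n_subjects number of subjects.
#' @param model_runner `function(theta, seed)` returning an FC vector, or
#'   the string `"surrogate"`.
#' @param noise_sd measurement-noise SD on each FC value (default 0.05).
#' @param seed integer seed.
#' @param topology the circuit.
#' @return list of class `synthetic_fc_dataset`: `fc` (matrix), `theta`
#'   (hidden parameters), `label`, `seed`.
#' @export
generate_fc_dataset <- function(spec, n_subjects, model_runner = "surrogate",
                                noise_sd = 0.05, seed = 1L,
                                topology = canonical_topology()) {
  stopifnot(n_subjects >= 1)
  theta <- sample_group_theta(spec, n_subjects, seed = seed)
  labs <- canonical_edge_order(topology$regions)
  fc <- matrix(NA_real_, n_subjects, length(labs),
               dimnames = list(NULL, labs))
  n_redrawn <- 0L
  for (i in seq_len(n_subjects)) {
    sim_seed <- (seed + 31L * i) %% 2147483647L
    map_one <- function(th, s) {
      if (identical(model_runner, "surrogate")) surrogate_fc(th, topology)
      else model_runner(th, s)
    }
    row <- NULL; tries <- 0L
    while (is.null(row)) {
      row <- tryCatch(map_one(theta[i, ], sim_seed + tries),
                      error = function(e) NULL)
      if (is.null(row)) {
        # pathological draw (e.g. no stable state at a fold): redraw, logged
        tries <- tries + 1L
        n_redrawn <- n_redrawn + 1L
        if (tries > 20L) stop("FC mapping failed repeatedly for subject ", i)
        theta[i, ] <- sample_group_theta(spec, 1, seed = sim_seed + tries)
      }
    }
    fc[i, ] <- if (is.matrix(row)) row[1, ] else row
  }
  if (noise_sd > 0) {
    set.seed((seed + 999983L) %% 2147483647L)
    fc <- fc + matrix(stats::rnorm(length(fc), 0, noise_sd), nrow(fc))
  }
  fc <- pmin(pmax(fc, -1), 1)
  structure(list(fc = fc, theta = theta, label = attr(spec, "label"),
                 seed = seed, n_redrawn = n_redrawn),
            class = "synthetic_fc_dataset")
}

#' Generate longitudinal symptom changes
#'
#' Symptom-score changes (e.g. Y-BOCS total differences between baseline and
#' follow-up) with an exactly planted in-sample Pearson correlation against a
#' per-subject FC-change scalar, and the requested mean and standard
#' deviation. Defaults mirror a moderate four-week clinical improvement:
#' mean change -4.7 points, SD 5.0, correlation 0.35 with FC normalisation.
#'
#' The construction standardises the FC-change vector, draws a noise vector,
#' orthogonalises it, and mixes the two with weights `target_r` and
#' `sqrt(1 - target_r^2)`, so the sample correlation equals `target_r` up to
#' float round-off.
#'
#' @param fc_change_scalar per-subject FC change (non-degenerate variance).
#' @param target_r planted correlation, `|target_r| < 1` (or exactly 1).
#' @param mean_change,sd_change requested sample moments of the output.
#' @param seed integer seed.
#' @return numeric vector of symptom changes, one per subject.
#' @export
generate_longitudinal_symptoms <- function(fc_change_scalar, target_r = 0.35,
                                           mean_change = -4.7,
                                           sd_change = 5.0, seed = 1L) {
  x <- as.numeric(fc_change_scalar)
  if (length(x) < 3) stop("need at least 3 subjects")
  if (stats::sd(x) == 0) stop("degenerate fc_change variance")
  if (abs(target_r) > 1) stop("|target_r| must not exceed 1")
  zx <- as.numeric(scale(x))
  if (!is.null(seed)) set.seed(seed)
  e <- stats::rnorm(length(x))
  e <- stats::residuals(stats::lm(e ~ zx))
  ze <- as.numeric(scale(e))
  y0 <- target_r * zx + sqrt(max(0, 1 - target_r^2)) * ze
  y0 <- as.numeric(scale(y0))
  mean_change + sd_change * y0
}

#' Generate a complete synthetic two-group study
#'
#' Bundles the generator stages into one reproducible object: hidden
#' parameters and FC for a control-like and a patient-like group, a second
#' (follow-up) FC session for the patient group in which each subject's
#' parameters move a configurable fraction towards the control locations,
#' and symptom changes correlated with the FC normalisation.
#'
#' @param n_per_group subjects per group.
#' @param seed master seed; stage seeds are derived from it.
#' @param model_runner forwarded to [generate_fc_dataset()].
#' @param recovery_frac fraction of the parameter gap to control locations
#'   closed at follow-up (default 0.3).
#' @param noise_sd FC measurement noise.
#' @param target_r,mean_change,sd_change forwarded to
#'   [generate_longitudinal_symptoms()].
#' @param topology the circuit.
#' @return list of class `synthetic_study`.
#' @export
generate_synthetic_study <- function(n_per_group = 50, seed = 1L,
                                     model_runner = "surrogate",
                                     recovery_frac = 0.3, noise_sd = 0.05,
                                     target_r = 0.35, mean_change = -4.7,
                                     sd_change = 5.0,
                                     topology = canonical_topology()) {
  spec_hc <- make_group_spec("control-like", topology)
  spec_ocd <- make_group_spec("OCD-like", topology)
  hc <- generate_fc_dataset(spec_hc, n_per_group, model_runner, noise_sd,
                            seed = seed, topology = topology)
  ocd <- generate_fc_dataset(spec_ocd, n_per_group, model_runner, noise_sd,
                             seed = seed + 1L, topology = topology)
  # follow-up: patient parameters relax part-way towards control locations
  loc_hc <- stats::setNames(spec_hc$location, spec_hc$name)
  theta_post <- ocd$theta +
    recovery_frac * (matrix(loc_hc[colnames(ocd$theta)],
                            nrow(ocd$theta), ncol(ocd$theta), byrow = TRUE) -
                       ocd$theta)
  labs <- canonical_edge_order(topology$regions)
  fc_post <- matrix(NA_real_, n_per_group, length(labs),
                    dimnames = list(NULL, labs))
  for (i in seq_len(n_per_group)) {
    sim_seed <- (seed + 2L + 31L * i) %% 2147483647L
    frac <- recovery_frac
    row <- NULL
    while (is.null(row)) {
      th_i <- ocd$theta[i, ] +
        frac * (loc_hc[colnames(ocd$theta)] - ocd$theta[i, ])
      row <- tryCatch({
        if (identical(model_runner, "surrogate")) surrogate_fc(th_i, topology)
        else model_runner(th_i, sim_seed)
      }, error = function(e) NULL)
      if (is.null(row)) {
        # a fold-degenerate state: move the subject marginally further
        # towards the control locations and retry
        frac <- frac + 0.02
        if (frac > 1) stop("follow-up FC mapping failed for subject ", i)
      }
    }
    theta_post[i, ] <- th_i
    fc_post[i, ] <- if (is.matrix(row)) row[1, ] else row
  }
  if (noise_sd > 0) {
    set.seed((seed + 424243L) %% 2147483647L)
    fc_post <- pmin(pmax(fc_post +
                           matrix(stats::rnorm(length(fc_post), 0, noise_sd),
                                  nrow(fc_post)), -1), 1)
  }
  dfc <- fc_change_towards_controls(ocd$fc, fc_post, colMeans(hc$fc))
  dy <- generate_longitudinal_symptoms(dfc, target_r, mean_change, sd_change,
                                       seed = seed + 3L)
  structure(list(hc = hc, ocd = ocd, fc_post = fc_post,
                 theta_post = theta_post, delta_fc = dfc,
                 delta_symptoms = dy, seed = seed,
                 topology = topology),
            class = "synthetic_study")
}
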