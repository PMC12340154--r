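#' Population transfer function
#'
#' Converts net input current to population firing rate,
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`. The apparent singularity at
#' `a x = b` is removable (the limit is `1/d`) and is evaluated by a series
#' expansion there.
#'
#' @param x input current in nA (vectorised).
#' @param params a [model_parameters()] object, or `NULL` to use `a`, `b`, `d`.
#' @param a,b,d transfer constants (nC^-1, Hz, s) used when `params` is `NULL`.
#' @return firing rates in Hz.
#' @export
transfer_function <- function(x, params = NULL, a = 270, b = 108, d = 0.154) {
  if (!is.null(params)) {
    a <- params$a; b <- params$b; d <- params$d
  }
  if (d <= 0) stop("d must be positive")
  if (any(!is.finite(x))) stop("x must be finite")
  transfer_H_cpp(as.numeric(x), a, b, d)
}

#' Deterministic drift of the gating equations
#'
#' Evaluates `dS/dt = -S/tau_S + (1 - S) gamma H(x)` with input currents
#' `x_i = w J_N S_i + G J_N sum_j C_ij S_j + I_0`, where `C` is the effective
#' coupling matrix (static couplings plus the current values of any dynamic
#' couplings). No noise term: this is the deterministic skeleton used by the
#' equilibrium and bifurcation analysis.
#'
#' @param S gating vector in `[0, 1]`.
#' @param C_effective n-by-n effective coupling matrix (row = target).
#' @param params a [model_parameters()] object.
#' @return vector `dS/dt` in s^-1.
#' @export
drift_field <- function(S, C_effective, params) {
  n <- length(S)
  if (!is.matrix(C_effective) || !all(dim(C_effective) == c(n, n))) {
    stop("dimension mismatch between S and C_effective")
  }
  x <- params$w * params$J_N * S +
    params$G * params$J_N * as.numeric(C_effective %*% S) + params$I_0
  -S / params$tau_S +
    (1 - S) * params$gamma * transfer_function(x, params)
}

#' One Euler-Maruyama step of a mean-reverting coupling
#'
#' Updates an Ornstein-Uhlenbeck coupling:
#' `c' = c - eta (c - c_mean) dt + sigma sqrt(dt) xi`. With `eta = 0` and
#' `sigma = 0` the coupling is invariant. Vectorised over `c_now` (parallel
#' chains).
#'
#' @param c_now current coupling value(s).
#' @param c_mean mean coupling (set point).
#' @param eta drift rate, s^-1 (non-negative).
#' @param sigma volatility, s^-1 (non-negative).
#' @param dt step, s (positive).
#' @param noise_draw standard-normal draw(s); defaults to `rnorm`.
#' @return updated coupling value(s).
#' @export
step_ou <- function(c_now, c_mean, eta, sigma, dt,
                    noise_draw = stats::rnorm(length(c_now))) {
  if (dt <= 0) stop("dt must be positive")
  if (any(eta < 0)) stop("eta must be non-negative")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  c_now - eta * (c_now - c_mean) * dt + sigma * sqrt(dt) * noise_draw
}

#' Simulate the stochastic circuit model
#'
#' Integrates the coupled gating equations by Euler-Maruyama. Dynamic edges
#' evolve as mean-reverting stochastic couplings and enter the input current
#' in place of their static means; node noise of amplitude
#' `sigma_node * sqrt(dt)` per step perturbs every gating variable. Gating
#' values are clipped to `[0, 1]` after each step (the state is a channel
#' fraction); clip events are counted in the returned object. Identical
#' `(params, config, seed)` give bit-identical trajectories.
#'
#' @param params a [model_parameters()] object.
#' @param topology the matching [circuit_topology()] (defaults to the one
#'   stored in `params`).
#' @param config a [simulation_config()].
#' @param S0 initial gating values (default 0.1 for every region).
#' @param C0 initial dynamic-coupling values (default: the mean couplings).
#' @param noise_path optional matrix of standard-normal draws (rows = coarse
#'   steps, columns = regions then dynamic edges) with `refine` sub-steps per
#'   row; used by the step-size convergence check.
#' @param refine sub-steps per `noise_path` row.
#' @return an object of class `trajectory_set`: `times` (s), `S` (matrix,
#'   one column per region), `C_tilde` (matrix, one column per dynamic edge),
#'   `clip_count`, and the `config` used.
#' @export
simulate_circuit <- function(params, topology = params$topology,
                             config = simulation_config(),
                             S0 = NULL, C0 = NULL,
                             noise_path = NULL, refine = 1L) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(config, "simulation_config"))
  if (!identical(topology$regions, params$topology$regions)) {
    stop("incompatible topology and parameters")
  }
  n <- length(topology$regions)
  dyn <- dynamic_edges(topology)
  k <- nrow(dyn)
  if (is.null(S0)) S0 <- rep(0.1, n)
  if (length(S0) != n) stop("S0 must have one value per region")
  if (is.null(C0)) {
    C0 <- vapply(dyn$label, function(l) {
      ij <- edge_index(topology, l); params$C[ij["target"], ij["source"]]
    }, numeric(1))
  }
  if (length(C0) != k) stop("C0 must have one value per dynamic edge")
  dyn_idx <- matrix(0L, k, 2)
  for (i in seq_len(k)) {
    ij <- edge_index(topology, dyn$label[i])
    dyn_idx[i, ] <- as.integer(ij) - 1L
  }
  if (is.null(noise_path)) noise_path <- matrix(numeric(0), 0, 0)

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- rww_simulate_cpp(params$C, dyn_idx,
                          as.numeric(params$eta), as.numeric(params$sigma_coupling),
                          params$a, params$b, params$d,
                          params$w, params$G, params$J_N, params$I_0,
                          params$tau_S, params$gamma, params$sigma_node,
                          config$dt, config$duration, config$burn_in,
                          config$record_dt,
                          as.numeric(S0), as.numeric(C0),
                          noise_path, as.integer(refine))
  if (isTRUE(res$diverged)) {
    stop("simulation diverged at step ", res$step,
         if (!is.na(res$region)) paste0(" (region ", res$region, ")"))
  }
  S <- res$S
  colnames(S) <- topology$regions
  Ct <- res$C
  if (k > 0) colnames(Ct) <- dyn$label
  if (!config$record_couplings) Ct <- NULL
  structure(list(times = as.numeric(res$times), S = S, C_tilde = Ct,
                 clip_count = res$clip_count, config = config,
                 topology_name = topology$name),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set (", x$topology_name, "): ", nrow(x$S), " samples x ",
      ncol(x$S), " regions, t in [", min(x$times), ", ", max(x$times),
      "] s, ", x$clip_count, " clip events\n", sep = "")
  invisible(x)
}
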