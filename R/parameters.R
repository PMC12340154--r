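#' Model parameters for a frontostriatal circuit
#'
#' Bundles one full parameter vector for a simulation: the mean coupling
#' matrix, per-dynamic-edge drift and volatility, node-noise amplitude and
#' the global constants of the reduced Wong-Wang population model.
#'
#' Global defaults follow the resting-state literature for this model family:
#' gating relaxation `tau_S` = 0.1 s, kinetic constant `gamma` = 0.641 s^-1
#' (couplings scaled in time by 1/gamma, about 1.56 s), local recurrence
#' `w` = 0.9, global coupling scale `G` = 2.5, synaptic factor
#' `J_N` = 0.2609 nA, and node-noise amplitude `sigma_node` = 0.1 s^-1
#' (white-noise variance 0.01 s^-2). The transfer-function constants
#' `a` = 270 nC^-1, `b` = 108 Hz, `d` = 0.154 s and background current
#' `I_0` = 0.3 nA are the canonical reduced Wong-Wang values; they are kept
#' configurable because they are treated as fixed biophysical constants
#' rather than fitted quantities.
#'
#' @param topology a [circuit_topology()].
#' @param C named numeric vector of mean coupling strengths, names matching
#'   the topology's edge labels (missing edges default to 0), or a full
#'   n-by-n matrix (row = target, column = source).
#' @param eta named numeric vector of drift rates (s^-1), one per dynamic edge.
#' @param sigma_coupling named numeric vector of volatilities (s^-1), one per
#'   dynamic edge.
#' @param sigma_node node-noise amplitude (s^-1).
#' @param tau_S,gamma,w,G,J_N,I_0,a,b,d global model constants (see Details).
#' @return an object of class `model_parameters`.
#' @export
model_parameters <- function(topology, C, eta = NULL, sigma_coupling = NULL,
                             sigma_node = 0.1, tau_S = 0.1, gamma = 0.641,
                             w = 0.9, G = 2.5, J_N = 0.2609, I_0 = 0.3,
                             a = 270, b = 108, d = 0.154) {
  stopifnot(inherits(topology, "circuit_topology"))
  n <- length(topology$regions)
  dyn <- dynamic_edges(topology)

  if (is.matrix(C)) {
    if (!all(dim(C) == c(n, n))) stop("C matrix must be ", n, "x", n)
    Cmat <- C
  } else {
    if (is.null(names(C)) || !all(names(C) %in% topology$edges$label)) {
      stop("C must be a named vector over the topology's edge labels")
    }
    Cmat <- matrix(0, n, n, dimnames = list(topology$regions, topology$regions))
    for (lbl in names(C)) {
      ij <- edge_index(topology, lbl)
      Cmat[ij["target"], ij["source"]] <- C[[lbl]]
    }
  }
  dimnames(Cmat) <- list(topology$regions, topology$regions)

  eta <- check_dyn_param(eta, dyn, "eta")
  sigma_coupling <- check_dyn_param(sigma_coupling, dyn, "sigma_coupling")
  if (tau_S <= 0) stop("tau_S must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (d <= 0) stop("d must be positive")
  if (sigma_node < 0) stop("sigma_node must be non-negative")
  if (any(eta < 0)) stop("eta must be non-negative")
  if (any(sigma_coupling < 0)) stop("sigma_coupling must be non-negative")

  structure(list(topology = topology, C = Cmat, eta = eta,
                 sigma_coupling = sigma_coupling, sigma_node = sigma_node,
                 tau_S = tau_S, gamma = gamma, w = w, G = G, J_N = J_N,
                 I_0 = I_0, a = a, b = b, d = d),
            class = "model_parameters")
}

check_dyn_param <- function(x, dyn, what) {
  if (nrow(dyn) == 0) {
    if (!is.null(x) && length(x)) stop(what, " given but topology has no dynamic edge")
    return(stats::setNames(numeric(0), character(0)))
  }
  if (is.null(x)) stop("every dynamic edge needs ", what, " (missing for: ",
                       paste(dyn$label, collapse = ", "), ")")
  if (is.null(names(x))) {
    if (length(x) == 1) x <- stats::setNames(rep(x, nrow(dyn)), dyn$label)
    else stop(what, " must be named by dynamic edge label")
  }
  miss <- setdiff(dyn$label, names(x))
  if (length(miss)) stop(what, " missing for dynamic edge(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(x), dyn$label)
  if (length(extra)) stop(what, " given for non-dynamic edge(s): ",
                          paste(extra, collapse = ", "))
  x[dyn$label]
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters on topology '", x$topology$name, "'\n", sep = "")
  cat("  couplings C (target x source):\n")
  print(round(x$C, 4))
  if (length(x$eta)) {
    cat("  dynamic edges: eta =", paste(sprintf("%s=%g", names(x$eta), x$eta),
                                        collapse = ", "), "\n")
    cat("                 sigma =", paste(sprintf("%s=%g", names(x$sigma_coupling),
                                                  x$sigma_coupling), collapse = ", "), "\n")
  }
  cat(sprintf("  sigma_node=%g s^-1, tau_S=%g s, gamma=%g s^-1, w=%g, G=%g, J_N=%g nA, I_0=%g nA\n",
              x$sigma_node, x$tau_S, x$gamma, x$w, x$G, x$J_N, x$I_0))
  invisible(x)
}

#' Build model parameters from a named parameter vector
#'
#' Maps a flat named vector -- the representation used by the priors, the
#' ABC particles and the synthetic-data generator -- onto a
#' [model_parameters()] object. Recognised names are the topology's edge
#' labels (`C_*`) for mean couplings, `eta_<suffix>` and `sigma_<suffix>`
#' for the drift and volatility of dynamic edge `C_<suffix>`, and the bare
#' name `sigma` for the global node-noise amplitude.
#'
#' @param topology a [circuit_topology()].
#' @param theta named numeric vector.
#' @param ... further arguments passed to [model_parameters()] (e.g. fixed
#'   global constants).
#' @return a `model_parameters` object.
#' @export
params_from_theta <- function(topology, theta, ...) {
  stopifnot(!is.null(names(theta)))
  dyn <- dynamic_edges(topology)
  suf <- sub("^C_", "", dyn$label)
  C <- theta[names(theta) %in% topology$edges$label]
  eta <- sig <- stats::setNames(rep(NA_real_, nrow(dyn)), dyn$label)
  for (i in seq_along(suf)) {
    en <- paste0("eta_", suf[i]); sn <- paste0("sigma_", suf[i])
    if (en %in% names(theta)) eta[i] <- theta[[en]]
    if (sn %in% names(theta)) sig[i] <- theta[[sn]]
  }
  if (anyNA(eta)) stop("theta is missing eta for dynamic edge(s): ",
                       paste(dyn$label[is.na(eta)], collapse = ", "))
  if (anyNA(sig)) stop("theta is missing sigma for dynamic edge(s): ",
                       paste(dyn$label[is.na(sig)], collapse = ", "))
  extra <- list(...)
  if (!"sigma_node" %in% names(extra) && "sigma" %in% names(theta)) {
    extra$sigma_node <- theta[["sigma"]]
  }
  do.call(model_parameters,
          c(list(topology = topology, C = C, eta = eta, sigma_coupling = sig),
            extra))
}

#' Simulation configuration
#'
#' @param dt integration step in seconds (default 1e-5 s, i.e. 0.01 ms;
#'   desk-scale analyses typically pass 1e-3 s, guarded by the step-size
#'   convergence property).
#' @param duration total simulated time in seconds (default 780 s: a 12-min
#'   recording plus burn-in).
#' @param burn_in initial transient discarded from all outputs, seconds.
#' @param tr BOLD sampling period in seconds (default 0.81 s).
#' @param record_dt spacing of recorded neural samples in seconds; the
#'   hemodynamic model is driven at this resolution (default 0.01 s).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param record_couplings keep the dynamic-coupling series in the output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1e-5, duration = 780, burn_in = 60,
                              tr = 0.81, record_dt = 0.01, seed = NULL,
                              record_couplings = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  if (burn_in >= duration) stop("burn_in must be smaller than duration")
  if (tr < dt) stop("tr must be at least dt")
  if (record_dt < dt) record_dt <- dt
  structure(list(dt = dt, duration = duration, burn_in = burn_in, tr = tr,
                 record_dt = record_dt, seed = seed,
                 record_couplings = isTRUE(record_couplings)),
            class = "simulation_config")
}
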