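#' Balloon-Windkessel hemodynamic parameters
#'
#' The canonical parameter set of the original hemodynamic model: signal
#' decay `kappa` = 0.65 s^-1, autoregulatory feedback `gamma_h` = 0.41 s^-1,
#' transit time `tau_h` = 0.98 s, vessel stiffness exponent `alpha` = 0.32,
#' resting oxygen extraction `rho` = 0.34 and resting venous volume fraction
#' `V0` = 0.02. Region-specific hemodynamics are deliberately out of scope;
#' the same parameters drive every region.
#'
#' @param kappa,gamma_h,tau_h,alpha,rho,V0 see Description.
#' @return an object of class `hemodynamic_parameters`.
#' @export
hemodynamic_parameters <- function(kappa = 0.65, gamma_h = 0.41, tau_h = 0.98,
                                   alpha = 0.32, rho = 0.34, V0 = 0.02) {
  vals <- c(kappa = kappa, gamma_h = gamma_h, tau_h = tau_h,
            alpha = alpha, rho = rho, V0 = V0)
  if (any(vals <= 0)) stop("all hemodynamic parameters must be positive")
  if (alpha >= 1) stop("alpha must lie in (0, 1)")
  if (rho >= 1) stop("rho must lie in (0, 1)")
  structure(as.list(vals), class = "hemodynamic_parameters")
}

#' Convert neural activity to BOLD
#'
#' Integrates the four-state Balloon-Windkessel system (vasodilatory signal,
#' blood inflow, venous volume, deoxyhemoglobin) independently per region,
#' driven by the supplied activity series, and samples the resulting BOLD
#' signal on the `tr` grid. Deterministic given its input.
#'
#' @param activity matrix of neural drive (rows = time at fixed `dt`,
#'   columns = regions), typically the synaptic gating series of a
#'   [simulate_circuit()] run.
#' @param hparams a [hemodynamic_parameters()] object.
#' @param dt sampling step of `activity`, s.
#' @param tr output sampling period, s (must be >= `dt`).
#' @param discard initial output span to drop, s (hemodynamic transient from
#'   the resting initial state; default 0).
#' @return list with `times` (s) and `bold` (matrix, one column per region).
#' @export
bold_from_activity <- function(activity, hparams = hemodynamic_parameters(),
                               dt, tr, discard = 0) {
  activity <- as.matrix(activity)
  if (tr < dt) stop("tr must be at least dt")
  res <- balloon_bold_cpp(activity, dt, tr, hparams$kappa, hparams$gamma_h,
                          hparams$tau_h, hparams$alpha, hparams$rho, hparams$V0)
  if (isTRUE(res$diverged)) {
    stop("hemodynamic integration diverged at time index ", res$step,
         " (region ", res$region, ")")
  }
  bold <- res$bold
  colnames(bold) <- colnames(activity)
  times <- as.numeric(res$times)
  if (discard > 0) {
    keep <- times >= discard
    bold <- bold[keep, , drop = FALSE]
    times <- times[keep]
  }
  list(times = times, bold = bold)
}

# Algebraic steady state of the hemodynamic system under constant drive z.
# Used internally and as a reference for diagnostics; tests check the
# integrator against an independent root-finding oracle instead.
balloon_steady_state <- function(z, hparams = hemodynamic_parameters()) {
  f <- 1 + z / hparams$gamma_h
  v <- f^hparams$alpha
  E <- 1 - (1 - hparams$rho)^(1 / f)
  q <- f * E / hparams$rho * v^(1 - 1 / hparams$alpha)
  k1 <- 7 * hparams$rho; k2 <- 2; k3 <- 2 * hparams$rho - 0.2
  bold <- hparams$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
  c(s = 0, f = f, v = v, q = q, bold = bold)
}
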