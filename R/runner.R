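#' Build a theta-to-FC model runner
#'
#' Closes over a topology, simulation settings and hemodynamic parameters and
#' returns a `function(theta, seed, n_rep)` mapping a named parameter vector
#' to simulated FC: the stochastic circuit is integrated, the gating series
#' drives the Balloon-Windkessel model (the default drive; a firing-rate
#' drive is available via `drive`), BOLD is sampled at the TR, an initial
#' hemodynamic transient is discarded and pairwise Pearson correlations are
#' taken in canonical edge order. One row per repetition; repetitions use
#' consecutive derived seeds.
#'
#' Desk-scale defaults (`dt` = 1 ms, 200 s of simulated time after a 20 s
#' burn-in) keep a single evaluation in the low tens of milliseconds so that
#' ABC fits and cohort builds stay tractable; the step-size convergence
#' property guards the coarser step.
#'
#' @param topology a [circuit_topology()].
#' @param config a [simulation_config()]; its `seed` is ignored (the runner
#'   seed is per call).
#' @param hparams [hemodynamic_parameters()].
#' @param fixed named list of global constants overriding the
#'   [model_parameters()] defaults (entries of `theta` still win for
#'   `sigma`).
#' @param drive `"gating"` (default) or `"rate"`: the neural series handed
#'   to the hemodynamic stage.
#' @param hemo_discard initial BOLD span dropped, s.
#' @return a function `(theta, seed, n_rep = 1)` returning an
#'   `n_rep x n_edges` FC matrix.
#' @export
fc_model_runner <- function(topology,
                            config = simulation_config(dt = 1e-3,
                                                       duration = 220,
                                                       burn_in = 20),
                            hparams = hemodynamic_parameters(),
                            fixed = list(),
                            drive = c("gating", "rate"),
                            hemo_discard = 20) {
  drive <- match.arg(drive)
  labs <- canonical_edge_order(topology$regions)
  force(config); force(hparams); force(fixed)
  function(theta, seed, n_rep = 1) {
    params <- do.call(params_from_theta,
                      c(list(topology = topology, theta = theta), fixed))
    out <- matrix(NA_real_, n_rep, length(labs),
                  dimnames = list(NULL, labs))
    for (r in seq_len(n_rep)) {
      cfg <- config
      cfg$seed <- (seed + r - 1L) %% 2147483647L
      tr_set <- simulate_circuit(params, topology, cfg)
      act <- if (drive == "gating") {
        tr_set$S
      } else {
        x <- tr_set$S %*% t(skeleton_matrix(params)) + params$I_0
        dyn <- dynamic_edges(topology)
        for (e in seq_len(nrow(dyn))) {
          ij <- edge_index(topology, dyn$label[e])
          x[, ij["target"]] <- x[, ij["target"]] +
            params$G * params$J_N *
            (tr_set$C_tilde[, e] - params$C[ij["target"], ij["source"]]) *
            tr_set$S[, ij["source"]]
        }
        matrix(transfer_function(as.numeric(x), params), nrow(x),
               dimnames = dimnames(tr_set$S))
      }
      bb <- bold_from_activity(act, hparams, dt = cfg$record_dt, tr = cfg$tr,
                               discard = hemo_discard)
      out[r, ] <- compute_fc(bb$bold)
    }
    out
  }
}
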