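# Deterministic-skeleton analysis: equilibria, stability, saddle-node folds,
# regime classification, and the stochastic transition-rate / FC maps.

# H and dH/dx, vectorised, with series handling of the removable singularity.
h_and_deriv <- function(x, params) {
  u <- params$a * x - params$b
  t <- params$d * u
  H <- ifelse(abs(t) < 1e-6,
              (1 / params$d) * (1 + t / 2 + t^2 / 12),
              u / (1 - exp(-t)))
  dHdu <- ifelse(abs(t) < 1e-6,
                 0.5 + t / 6,
                 {
                   em <- exp(-t)
                   (1 - em - t * em) / (1 - em)^2
                 })
  list(H = H, dHdx = params$a * dHdu)
}

# Frozen effective coupling matrix of the deterministic skeleton
# (dynamic couplings held at their means).
skeleton_matrix <- function(params) {
  params$w * params$J_N * diag(nrow(params$C)) + params$G * params$J_N * params$C
}

# Drift for a batch of states (rows of Smat), using x = M S + I_0.
drift_batch <- function(Smat, M, params) {
  X <- Smat %*% t(M) + params$I_0
  hd <- h_and_deriv(X, params)
  list(D = -Smat / params$tau_S + (1 - Smat) * params$gamma * hd$H,
       H = hd$H, dHdx = hd$dHdx, X = X)
}

# Batched damped Newton refinement of equilibrium candidates, with a
# backtracking line search (a step is only accepted where it does not
# increase the residual; otherwise it is halved, and a point that cannot
# improve stalls and is filtered by the caller's residual check).
# Analytic Jacobian: J_ik = -delta_ik (1/tau + gamma H_i)
#                          + (1 - S_i) gamma H'_i M_ik.
newton_batch <- function(Smat, M, params, maxit = 80, step_cap = 0.25) {
  n <- ncol(Smat)
  db <- drift_batch(Smat, M, params)
  normD <- apply(abs(db$D), 1, max)
  for (it in seq_len(maxit)) {
    if (max(normD, na.rm = TRUE) < 1e-13) break
    D <- db$D
    coef <- (1 - Smat) * params$gamma * db$dHdx    # P x n
    if (n == 2) {
      a11 <- -1 / params$tau_S - params$gamma * db$H[, 1] + coef[, 1] * M[1, 1]
      a12 <- coef[, 1] * M[1, 2]
      a21 <- coef[, 2] * M[2, 1]
      a22 <- -1 / params$tau_S - params$gamma * db$H[, 2] + coef[, 2] * M[2, 2]
      det <- a11 * a22 - a12 * a21
      det[abs(det) < 1e-14] <- NA
      d1 <- (a22 * D[, 1] - a12 * D[, 2]) / det
      d2 <- (a11 * D[, 2] - a21 * D[, 1]) / det
      step <- cbind(d1, d2)
    } else {
      step <- matrix(NA_real_, nrow(Smat), n)
      for (p in seq_len(nrow(Smat))) {
        J <- -diag(1 / params$tau_S + params$gamma * db$H[p, ], n) +
          coef[p, ] * M
        s <- tryCatch(solve(J, D[p, ]), error = function(e) rep(NA_real_, n))
        step[p, ] <- s
      }
    }
    step[!is.finite(step)] <- 0
    nrm <- sqrt(rowSums(step^2))
    scl <- ifelse(nrm > step_cap, step_cap / nrm, 1)
    lam <- rep(1, nrow(Smat))
    for (bt in 1:5) {
      Snew <- Smat - step * (scl * lam)
      dbn <- drift_batch(Snew, M, params)
      nn <- apply(abs(dbn$D), 1, max)
      worse <- is.na(nn) | nn > normD
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    accept <- !is.na(nn) & nn <= normD
    Smat[accept, ] <- Snew[accept, ]
    db <- drift_batch(Smat, M, params)
    normD <- apply(abs(db$D), 1, max)
  }
  Smat
}

# Jacobian of the drift field at a single state.
drift_jacobian <- function(S, M, params) {
  x <- as.numeric(M %*% S) + params$I_0
  hd <- h_and_deriv(x, params)
  -diag(1 / params$tau_S + params$gamma * hd$H, length(S)) +
    ((1 - S) * params$gamma * hd$dHdx) * M
}

#' Find equilibria of the deterministic circuit
#'
#' Locates all fixed points of the noise-free skeleton (dynamic couplings
#' frozen at their means) by dense multi-start Newton refinement over a grid
#' in the gating cube, followed by duplicate merging and a residual check.
#' Stability is read from the eigenvalues of the drift Jacobian.
#'
#' @param params a [model_parameters()] object.
#' @param topology matching topology (defaults to the one in `params`).
#' @param grid_res spacing of the multi-start grid in each gating dimension
#'   (default 0.02 for up to 3 regions, 0.1 above to bound the start count).
#' @param merge_tol two roots closer than this (max-norm) are merged.
#' @param residual_tol returned points must satisfy
#'   `max(abs(drift)) < residual_tol`.
#' @return data.frame with one row per equilibrium: gating values `S_*`,
#'   `stable` (logical), `max_re_eig`, `residual`.
#' @export
find_equilibria <- function(params, topology = params$topology,
                            grid_res = NULL, merge_tol = 1e-4,
                            residual_tol = 1e-8) {
  n <- length(topology$regions)
  if (is.null(grid_res)) grid_res <- if (n <= 3) 0.02 else 0.1
  M <- skeleton_matrix(params)
  axes <- rep(list(seq(0, 1, by = grid_res)), n)
  starts <- as.matrix(expand.grid(axes))
  roots <- newton_batch(starts, M, params)
  db <- drift_batch(roots, M, params)
  ok <- rowSums(!is.finite(roots)) == 0 &
    apply(abs(db$D), 1, max) < residual_tol &
    apply(roots, 1, function(r) all(r > -1e-6 & r < 1 + 1e-6))
  roots <- roots[ok, , drop = FALSE]
  if (nrow(roots) == 0) {
    warning("no equilibrium found: solver failed from every start")
    out <- as.data.frame(matrix(numeric(0), 0, n))
    names(out) <- paste0("S_", topology$regions)
    out$stable <- logical(0); out$max_re_eig <- numeric(0)
    out$residual <- numeric(0)
    return(out)
  }
  roots <- pmin(pmax(roots, 0), 1)
  key <- apply(round(roots / merge_tol), 1, paste, collapse = "/")
  uniq <- !duplicated(key)
  roots <- roots[uniq, , drop = FALSE]
  # merge near-duplicates that rounded into adjacent cells
  keep <- rep(TRUE, nrow(roots))
  for (i in seq_len(nrow(roots))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(roots))) {
      if (j <= i || !keep[j]) next
      if (max(abs(roots[i, ] - roots[j, ])) < 2 * merge_tol) keep[j] <- FALSE
    }
  }
  roots <- roots[keep, , drop = FALSE]
  res <- apply(roots, 1, function(r) max(abs(drift_field(r, params$C, params))))
  eigs <- apply(roots, 1, function(r) {
    max(Re(eigen(drift_jacobian(r, M, params), only.values = TRUE)$values))
  })
  out <- as.data.frame(roots)
  names(out) <- paste0("S_", topology$regions)
  out$stable <- eigs < 0
  out$max_re_eig <- eigs
  out$residual <- res
  out[order(rowMeans(roots)), , drop = FALSE]
}

#' Classify the dynamical regime
#'
#' Labels the deterministic skeleton as `monostable-low`, `monostable-high`
#' or `bistable` from the number of stable equilibria and the gating level of
#' the stable branch (threshold 0.5 between the low and high branches). More
#' than three equilibria are reported as `unclassified` rather than silently
#' labelled.
#'
#' @inheritParams find_equilibria
#' @param ... passed to [find_equilibria()].
#' @return character label.
#' @export
classify_regime <- function(params, topology = params$topology, ...) {
  eq <- find_equilibria(params, topology, ...)
  n_stable <- sum(eq$stable)
  if (nrow(eq) > 3 || n_stable > 2) {
    warning("found ", nrow(eq), " equilibria (", n_stable,
            " stable): regime unclassified")
    return("unclassified")
  }
  if (n_stable >= 2) return("bistable")
  if (n_stable == 1) {
    lev <- mean(as.numeric(eq[eq$stable, seq_along(topology$regions)][1, ]))
    return(if (lev < 0.5) "monostable-low" else "monostable-high")
  }
  "unclassified"
}

#' Sweep a coupling and track equilibria (bifurcation scan)
#'
#' Tracks all equilibria over a monotone grid of one edge's mean coupling and
#' localises fold (saddle-node) points by bisection wherever the equilibrium
#' count changes by two between neighbouring grid values.
#'
#' @param params baseline [model_parameters()].
#' @param topology matching topology.
#' @param edge edge label to sweep (e.g. `"C_12"`).
#' @param grid monotone numeric vector of coupling values.
#' @param fold_tol bisection stops when the bracket is narrower than this.
#' @param ... passed to [find_equilibria()].
#' @return list of class `bifurcation_branch`: `edge`, `grid`, `equilibria`
#'   (list of data.frames per grid value), `counts`, and `folds` (data.frame
#'   with bracketing values and the localised fold point).
#' @export
bifurcation_scan <- function(params, topology = params$topology, edge, grid,
                             fold_tol = 1e-3, ...) {
  dg <- diff(grid)
  if (length(grid) < 2 || !(all(dg > 0) || all(dg < 0))) {
    stop("grid must be monotone")
  }
  ij <- edge_index(topology, edge)
  at_value <- function(v) {
    p <- params
    p$C[ij["target"], ij["source"]] <- v
    find_equilibria(p, topology, ...)
  }
  eqs <- lapply(grid, at_value)
  counts <- vapply(eqs, nrow, integer(1))
  folds <- data.frame(lower = numeric(0), upper = numeric(0),
                      location = numeric(0), count_change = integer(0))
  for (i in seq_len(length(grid) - 1)) {
    dc <- counts[i + 1] - counts[i]
    if (abs(dc) == 2) {
      lo <- grid[i]; hi <- grid[i + 1]
      c_lo <- counts[i]
      while (abs(hi - lo) > fold_tol) {
        mid <- (lo + hi) / 2
        if (nrow(at_value(mid)) == c_lo) lo <- mid else hi <- mid
      }
      folds <- rbind(folds, data.frame(lower = min(lo, hi),
                                       upper = max(lo, hi),
                                       location = (lo + hi) / 2,
                                       count_change = dc))
    }
  }
  structure(list(edge = edge, grid = grid, equilibria = eqs,
                 counts = counts, folds = folds),
            class = "bifurcation_branch")
}

#' @export
print.bifurcation_branch <- function(x, ...) {
  cat("Bifurcation scan over ", x$edge, " in [", min(x$grid), ", ",
      max(x$grid), "]: equilibrium counts ",
      paste(range(x$counts), collapse = "-"), ", ",
      nrow(x$folds), " fold(s)", sep = "")
  if (nrow(x$folds)) {
    cat(" at ", paste(signif(x$folds$location, 4), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Zero-crossing transition rate
#'
#' Counts sign changes between consecutive samples of a coupling series,
#' normalised per minute of recording. Exact zeros inherit the previous
#' sample's sign so that only genuine sign reversals are counted; an all-zero
#' series has rate 0 (flagged with a warning).
#'
#' @param coupling_series numeric vector.
#' @param sample_period spacing between samples, s.
#' @return crossings per minute.
#' @export
transition_rate <- function(coupling_series, sample_period) {
  x <- as.numeric(coupling_series)
  if (length(x) < 2) stop("series must have at least 2 samples")
  s <- sign(x)
  if (all(s == 0)) {
    warning("constant-zero series: transition rate defined as 0")
    return(0)
  }
  # zeros carry the previous sign; leading zeros take the first nonzero sign
  first_nz <- which(s != 0)[1]
  if (first_nz > 1) s[seq_len(first_nz - 1)] <- s[first_nz]
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  crossings <- sum(s[-1] != s[-length(s)])
  minutes <- length(x) * sample_period / 60
  crossings / minutes
}

#' Map functional connectivity and transition rate over (drift, volatility)
#'
#' For every cell of the (eta, sigma) grid, simulates the stochastic
#' two-region (or larger) circuit with those values on every dynamic edge,
#' converts gating to BOLD, and records (i) the Pearson correlation between
#' the first two regions and (ii) the zero-crossing rate of the first dynamic
#' coupling. Seeds are fixed per cell (`seed + cell index`) so the maps are
#' reproducible.
#'
#' @param params baseline [model_parameters()].
#' @param topology matching topology (must have at least one dynamic edge).
#' @param eta_grid,sigma_grid numeric vectors of drift and volatility values.
#' @param config a [simulation_config()] (desk-scale defaults recommended:
#'   `dt = 1e-3`, a few minutes of simulated time).
#' @param hparams hemodynamic parameters for the BOLD stage.
#' @param seed base seed.
#' @return list with matrices `fc` and `rate` (rows = eta, cols = sigma) and
#'   the grids; failed cells carry `NA` and a warning.
#' @export
sweep_noise_maps <- function(params, topology = params$topology,
                             eta_grid, sigma_grid,
                             config = simulation_config(dt = 1e-3,
                                                        duration = 200,
                                                        burn_in = 20),
                             hparams = hemodynamic_parameters(),
                             seed = 1L) {
  dyn <- dynamic_edges(topology)
  if (nrow(dyn) == 0) stop("topology has no dynamic edge to sweep")
  fc <- rate <- matrix(NA_real_, length(eta_grid), length(sigma_grid),
                       dimnames = list(eta = signif(eta_grid, 4),
                                       sigma = signif(sigma_grid, 4)))
  cell <- 0L
  for (i in seq_along(eta_grid)) {
    for (j in seq_along(sigma_grid)) {
      cell <- cell + 1L
      p <- params
      p$eta[] <- eta_grid[i]
      p$sigma_coupling[] <- sigma_grid[j]
      cfg <- config
      cfg$seed <- seed + cell
      tr_set <- tryCatch(simulate_circuit(p, topology, cfg),
                         error = function(e) {
                           warning("cell (", i, ",", j, ") failed: ",
                                   conditionMessage(e))
                           NULL
                         })
      if (is.null(tr_set)) next
      bb <- bold_from_activity(tr_set$S, hparams, dt = cfg$record_dt,
                               tr = cfg$tr, discard = 20)
      fc[i, j] <- stats::cor(bb$bold[, 1], bb$bold[, 2])
      rate[i, j] <- transition_rate(tr_set$C_tilde[, 1], cfg$record_dt)
    }
  }
  list(fc = fc, rate = rate, eta_grid = eta_grid, sigma_grid = sigma_grid)
}
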