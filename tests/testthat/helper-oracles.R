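# Independent oracles used to check the implementation by brute force on
# small instances, plus small shared fixtures.

# Brute-force equilibrium count for a 2-region deterministic skeleton:
# scan a fine grid and flag cells where both drift components change sign
# among the cell corners, merge adjacent flagged cells into clusters, and
# keep only clusters whose boundary carries a non-zero winding number of the
# drift field (near-misses of the two nullclines wind zero times).
brute_force_equilibria_2d <- function(params, res = 0.004) {
  g <- seq(0, 1, by = res)
  n <- length(g)
  D1 <- matrix(NA_real_, n, n)
  D2 <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- drift_field(c(g[i], g[j]), params$C, params)
      D1[i, j] <- d[1]; D2[i, j] <- d[2]
    }
  }
  cell_flag <- matrix(FALSE, n - 1, n - 1)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n - 1)) {
      c1 <- c(D1[i, j], D1[i + 1, j], D1[i, j + 1], D1[i + 1, j + 1])
      c2 <- c(D2[i, j], D2[i + 1, j], D2[i, j + 1], D2[i + 1, j + 1])
      cell_flag[i, j] <- (min(c1) < 0 && max(c1) > 0 &&
                            min(c2) < 0 && max(c2) > 0)
    }
  }
  # group flagged cells into connected clusters (8-neighbourhood flood fill)
  visited <- matrix(FALSE, n - 1, n - 1)
  clusters <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n - 1)) {
      if (!cell_flag[i, j] || visited[i, j]) next
      members <- list()
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > n - 1 || p[2] > n - 1) next
        if (visited[p[1], p[2]] || !cell_flag[p[1], p[2]]) next
        visited[p[1], p[2]] <- TRUE
        members <- c(members, list(p))
        for (di in -1:1) for (dj in -1:1) {
          if (di || dj) stack <- c(stack, list(p + c(di, dj)))
        }
      }
      clusters <- c(clusters, list(do.call(rbind, members)))
    }
  }
  # winding number of the drift field around each cluster centre
  winding <- vapply(clusters, function(m) {
    cx <- g[round(mean(m[, 1]))] + res / 2
    cy <- g[round(mean(m[, 2]))] + res / 2
    r <- max(3 * res, res * (max(m[, 1]) - min(m[, 1]) + 2) / 2,
             res * (max(m[, 2]) - min(m[, 2]) + 2) / 2)
    th <- seq(0, 2 * pi, length.out = 129)
    ang <- vapply(th, function(t) {
      d <- drift_field(c(cx + r * cos(t), cy + r * sin(t)), params$C, params)
      atan2(d[2], d[1])
    }, numeric(1))
    dd <- diff(ang)
    dd <- ifelse(dd > pi, dd - 2 * pi, ifelse(dd < -pi, dd + 2 * pi, dd))
    round(sum(dd) / (2 * pi))
  }, numeric(1))
  sum(winding != 0)
}

# Brute-force Mann-Whitney U (pairs with x < y, ties half) and AUC.
brute_force_auc_less <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi < yi) + 0.5 * (xi == yi)
  u / (length(x) * length(y))
}

# Brute-force 1-Wasserstein via exhaustive assignment enumeration
# (equal sample sizes, n <= 6): minimal mean absolute difference over all
# pairings, which is the optimal-transport solution for W1 on the line.
brute_force_w1 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  best <- Inf
  for (p in perms(seq_along(b))) {
    best <- min(best, mean(abs(a - b[p])))
  }
  best
}

# Brute-force Wilcoxon signed-rank statistic (sum of ranks of |d| over
# positive differences; zeros dropped, ties mid-ranked).
brute_force_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

# Fixtures ------------------------------------------------------------------

two_region_static_params <- function(c12, c21 = c12) {
  topo <- two_region_topology()
  model_parameters(topo, C = c(C_12 = c12, C_21 = c21),
                   eta = c(C_12 = 0), sigma_coupling = c(C_12 = 0))
}

bistable_two_region_params <- function(eta = 0.05, sigma_coupling = 0.25,
                                       sigma_node = 0.1) {
  topo <- two_region_topology()
  model_parameters(topo, C = c(C_12 = 0.25, C_21 = 0.25),
                   eta = c(C_12 = eta), sigma_coupling = c(C_12 = sigma_coupling),
                   sigma_node = sigma_node)
}

# A cheap analytic stand-in for the simulator in machinery tests: maps theta
# linearly to a 6-edge FC vector plus seeded noise. Exercises the ABC /
# intervention plumbing without SDE integration.
linear_fc_runner <- function(topology = canonical_topology(), noise_sd = 0.02) {
  labs <- canonical_edge_order(topology$regions)
  function(theta, seed, n_rep = 1) {
    set.seed(seed %% 2147483647)
    base <- c(theta[["C_OA"]], 0.5 * theta[["C_AP"]], 0.3 * theta[["C_PA"]],
              0.5 * theta[["C_OL"]] + 0.3 * theta[["C_LO"]],
              0.2 * theta[["C_AO"]], 0.5 * theta[["C_PL"]] + theta[["C_LP"]])
    out <- matrix(rep(base, each = n_rep), n_rep) +
      matrix(stats::rnorm(n_rep * 6, 0, noise_sd), n_rep)
    colnames(out) <- labs
    pmin(pmax(out, -1), 1)
  }
}
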