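# Digital-twin analysis: pair empirical subjects to their nearest simulations
# in FC space and relate the twins' hidden parameter changes to symptom
# changes.

#' Pair subjects to their digital twins
#'
#' Exact nearest-neighbour search under the Euclidean FC distance: every
#' subject is paired to the simulation in the library whose FC vector is
#' closest; ties are broken by the lowest simulation index.
#'
#' @param subjects_fc matrix of subject FC vectors (rows = subjects).
#' @param library_fc matrix of simulated FC vectors (rows = simulations),
#'   same edge ordering.
#' @param library_theta optional matrix of the simulations' parameters; the
#'   matched rows are returned.
#' @param subject_ids optional identifiers.
#' @return object of class `twin_pairs`: data.frame `pairs` (subject,
#'   sim_index, distance) and matrix `theta` of matched parameters (or NULL).
#' @export
pair_twins <- function(subjects_fc, library_fc, library_theta = NULL,
                       subject_ids = NULL) {
  subjects_fc <- as.matrix(subjects_fc)
  library_fc <- as.matrix(library_fc)
  if (nrow(library_fc) == 0) stop("empty simulation library")
  if (ncol(subjects_fc) != ncol(library_fc)) {
    stop("subjects and library must share the edge ordering")
  }
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(subjects_fc))
  lib_sq <- rowSums(library_fc^2)
  idx <- integer(nrow(subjects_fc))
  dst <- numeric(nrow(subjects_fc))
  for (i in seq_len(nrow(subjects_fc))) {
    d2 <- lib_sq - 2 * as.numeric(library_fc %*% subjects_fc[i, ]) +
      sum(subjects_fc[i, ]^2)
    idx[i] <- which.min(d2)   # which.min returns the first (lowest) index
    dst[i] <- sqrt(max(0, d2[idx[i]]))
  }
  theta <- if (!is.null(library_theta)) {
    as.matrix(library_theta)[idx, , drop = FALSE]
  }
  structure(list(pairs = data.frame(subject = subject_ids, sim_index = idx,
                                    distance = dst),
                 theta = theta),
            class = "twin_pairs")
}

#' @export
print.twin_pairs <- function(x, ...) {
  cat("Digital-twin pairing: ", nrow(x$pairs), " subjects, median distance ",
      signif(stats::median(x$pairs$distance), 3), "\n", sep = "")
  invisible(x)
}

#' Parameter changes between twin sessions
#'
#' Computes per-subject parameter changes `theta_post - theta_pre` between
#' the baseline and follow-up twin pairings, and tests each parameter for a
#' time effect with a two-sided paired Wilcoxon signed-rank test
#' (family-wise corrected). Subjects present in only one session are
#' excluded (and reported).
#'
#' @param pairs_pre,pairs_post [pair_twins()] results with `theta`.
#' @param method multiplicity correction.
#' @return list of class `twin_change`: `delta` (matrix of changes),
#'   `tests` (data.frame per parameter), `excluded` (subject ids).
#' @export
twin_parameter_change <- function(pairs_pre, pairs_post,
                                  method = "bonferroni") {
  if (is.null(pairs_pre$theta) || is.null(pairs_post$theta)) {
    stop("twin pairings must carry matched parameters")
  }
  common <- intersect(pairs_pre$pairs$subject, pairs_post$pairs$subject)
  excluded <- setdiff(union(pairs_pre$pairs$subject, pairs_post$pairs$subject),
                      common)
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " subject(s) present in only one session")
  }
  ia <- match(common, pairs_pre$pairs$subject)
  ib <- match(common, pairs_post$pairs$subject)
  delta <- pairs_post$theta[ib, , drop = FALSE] -
    pairs_pre$theta[ia, , drop = FALSE]
  rownames(delta) <- common
  tests <- lapply(colnames(delta), function(p) {
    d <- delta[, p]
    if (all(d == 0)) {
      return(data.frame(parameter = p, V = NA_real_, p = NA_real_,
                        median_delta = 0, no_change = TRUE))
    }
    wt <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
    data.frame(parameter = p, V = unname(wt$statistic), p = wt$p.value,
               median_delta = stats::median(d), no_change = FALSE)
  })
  tests <- do.call(rbind, tests)
  tests$p_fwe <- stats::p.adjust(tests$p, method = method)
  structure(list(delta = delta, tests = tests, excluded = excluded),
            class = "twin_change")
}

#' Association between parameter changes and symptom changes
#'
#' Per-parameter dot product between z-scored parameter changes and symptom
#' changes across subjects. Deliberately no mean-centreing before the
#' product: the sign of the result keeps its interpretation (a positive
#' score means parameter increases co-occur with symptom-score increases).
#'
#' @param delta_theta_z matrix of z-scored parameter changes (rows =
#'   subjects).
#' @param delta_symptoms numeric vector of symptom changes, same subject
#'   order.
#' @return named numeric vector of association scores.
#' @export
symptom_association <- function(delta_theta_z, delta_symptoms) {
  delta_theta_z <- as.matrix(delta_theta_z)
  if (nrow(delta_theta_z) != length(delta_symptoms)) {
    stop("subject ordering mismatch")
  }
  colSums(delta_theta_z * delta_symptoms)
}

#' Z-score twin parameter changes against the baseline twins
#'
#' Normalises per-subject parameter changes by the mean and standard
#' deviation of the baseline-session twin parameters across subjects.
#'
#' @param twin_change a [twin_parameter_change()] result.
#' @param pairs_pre the baseline [pair_twins()] result.
#' @return matrix of z-scored changes.
#' @export
zscore_twin_delta <- function(twin_change, pairs_pre) {
  sd0 <- apply(pairs_pre$theta, 2, stats::sd)
  if (any(sd0 == 0)) {
    stop("zero baseline SD for parameter(s): ",
         paste(colnames(pairs_pre$theta)[sd0 == 0], collapse = ", "))
  }
  sweep(twin_change$delta, 2, sd0, "/")
}

#' Correlation between FC change and symptom change
#'
#' Pearson correlation with a two-sided test and a bootstrap percentile 95%
#' confidence interval (default 1000 resamples, seeded).
#'
#' @param delta_fc_scalar per-subject scalar FC change.
#' @param delta_symptoms per-subject symptom change.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return list with `r`, `p`, `ci` (length 2), `n`.
#' @export
fc_symptom_correlation <- function(delta_fc_scalar, delta_symptoms,
                                   n_boot = 1000, seed = 1L) {
  x <- as.numeric(delta_fc_scalar); y <- as.numeric(delta_symptoms)
  if (length(x) != length(y)) stop("paired observations required")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables")
  }
  ct <- stats::cor.test(x, y)
  if (!is.null(seed)) set.seed(seed)
  rb <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(x), replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i])
  }, numeric(1))
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = unname(stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE)),
       n = length(x))
}

#' Scalar FC change towards the control mean
#'
#' The default operational definition of the per-subject "change in FC" used
#' against symptom changes: the baseline-minus-follow-up change in Euclidean
#' distance between the subject's FC vector and the control-group mean FC
#' vector (positive = moved closer to controls).
#'
#' @param fc_pre,fc_post matrices of subject FC at the two sessions.
#' @param control_mean_fc control-group mean FC vector.
#' @return numeric vector of per-subject scalar changes.
#' @export
fc_change_towards_controls <- function(fc_pre, fc_post, control_mean_fc) {
  fc_pre <- as.matrix(fc_pre); fc_post <- as.matrix(fc_post)
  stopifnot(nrow(fc_pre) == nrow(fc_post),
            ncol(fc_pre) == length(control_mean_fc))
  d_pre <- sqrt(rowSums(sweep(fc_pre, 2, control_mean_fc)^2))
  d_post <- sqrt(rowSums(sweep(fc_post, 2, control_mean_fc)^2))
  d_pre - d_post
}
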