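# Functional connectivity vectors and distances between subjects and cohorts.

#' Canonical edge order for FC vectors
#'
#' The whole pipeline uses one fixed ordering of region pairs so that FC
#' vectors are comparable across modules and files. For the canonical
#' four-region topology the order is NAcc-OFC, NAcc-LPFC, NAcc-dPut,
#' OFC-LPFC, OFC-dPut, LPFC-dPut; for any other region set, pairs are taken
#' in the order the regions are listed.
#'
#' @param regions character vector of region labels.
#' @return character vector of `length n(n-1)/2` edge labels (`"A-B"`).
#' @export
canonical_edge_order <- function(regions) {
  canon <- c("OFC", "LPFC", "NAcc", "dPut")
  if (setequal(regions, canon)) {
    return(c("NAcc-OFC", "NAcc-LPFC", "NAcc-dPut",
             "OFC-LPFC", "OFC-dPut", "LPFC-dPut"))
  }
  pairs <- utils::combn(regions, 2)
  paste(pairs[1, ], pairs[2, ], sep = "-")
}

fc_pair_indices <- function(regions) {
  labs <- canonical_edge_order(regions)
  do.call(rbind, lapply(strsplit(labs, "-", fixed = TRUE), function(p) {
    c(match(p[1], regions), match(p[2], regions))
  }))
}

#' Compute a functional-connectivity vector
#'
#' Pairwise Pearson correlations between regional BOLD series, in the
#' canonical edge order.
#'
#' @param bold matrix (rows = time, columns = regions, named).
#' @param regions region labels; defaults to `colnames(bold)`.
#' @return named numeric vector of class `fc_vector`.
#' @export
compute_fc <- function(bold, regions = colnames(bold)) {
  bold <- as.matrix(bold)
  if (is.null(regions)) stop("bold must have region column names")
  if (nrow(bold) < 3) stop("need at least 3 samples per region")
  sds <- apply(bold, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant series: correlation undefined for region(s) ",
         paste(regions[sds == 0], collapse = ", "))
  }
  idx <- fc_pair_indices(regions)
  labs <- canonical_edge_order(regions)
  cm <- stats::cor(bold)
  out <- vapply(seq_len(nrow(idx)), function(k) cm[idx[k, 1], idx[k, 2]],
                numeric(1))
  structure(stats::setNames(out, labs), class = "fc_vector")
}

#' @export
print.fc_vector <- function(x, ...) {
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' One-dimensional Wasserstein distance between samples
#'
#' The 1-Wasserstein (earth mover's) distance between the empirical
#' distributions of two samples, computed from the quantile functions. For
#' equal sizes this equals the mean absolute difference between the sorted
#' samples; unequal sizes use the general piecewise-constant quantile form.
#'
#' @param samples_a,samples_b non-empty numeric vectors.
#' @return non-negative distance.
#' @export
wasserstein_1d <- function(samples_a, samples_b) {
  if (!length(samples_a) || !length(samples_b)) stop("empty sample set")
  if (anyNA(samples_a) || anyNA(samples_b)) stop("samples must be finite")
  na <- length(samples_a); nb <- length(samples_b)
  sa <- sort(samples_a); sb <- sort(samples_b)
  if (na == nb) return(mean(abs(sa - sb)))
  u <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  w <- diff(c(0, u))
  qa <- sa[pmin(na, ceiling(u * na - 1e-9))]
  qb <- sb[pmin(nb, ceiling(u * nb - 1e-9))]
  sum(w * abs(qa - qb))
}

#' Assemble a cohort of FC vectors
#'
#' @param fc matrix of FC values (rows = subjects/simulations, columns =
#'   canonical edges, named) or a list of `fc_vector`s.
#' @param label group label.
#' @param theta optional matrix of the generating parameters per subject
#'   (used by the intervention contribution analysis).
#' @param subject_ids optional identifiers.
#' @return an object of class `fc_cohort`.
#' @export
fc_cohort <- function(fc, label = "cohort", theta = NULL, subject_ids = NULL) {
  if (is.list(fc) && !is.data.frame(fc)) fc <- do.call(rbind, fc)
  fc <- as.matrix(fc)
  if (is.null(colnames(fc))) stop("fc must have edge column names")
  if (!is.null(theta)) {
    theta <- as.matrix(theta)
    if (nrow(theta) != nrow(fc)) stop("theta must have one row per subject")
  }
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(fc))
  structure(list(label = label, fc = fc, theta = theta,
                 subject_ids = subject_ids),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat("FC cohort '", x$label, "': ", nrow(x$fc), " subjects x ",
      ncol(x$fc), " edges\n", sep = "")
  invisible(x)
}

#' Distance between two cohorts in FC space
#'
#' Sum over edges of the 1-Wasserstein distance between the per-edge
#' empirical FC distributions of the two cohorts:
#' `d(A, B) = sum_p W(A_p, B_p)`.
#'
#' @param a,b [fc_cohort()] objects with identical edge ordering.
#' @return non-negative distance.
#' @export
cohort_distance <- function(a, b) {
  if (!identical(colnames(a$fc), colnames(b$fc))) {
    stop("cohorts must share the same edge set and ordering")
  }
  sum(vapply(seq_len(ncol(a$fc)), function(p) {
    wasserstein_1d(a$fc[, p], b$fc[, p])
  }, numeric(1)))
}

#' Euclidean distance between two FC vectors
#'
#' @param x,y numeric FC vectors in the same edge order.
#' @return non-negative L2 distance.
#' @export
euclidean_fc_distance <- function(x, y) {
  if (length(x) != length(y)) stop("FC vectors must have the same length")
  if (!is.null(names(x)) && !is.null(names(y)) &&
      !identical(names(x), names(y))) {
    stop("FC vectors must share the same edge ordering")
  }
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}
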