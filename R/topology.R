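#' Define a circuit topology
#'
#' A topology names the modelled brain regions and the directed coupling edges
#' between them. Each edge is either `static` (a fixed coupling strength) or
#' `dynamic` (a mean-reverting stochastic coupling, used here for the
#' striato-cortical projections whose net effect fluctuates between excitation
#' and inhibition). Every edge carries uniform prior bounds on its mean
#' coupling strength, used both by the Bayesian fitting and by the
#' synthetic-data generator.
#'
#' @param regions character vector of region labels.
#' @param edges data.frame with columns `source`, `target`, `kind`
#'   (`"static"` or `"dynamic"`), `lower`, `upper` (dimensionless coupling
#'   bounds) and optionally `label` (defaults to `C_<ti><si>` built from the
#'   first letters of target and source).
#' @param name optional topology name.
#' @return an object of class `circuit_topology`.
#' @seealso [canonical_topology()], [two_region_topology()]
#' @export
circuit_topology <- function(regions, edges, name = "custom") {
  stopifnot(is.character(regions), length(regions) >= 2, !anyDuplicated(regions))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source", "target", "kind", "lower", "upper")
  if (!all(req %in% names(edges))) {
    stop("edges must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(edges$source %in% regions) || !all(edges$target %in% regions)) {
    stop("every edge must reference declared regions")
  }
  if (any(edges$source == edges$target)) {
    stop("edges must connect two distinct regions")
  }
  if (!all(edges$kind %in% c("static", "dynamic"))) {
    stop("edge kind must be 'static' or 'dynamic'")
  }
  if (any(edges$lower > edges$upper)) {
    stop("edge prior bounds must satisfy lower <= upper")
  }
  if (is.null(edges$label)) {
    edges$label <- paste0("C_", substr(edges$target, 1, 1), substr(edges$source, 1, 1))
  }
  if (anyDuplicated(edges$label)) stop("edge labels must be unique")
  structure(list(regions = regions, edges = edges, name = name),
            class = "circuit_topology")
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat("Circuit topology '", x$name, "': ", length(x$regions), " regions, ",
      nrow(x$edges), " edges (", sum(x$edges$kind == "dynamic"),
      " dynamic)\n", sep = "")
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %-6s %s -> %s  [%s]  prior [%g, %g]\n", e$label,
                e$source, e$target, e$kind, e$lower, e$upper))
  }
  invisible(x)
}

#' Canonical four-region frontostriatal topology
#'
#' The ventral (NAcc-OFC) and dorsal (dPut-LPFC) frontostriatal circuits with
#' lateral cortico-cortical and striato-striatal cross-couplings: eight
#' directed edges in total. The two striatum-to-cortex projections
#' (NAcc to OFC, dPut to LPFC) are dynamic; all other edges are static.
#' Prior bounds encode the biological assumptions: cortico-cortical and
#' cortico-striatal couplings are excitatory (bounds 0 to 0.5), while
#' striato-cortical means and striato-striatal couplings can take either sign
#' (bounds -0.5 to 0.5).
#'
#' @return a `circuit_topology` with regions OFC, LPFC, NAcc, dPut.
#' @export
canonical_topology <- function() {
  edges <- data.frame(
    source = c("LPFC", "OFC", "NAcc", "dPut", "OFC", "LPFC", "dPut", "NAcc"),
    target = c("OFC", "LPFC", "OFC", "LPFC", "NAcc", "dPut", "NAcc", "dPut"),
    kind   = c("static", "static", "dynamic", "dynamic",
               "static", "static", "static", "static"),
    lower  = c(0, 0, -0.5, -0.5, 0, 0, -0.5, -0.5),
    upper  = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    label  = c("C_OL", "C_LO", "C_OA", "C_LP", "C_AO", "C_PL", "C_AP", "C_PA"),
    stringsAsFactors = FALSE
  )
  circuit_topology(c("OFC", "LPFC", "NAcc", "dPut"), edges, name = "frontostriatal-4")
}

#' Two-region frontal-striatal circuit
#'
#' The reduced single-circuit system used for stability analysis: one frontal
#' and one striatal population, with a dynamic striato-cortical projection
#' (`C_12`) and a static cortico-striatal projection (`C_21`).
#'
#' @param dynamic logical; if `FALSE` the striato-cortical edge is static too
#'   (useful for the deterministic skeleton).
#' @return a `circuit_topology` with regions Frontal, Striatum.
#' @export
two_region_topology <- function(dynamic = TRUE) {
  edges <- data.frame(
    source = c("Striatum", "Frontal"),
    target = c("Frontal", "Striatum"),
    kind   = c(if (dynamic) "dynamic" else "static", "static"),
    lower  = c(-0.5, 0),
    upper  = c(0.5, 0.5),
    label  = c("C_12", "C_21"),
    stringsAsFactors = FALSE
  )
  circuit_topology(c("Frontal", "Striatum"), edges, name = "frontostriatal-2")
}

# Indices (target, source) of an edge label in the region ordering.
edge_index <- function(topology, label) {
  e <- topology$edges[topology$edges$label == label, ]
  if (nrow(e) != 1) stop("unknown edge label: ", label)
  c(target = match(e$target, topology$regions),
    source = match(e$source, topology$regions))
}

dynamic_edges <- function(topology) {
  topology$edges[topology$edges$kind == "dynamic", , drop = FALSE]
}
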