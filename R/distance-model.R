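#' Partition bead pairs by observed contact
#'
#' Splits all unordered off-diagonal bead pairs of a contact matrix into the
#' set C1 of pairs with a non-zero contact count and the complementary set C2
#' of pairs with zero contacts. The diagonal belongs to neither set.
#'
#' @param matrix A [contact_matrix()].
#' @return List with logical n-by-n matrices `c1_mask` and `c2_mask`; both
#'   are symmetric with a `FALSE` diagonal and together cover every
#'   off-diagonal pair exactly once.
#' @export
partition_contacts <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  c1 <- matrix$counts != 0
  diag(c1) <- FALSE
  c2 <- !c1
  diag(c2) <- FALSE
  list(c1_mask = c1, c2_mask = c2)
}

#' Convert Hi-C contacts to target spatial distances
#'
#' Applies the power-law conversion `delta_ij = beta * (1 / c_ij)^alpha` to
#' every pair in C1 (non-zero contacts). Pairs in C2 have no target distance;
#' the mask carries definedness (no sentinel values are stored).
#'
#' @param matrix A [contact_matrix()].
#' @param alpha Conversion exponent, default `1/3`.
#' @param beta Scale parameter, default `1`.
#' @return An object of class `target_distance_model` with fields `delta`
#'   (n-by-n, `NA` outside C1), `c1_mask`, `c2_mask`, `alpha`, `beta` and
#'   unset `r_scalar` / `r_matrix` slots for [max_distance_r()] /
#'   [shortest_path_r()].
#' @export
#' @examples
#' cm <- contact_matrix(matrix(c(0, 8, 8, 0), 2, 2))
#' m <- contacts_to_distances(cm)
#' m$delta[1, 2]  # (1/8)^(1/3) = 0.5
contacts_to_distances <- function(matrix, alpha = 1 / 3, beta = 1) {
  stopifnot(inherits(matrix, "contact_matrix"), alpha > 0, beta > 0)
  p <- partition_contacts(matrix)
  delta <- matrix(NA_real_, matrix$n_beads, matrix$n_beads)
  delta[p$c1_mask] <- beta * (1 / matrix$counts[p$c1_mask])^alpha
  structure(
    list(delta = delta, c1_mask = p$c1_mask, c2_mask = p$c2_mask,
         alpha = alpha, beta = beta, n_beads = matrix$n_beads,
         r_scalar = NULL, r_matrix = NULL),
    class = "target_distance_model"
  )
}

#' @export
print.target_distance_model <- function(x, ...) {
  cat("<target_distance_model> ", x$n_beads, " beads, alpha = ",
      signif(x$alpha, 4), ", beta = ", x$beta, "\n", sep = "")
  cat("  C1 pairs: ", sum(x$c1_mask[upper.tri(x$c1_mask)]),
      ", C2 pairs: ", sum(x$c2_mask[upper.tri(x$c2_mask)]), "\n", sep = "")
  if (!is.null(x$r_scalar)) cat("  R (max-distance) = ",
                                signif(x$r_scalar, 6), "\n", sep = "")
  if (!is.null(x$r_matrix)) cat("  R matrix (shortest-path) set\n")
  invisible(x)
}

contact_graph <- function(model) {
  edges <- which(model$c1_mask & upper.tri(model$c1_mask), arr.ind = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               weight = model$delta[edges]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(model$n_beads))
  )
}

#' Shortest-path target distance R for zero-contact pairs
#'
#' Treats each bead as a graph node, each C1 pair as an edge weighted by its
#' target distance, and computes all-pairs shortest-path distances. For a C1
#' pair the shortest path may undercut the direct edge; only C2 entries are
#' consumed by the corresponding objective function.
#'
#' @param model A `target_distance_model` from [contacts_to_distances()].
#' @return The model with `r_matrix` set (symmetric, zero diagonal).
#' @export
shortest_path_r <- function(model) {
  stopifnot(inherits(model, "target_distance_model"))
  g <- contact_graph(model)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("contact graph is disconnected (", comp$no,
         " components of sizes ", sizes,
         "); shortest-path R undefined across components. ",
         "Consider largest_connected_component() first.")
  }
  r <- igraph::distances(g, weights = igraph::E(g)$weight)
  ord <- as.integer(igraph::V(g)$name)
  r <- r[order(ord), order(ord)]
  dimnames(r) <- NULL
  model$r_matrix <- r
  model
}

#' Maximum target distance R for zero-contact pairs
#'
#' @param model A `target_distance_model` from [contacts_to_distances()].
#' @return The model with `r_scalar` set to the maximum target distance over
#'   all C1 pairs.
#' @export
max_distance_r <- function(model) {
  stopifnot(inherits(model, "target_distance_model"))
  if (!any(model$c1_mask)) stop("C1 is empty: no contacts to take a maximum over")
  model$r_scalar <- max(model$delta[model$c1_mask])
  model
}

#' Restrict a contact matrix to its largest connected component
#'
#' Beads outside the largest component of the contact graph (nodes = beads,
#' edges = non-zero contacts) are dropped. Useful before [shortest_path_r()]
#' or an Eq.-3-style objective, both of which require a connected graph.
#'
#' @param matrix A [contact_matrix()].
#' @return List with the reduced [contact_matrix()] (`matrix`) and the
#'   1-based indices of the retained beads (`kept`).
#' @export
largest_connected_component <- function(matrix) {
  p <- partition_contacts(matrix)
  edges <- which(p$c1_mask & upper.tri(p$c1_mask), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(matrix$n_beads)))
  comp <- igraph::components(g)
  keep <- sort(as.integer(igraph::V(g)$name[comp$membership ==
                                              which.max(comp$csize)]))
  list(matrix = contact_matrix(matrix$counts[keep, keep, drop = FALSE],
                               matrix$resolution, matrix$chrom,
                               matrix$start_offset),
       kept = keep)
}
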