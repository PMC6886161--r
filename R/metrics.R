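#' Per-bead masses under a named feature scheme
#'
#' In the feature-weighted radius of gyration, each bead's mass encodes how
#' much of a genetic/epigenetic feature it carries:
#' \describe{
#'   \item{`mass_unit`}{every bead has mass 1 (pure geometry).}
#'   \item{`mass_TSS`}{1 plus the number of transcription start sites in the
#'     bead.}
#'   \item{`mass_or`}{2 if the bead carries at least one of TSS, H3K4me3 or
#'     RNA polII peaks, else 1.}
#'   \item{`mass_and`}{1 plus the total number of TSS, H3K4me3 peaks and
#'     RNA polII peaks in the bead.}
#' }
#'
#' @param n_beads Number of beads.
#' @param scheme One of `"mass_unit"`, `"mass_TSS"`, `"mass_or"`,
#'   `"mass_and"`.
#' @param tss_counts,h3k4me3_counts,polii_counts Non-negative integer count
#'   vectors of length `n_beads`; only those a scheme uses are required.
#' @return Object of class `mass_vector` with fields `masses` (all `>= 1`),
#'   `scheme` and `total_mass`.
#' @export
assign_masses <- function(n_beads,
                          scheme = c("mass_unit", "mass_TSS", "mass_or",
                                     "mass_and"),
                          tss_counts = NULL, h3k4me3_counts = NULL,
                          polii_counts = NULL) {
  scheme <- match.arg(scheme)
  need <- function(v, nm) {
    if (is.null(v)) stop("scheme '", scheme, "' requires ", nm)
    if (length(v) != n_beads) stop(nm, " must have length ", n_beads)
    if (any(v < 0)) stop(nm, " must be non-negative")
    v
  }
  masses <- switch(scheme,
    mass_unit = rep(1, n_beads),
    mass_TSS = 1 + need(tss_counts, "tss_counts"),
    mass_or = {
      tot <- need(tss_counts, "tss_counts") +
        need(h3k4me3_counts, "h3k4me3_counts") +
        need(polii_counts, "polii_counts")
      ifelse(tot > 0, 2, 1)
    },
    mass_and = 1 + need(tss_counts, "tss_counts") +
      need(h3k4me3_counts, "h3k4me3_counts") +
      need(polii_counts, "polii_counts")
  )
  structure(list(masses = as.numeric(masses), scheme = scheme,
                 total_mass = sum(masses)),
            class = "mass_vector")
}

#' Mass-weighted center of a structure
#'
#' The point `R_C` with `sum_i m_i (x_i - R_C) = 0`, i.e. the mass-weighted
#' mean coordinate.
#'
#' @param structure A [structure3d()].
#' @param masses A `mass_vector` from [assign_masses()], or `NULL` for unit
#'   masses.
#' @return Length-3 numeric vector.
#' @export
center_of_mass <- function(structure, masses = NULL) {
  m <- if (is.null(masses)) rep(1, structure$n_beads) else masses$masses
  stopifnot(length(m) == structure$n_beads, all(m > 0))
  colSums(structure$coords * m) / sum(m)
}

#' Feature-mass-weighted radius of gyration
#'
#' `R_g = sqrt( sum_i m_i ||x_i - R_C||^2 / M )` with `R_C` the
#' mass-weighted center. By default `M = sum_i m_i`; with
#' `length_normalized = TRUE` the total mass is divided by the number of
#' beads, `M = sum_i m_i / n`, inflating `R_g` by `sqrt(n)` — both variants
#' are exposed because either reading of "total mass normalized by length"
#' is defensible.
#'
#' @inheritParams center_of_mass
#' @param length_normalized Divide total mass by the number of beads
#'   (default `FALSE`).
#' @return Non-negative scalar; 0 iff all beads coincide.
#' @export
#' @examples
#' s <- structure3d(rbind(c(0, 0, 0), c(2, 0, 0)))
#' radius_of_gyration(s)  # 1 = d/2 for two unit-mass beads
radius_of_gyration <- function(structure, masses = NULL,
                               length_normalized = FALSE) {
  stopifnot(structure$n_beads >= 2)
  m <- if (is.null(masses)) rep(1, structure$n_beads) else masses$masses
  rc <- center_of_mass(structure, masses)
  sq <- rowSums(sweep(structure$coords, 2, rc)^2)
  big_m <- if (length_normalized) sum(m) / structure$n_beads else sum(m)
  sqrt(sum(m * sq) / big_m)
}

#' Build a chain graph over the beads of a structure
#'
#' Adjacency of the path graph connecting consecutive beads, the level-0
#' input to [line_graph()].
#'
#' @param n_beads Number of beads (`>= 2`).
#' @return Object of class `line_graph_chain` with fields `level` (0),
#'   `adjacency` (0/1 symmetric) and `node_labels` (list of bead-index
#'   tuples).
#' @export
bead_chain_graph <- function(n_beads) {
  stopifnot(n_beads >= 2)
  adj <- matrix(0, n_beads, n_beads)
  idx <- seq_len(n_beads - 1)
  adj[cbind(idx, idx + 1)] <- 1
  adj[cbind(idx + 1, idx)] <- 1
  structure(list(level = 0L, adjacency = adj,
                 node_labels = as.list(seq_len(n_beads))),
            class = "line_graph_chain")
}

#' One iteration of the line-graph construction
#'
#' The line graph `L(G)` has one node per edge of `G`; two nodes are
#' adjacent when the corresponding edges share an endpoint. Node labels
#' concatenate the bead indices of the merged edges, so iterating from the
#' bead chain keeps track of which consecutive beads each node spans. The
#' line graph of a path on `n` nodes is a path on `n - 1` nodes.
#'
#' @param chain A `line_graph_chain` (from [bead_chain_graph()] or a prior
#'   [line_graph()] call); `level < 3`.
#' @return A `line_graph_chain` one level up.
#' @export
line_graph <- function(chain) {
  stopifnot(inherits(chain, "line_graph_chain"))
  if (chain$level >= 3) stop("line graph iterated at most 3 times")
  n <- nrow(chain$adjacency)
  if (n < 2) stop("graph with ", n, " node(s) has no edges: no line graph")
  e <- which(chain$adjacency == 1 & upper.tri(chain$adjacency),
             arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  m <- nrow(e)
  if (m == 0) stop("graph has no edges: no line graph")
  adj <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      if (length(intersect(e[a, ], e[b, ])) > 0) adj[a, b] <- 1
    }
  }
  labels <- lapply(seq_len(m), function(k) {
    sort(unique(c(chain$node_labels[[e[k, 1]]], chain$node_labels[[e[k, 2]]])))
  })
  structure(list(level = chain$level + 1L, adjacency = adj,
                 node_labels = labels),
            class = "line_graph_chain")
}

#' Dihedral angles along a bead chain
#'
#' Every three consecutive beads span a plane; consecutive planes meet at a
#' dihedral angle. Angle `k` is the unsigned angle in `[0, pi]` between the
#' normals of plane `(k, k+1, k+2)` and plane `(k+1, k+2, k+3)`; chirality
#' is discarded. A planar all-trans (zigzag) chain gives `pi` everywhere.
#'
#' @param structure A [structure3d()] with `n >= 4` beads.
#' @return Numeric vector of length `n - 3`.
#' @export
dihedral_angles <- function(structure) {
  x <- structure$coords
  n <- nrow(x)
  if (n < 4) stop("dihedral angles need at least 4 beads")
  u <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]  # bond vectors
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  normals <- lapply(seq_len(n - 2), function(k) cross(u[k, ], u[k + 1, ]))
  nn <- vapply(normals, function(v) sqrt(sum(v^2)), numeric(1))
  bad <- which(nn < 1e-12)
  if (length(bad) > 0) {
    stop("beads ", bad[1], "-", bad[1] + 2,
         " are collinear: dihedral angle undefined")
  }
  vapply(seq_len(n - 3), function(k) {
    cosang <- sum(normals[[k]] * normals[[k + 1]]) / (nn[k] * nn[k + 1])
    acos(pmin(1, pmax(-1, cosang)))
  }, numeric(1))
}

#' Estrada-index folding degree of a bead chain
#'
#' Builds the third iterated line graph `L3` of the bead chain (a path on
#' `n - 3` nodes), forms the symmetric matrix `S = A(L3) + diag(phi)` whose
#' diagonal carries the chain's dihedral angles in radians, and returns the
#' normalized Estrada index `(1/m) * sum_j exp(lambda_j)` over the
#' eigenvalues of `S` (`m = n - 3`). The unnormalized sum is attached as
#' attribute `"estrada_sum"` so either convention is available.
#'
#' @param structure A [structure3d()] with `n >= 4` beads and no three
#'   consecutive beads collinear.
#' @return Scalar folding degree with attribute `estrada_sum`.
#' @export
folding_degree <- function(structure) {
  n <- structure$n_beads
  if (n < 4) stop("folding degree needs at least 4 beads")
  phi <- dihedral_angles(structure)
  l3 <- line_graph(line_graph(line_graph(bead_chain_graph(n))))
  stopifnot(nrow(l3$adjacency) == n - 3)
  s <- l3$adjacency + diag(phi, nrow = n - 3)
  lambda <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  out <- mean(exp(lambda))
  attr(out, "estrada_sum") <- sum(exp(lambda))
  out
}

#' Contact-decay exponent of a Hi-C matrix
#'
#' For each genomic separation `s = 1 .. n-1`, computes the mean contact
#' count `P(s)` over all bead pairs `|i - j| = s` (zero counts included),
#' drops separations whose mean is exactly zero, and fits
#' `log10 P(s) ~ log10 s` by least squares. The returned exponent is the
#' negated slope, so matrices whose contacts decay with distance give a
#' positive value.
#'
#' @param matrix A [contact_matrix()] with at least 4 beads.
#' @param max_s Optional cap on the separations entering the fit.
#' @return Scalar exponent.
#' @export
#' @examples
#' pm <- make_power_law_matrix(20, exponent = 1.2, prefactor = 5)
#' exponent_parameter(pm)  # 1.2
exponent_parameter <- function(matrix, max_s = NULL) {
  stopifnot(inherits(matrix, "contact_matrix"))
  n <- matrix$n_beads
  if (n < 4) stop("exponent fit needs at least 4 beads")
  smax <- if (is.null(max_s)) n - 1 else min(max_s, n - 1)
  s_vals <- seq_len(smax)
  p <- vapply(s_vals, function(s) {
    idx <- seq_len(n - s)
    mean(matrix$counts[cbind(idx, idx + s)])
  }, numeric(1))
  keep <- p > 0
  if (sum(keep) < 3) {
    stop("insufficient decay range: only ", sum(keep),
         " separations with positive mean contact")
  }
  fit <- stats::lm.fit(cbind(1, log10(s_vals[keep])), log10(p[keep]))
  -unname(fit$coefficients[2])
}

#' Structural metric table for a set of structures
#'
#' Convenience wrapper computing, per TAD/structure, the radius of gyration
#' (under one mass scheme), the folding degree and the contact-decay
#' exponent.
#'
#' @param structures List of [structure3d()] objects.
#' @param matrices List of matching [contact_matrix()] objects.
#' @param masses Optional list of `mass_vector`s (or `NULL` for unit mass).
#' @param ids Optional character vector of TAD identifiers.
#' @return Tibble with columns `tad_id`, `n_beads`, `rg`, `folding_degree`,
#'   `exponent`, `mass_scheme`.
#' @export
structure_metrics <- function(structures, matrices, masses = NULL,
                              ids = NULL) {
  k <- length(structures)
  stopifnot(length(matrices) == k)
  if (is.null(ids)) ids <- paste0("tad_", seq_len(k))
  rows <- lapply(seq_len(k), function(i) {
    mv <- if (is.null(masses)) NULL else masses[[i]]
    tibble::tibble(
      tad_id = ids[i],
      n_beads = structures[[i]]$n_beads,
      rg = radius_of_gyration(structures[[i]], mv),
      folding_degree = as.numeric(folding_degree(structures[[i]])),
      exponent = tryCatch(exponent_parameter(matrices[[i]]),
                          error = function(e) NA_real_),
      mass_scheme = if (is.null(mv)) "mass_unit" else mv$scheme
    )
  })
  dplyr::bind_rows(rows)
}
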