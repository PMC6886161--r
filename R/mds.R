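#' Configuration for metric-MDS reconstruction
#'
#' @param objective Which stress function to minimize:
#'   \describe{
#'     \item{`"eq2"`}{`sum_C1 (d - delta)^2 / delta^2` — relative squared
#'       error over observed pairs only.}
#'     \item{`"eq3"`}{`sum_C1 (d - delta)^2 / delta - gamma * sum_C2 d^2` —
#'       observed-pair stress (note the first-power denominator) minus a
#'       repulsive term pushing zero-contact pairs apart.}
#'     \item{`"eq4-shortest"`}{eq2 stress plus
#'       `sum_C2 (d - R_ij)^2 / R_ij^2` with `R_ij` the shortest-path
#'       distance through the contact graph.}
#'     \item{`"eq4-max"`}{as above with a single scalar `R`, the maximum
#'       target distance over C1.}
#'   }
#'   Sums run over unordered pairs `i < j`.
#' @param gamma Weight of the eq3 repulsion term (default 0.01).
#' @param n_restarts Number of random restarts (default 5).
#' @param max_iterations Optimizer iteration cap per restart (default 3000).
#' @param gradient_tolerance Projected-gradient tolerance (default 1e-7).
#' @param seed Integer seed making the whole reconstruction deterministic.
#' @param init_scale Side of the cube initial coordinates are drawn from;
#'   `NULL` (default) uses the mean target distance over C1.
#' @return An object of class `mds_config`.
#' @export
mds_config <- function(objective = c("eq2", "eq3", "eq4-shortest", "eq4-max"),
                       gamma = 0.01, n_restarts = 5L, max_iterations = 3000L,
                       gradient_tolerance = 1e-7, seed = 1L,
                       init_scale = NULL) {
  objective <- match.arg(objective)
  stopifnot(gamma >= 0, n_restarts >= 1, max_iterations >= 1,
            gradient_tolerance > 0)
  structure(list(objective = objective, gamma = gamma,
                 n_restarts = as.integer(n_restarts),
                 max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 seed = as.integer(seed), init_scale = init_scale),
            class = "mds_config")
}

# per-pair targets and denominators for the configured objective; returns
# masks and matrices shaped like delta. C2 machinery is NULL for eq2.
objective_terms <- function(model, config) {
  obj <- config$objective
  if (obj == "eq4-shortest" && is.null(model$r_matrix)) {
    stop("objective 'eq4-shortest' needs shortest_path_r() applied to the model")
  }
  if (obj == "eq4-max" && is.null(model$r_scalar)) {
    stop("objective 'eq4-max' needs max_distance_r() applied to the model")
  }
  if (obj == "eq3") {
    deg <- rowSums(model$c1_mask)
    if (any(deg == 0)) {
      stop("objective 'eq3' is unbounded below when a bead has no contacts ",
           "(bead ", which(deg == 0)[1], "); filter with ",
           "largest_connected_component() first")
    }
  }
  list(
    c1_denom = if (obj == "eq3") model$delta else model$delta^2,
    r_target = switch(obj,
      "eq4-shortest" = model$r_matrix,
      "eq4-max" = matrix(model$r_scalar, model$n_beads, model$n_beads),
      NULL)
  )
}

#' Evaluate an MDS objective function
#'
#' Computes the configured stress (see [mds_config()]) of a coordinate set
#' against a target distance model. All sums run over unordered bead pairs.
#'
#' @param coords n-by-3 coordinate matrix (or a [structure3d()]).
#' @param model A `target_distance_model`, with [shortest_path_r()] or
#'   [max_distance_r()] applied when the objective needs R.
#' @param config An [mds_config()].
#' @return The objective value (scalar).
#' @export
objective_value <- function(coords, model, config) {
  if (inherits(coords, "structure3d")) coords <- coords$coords
  terms <- objective_terms(model, config)
  d <- as.matrix(stats::dist(coords))
  up <- upper.tri(d)
  c1 <- model$c1_mask & up
  val <- sum((d[c1] - model$delta[c1])^2 / terms$c1_denom[c1])
  c2 <- model$c2_mask & up
  if (config$objective == "eq3") {
    val <- val - config$gamma * sum(d[c2]^2)
  } else if (!is.null(terms$r_target)) {
    r <- terms$r_target[c2]
    val <- val + sum((d[c2] - r)^2 / r^2)
  }
  val
}

#' Analytic gradient of an MDS objective
#'
#' Exact gradient of [objective_value()] with respect to every coordinate.
#' If two beads of an active pair coincide (zero distance makes the gradient
#' singular), a deterministic symmetric jitter of `1e-9 * init_scale` is
#' applied before differentiating and a message is emitted.
#'
#' @inheritParams objective_value
#' @return n-by-3 matrix of partial derivatives.
#' @export
objective_gradient <- function(coords, model, config) {
  if (inherits(coords, "structure3d")) coords <- coords$coords
  terms <- objective_terms(model, config)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  active <- model$c1_mask |
    (model$c2_mask & config$objective != "eq2")
  if (any(d[active] == 0)) {
    scale <- if (!is.null(config$init_scale)) config$init_scale else
      mean(model$delta[model$c1_mask])
    jit <- 1e-9 * scale * sin(seq_len(n) %o% c(1.3, 2.1, 3.7))
    message("objective_gradient: coincident beads in an active pair; ",
            "applying symmetric jitter")
    coords <- coords + jit
    d <- as.matrix(stats::dist(coords))
  }
  # grad_i = sum_j K_ij (x_i - x_j), K symmetric with zero diagonal
  k <- matrix(0, n, n)
  c1 <- model$c1_mask
  k[c1] <- 2 * (d[c1] - model$delta[c1]) / (terms$c1_denom[c1] * d[c1])
  c2 <- model$c2_mask
  if (config$objective == "eq3") {
    k[c2] <- k[c2] - 2 * config$gamma
  } else if (!is.null(terms$r_target)) {
    r <- terms$r_target[c2]
    k[c2] <- k[c2] + 2 * (d[c2] - r) / (r^2 * d[c2])
  }
  rowSums(k) * coords - k %*% coords
}

#' Reconstruct a 3D structure from a Hi-C contact matrix
#'
#' Converts contacts to target distances, attaches the R scheme the chosen
#' objective needs, and minimizes the objective by quasi-Newton (L-BFGS-B)
#' local optimization with analytic gradients over `n_restarts` starts. The
#' first start is a classical (Torgerson) MDS embedding of the target
#' distances, with zero-contact pairs completed by shortest-path distances
#' through the contact graph — the standard warm start for stress
#' minimization; remaining starts draw coordinates uniformly from a cube of
#' side `init_scale` under a seeded PRNG. The start with the lowest final
#' objective wins. Deterministic given `config$seed`.
#'
#' @param matrix A [contact_matrix()].
#' @param config An [mds_config()].
#' @param alpha,beta Contact-to-distance conversion parameters (see
#'   [contacts_to_distances()]).
#' @return A [structure3d()] whose `provenance` records the objective name,
#'   seed, winning restart and final objective value.
#' @export
#' @examples
#' truth <- make_structure(helix_spec(n_beads = 10))
#' cm <- structure_to_contacts(truth)
#' fit <- reconstruct(cm, mds_config("eq2", seed = 7))
#' kabsch_superpose(fit, truth, allow_scale = TRUE)$rmsd
reconstruct <- function(matrix, config = mds_config(), alpha = 1 / 3,
                        beta = 1) {
  stopifnot(inherits(matrix, "contact_matrix"), inherits(config, "mds_config"))
  model <- contacts_to_distances(matrix, alpha = alpha, beta = beta)
  if (!any(model$c1_mask)) stop("no contacts: C1 is empty")
  if (config$objective == "eq4-shortest") model <- shortest_path_r(model)
  if (config$objective == "eq4-max") model <- max_distance_r(model)
  if (is.null(config$init_scale)) {
    config$init_scale <- mean(model$delta[model$c1_mask])
  }
  n <- matrix$n_beads
  fn <- function(x) objective_value(matrix(x, n, 3), model, config)
  gr <- function(x) as.vector(objective_gradient(matrix(x, n, 3), model,
                                                 config))
  torgerson <- function() {
    full <- model$delta
    if (any(model$c2_mask)) {
      sp <- shortest_path_r(model)$r_matrix
      full[model$c2_mask] <- sp[model$c2_mask]
    }
    diag(full) <- 0
    x0 <- stats::cmdscale(stats::as.dist(full), k = 3)
    if (ncol(x0) < 3) x0 <- cbind(x0, matrix(0, n, 3 - ncol(x0)))
    x0
  }
  best <- NULL
  failures <- 0L
  for (r in seq_len(config$n_restarts)) {
    set.seed((config$seed + 7919L * (r - 1L)) %% .Machine$integer.max)
    x0 <- if (r == 1) {
      tryCatch(as.vector(torgerson()), error = function(e) {
        message("reconstruct: classical-MDS start unavailable (",
                conditionMessage(e), "); using a random start")
        stats::runif(3 * n, -config$init_scale / 2, config$init_scale / 2)
      })
    } else {
      stats::runif(3 * n, -config$init_scale / 2, config$init_scale / 2)
    }
    fit <- tryCatch(
      stats::optim(x0, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = config$max_iterations,
                                  pgtol = config$gradient_tolerance,
                                  factr = 10)),
      error = function(e) e
    )
    if (inherits(fit, "error") || !is.finite(fit$value)) {
      message("reconstruct: restart ", r, " discarded (",
              if (inherits(fit, "error")) conditionMessage(fit)
              else "non-finite objective", ")")
      failures <- failures + 1L
      next
    }
    if (is.null(best) || fit$value < best$value) {
      best <- list(value = fit$value, par = fit$par, restart = r)
    }
  }
  if (is.null(best)) stop("all ", failures, " restarts failed")
  structure3d(
    matrix(best$par, n, 3),
    bin_index = bin_index(matrix$resolution, matrix$chrom,
                          matrix$start_offset),
    provenance = list(objective = config$objective, seed = config$seed,
                      restart = best$restart, value = best$value)
  )
}

#' One-line summary of a reconstructed structure
#'
#' @param x A [structure3d()] returned by [reconstruct()].
#' @param ... Unused.
#' @return One-row tibble with `n_beads`, `objective`, `objective_value`,
#'   `seed` and `restart`.
#' @export
glance.structure3d <- function(x, ...) {
  p <- x$provenance
  tibble::tibble(
    n_beads = x$n_beads,
    objective = if (is.null(p)) NA_character_ else p$objective,
    objective_value = if (is.null(p)) NA_real_ else p$value,
    seed = if (is.null(p)) NA_integer_ else p$seed,
    restart = if (is.null(p)) NA_integer_ else p$restart
  )
}

#' Evaluate a reconstructed structure against its contact matrix
#'
#' Computes the agreement statistics used to benchmark reconstructions:
#' Pearson correlation and RMSE between target and inferred distances over
#' C1 pairs, Spearman correlations between inferred distances and contact
#' counts (over C1 pairs and over all pairs), and a summary of the inferred
#' distances across C2 (zero-contact) pairs.
#'
#' @param structure A [structure3d()].
#' @param model A `target_distance_model` for the same matrix.
#' @param matrix The [contact_matrix()] the model came from.
#' @return One-row tibble with columns `pearson_c1`, `rmse_c1`,
#'   `spearman_c1`, `spearman_all`, `c2_min`, `c2_median`, `c2_max` and
#'   `n_c1`, `n_c2`. Correlations over fewer than 3 pairs are `NA`.
#' @export
evaluate_reconstruction <- function(structure, model, matrix) {
  stopifnot(structure$n_beads == matrix$n_beads)
  d <- pairwise_distances(structure)
  up <- upper.tri(d)
  c1 <- model$c1_mask & up
  c2 <- model$c2_mask & up
  n_c1 <- sum(c1)
  n_c2 <- sum(c2)
  safe_cor <- function(x, y, method = "pearson") {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y, method = method)
  }
  pe <- safe_cor(d[c1], model$delta[c1])
  sc <- safe_cor(d[c1], matrix$counts[c1], method = "spearman")
  rm <- if (n_c1 >= 1) sqrt(mean((d[c1] - model$delta[c1])^2)) else NA_real_
  sa <- safe_cor(d[up], matrix$counts[up], method = "spearman")
  tibble::tibble(
    pearson_c1 = pe, rmse_c1 = rm, spearman_c1 = sc, spearman_all = sa,
    c2_min = if (n_c2) min(d[c2]) else NA_real_,
    c2_median = if (n_c2) stats::median(d[c2]) else NA_real_,
    c2_max = if (n_c2) max(d[c2]) else NA_real_,
    n_c1 = n_c1, n_c2 = n_c2
  )
}
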