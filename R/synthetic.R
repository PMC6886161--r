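#' Specifications for synthetic ground-truth fixtures
#'
#' Helpers constructing the parameter objects consumed by
#' [make_structure()]. A helix is fully deterministic; a random walk needs a
#' seed.
#'
#' @param n_beads Number of beads (`>= 4` if the structure will feed
#'   [folding_degree()]).
#' @param radius,angle,pitch Helix geometry: bead `k` (0-based) sits at
#'   `(radius * cos(k * angle), radius * sin(k * angle), k * pitch)`.
#' @param step Step length of the random walk.
#' @param seed Integer seed (mandatory for stochastic kinds).
#' @return A `synthetic_spec` list.
#' @name synthetic_spec
NULL

#' @rdname synthetic_spec
#' @export
helix_spec <- function(n_beads = 20L, radius = 1, angle = pi / 4,
                       pitch = 0.3) {
  structure(list(kind = "helix", n_beads = as.integer(n_beads),
                 radius = radius, angle = angle, pitch = pitch),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
random_walk_spec <- function(n_beads = 20L, step = 1, seed = 1L) {
  structure(list(kind = "random_walk", n_beads = as.integer(n_beads),
                 step = step, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a ground-truth 3D structure
#'
#' `helix` places beads on a regular helix (all consecutive-bead distances
#' equal, all dihedrals equal); `random_walk` takes seeded unit steps in
#' uniformly random directions, resampling any step that would create an
#' exactly collinear bead triple (which would make dihedral angles
#' undefined).
#'
#' @param spec A [helix_spec()] or [random_walk_spec()].
#' @param resolution,chrom,start_offset Bin metadata attached to the
#'   structure.
#' @return A [structure3d()].
#' @export
make_structure <- function(spec, resolution = 40000L, chrom = "chrS",
                           start_offset = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_beads
  if (n < 2) stop("need at least 2 beads")
  bi <- bin_index(resolution, chrom, start_offset)
  if (spec$kind == "helix") {
    k <- seq_len(n) - 1
    coords <- cbind(spec$radius * cos(k * spec$angle),
                    spec$radius * sin(k * spec$angle),
                    k * spec$pitch)
    return(structure3d(coords, bin_index = bi,
                       provenance = list(objective = "synthetic-helix",
                                         seed = NA, restart = NA, value = NA)))
  }
  set.seed(spec$seed)
  coords <- matrix(0, n, 3)
  for (k in 2:n) {
    repeat {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- coords[k - 1, ] + spec$step * u
      if (k < 3) break
      v1 <- coords[k - 1, ] - coords[k - 2, ]
      v2 <- cand - coords[k - 1, ]
      cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      if (sqrt(sum(cr^2)) > 1e-8) break
    }
    coords[k, ] <- cand
  }
  structure3d(coords, bin_index = bi,
              provenance = list(objective = "synthetic-random-walk",
                                seed = spec$seed, restart = NA, value = NA))
}

#' Contact matrix implied by a ground-truth structure
#'
#' Inverts the contact-to-distance power law: a pair at distance `d` gets
#' `c = (beta / d)^(1/alpha)` contacts, so converting the result back with
#' the same `alpha` and `beta` reproduces the true pairwise distances
#' exactly. Optional multiplicative lognormal noise (sd `noise_sd` on the
#' log scale) and symmetric pair dropout (each pair zeroed with probability
#' `dropout_rate`) create realistic noisy / incomplete matrices with a
#' non-empty C2 set.
#'
#' @param structure A [structure3d()] with no coincident beads.
#' @param alpha,beta Power-law parameters matching
#'   [contacts_to_distances()].
#' @param noise_sd Lognormal noise sd (0 = noiseless).
#' @param dropout_rate Per-pair zeroing probability in `[0, 1)`.
#' @param seed Seed used when noise or dropout is active.
#' @return A [contact_matrix()].
#' @export
structure_to_contacts <- function(structure, alpha = 1 / 3, beta = 1,
                                  noise_sd = 0, dropout_rate = 0, seed = 1L) {
  stopifnot(alpha > 0, beta > 0, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  d <- pairwise_distances(structure)
  if (any(d[upper.tri(d)] == 0)) stop("coincident beads: distances of 0")
  n <- nrow(d)
  cmat <- matrix(0, n, n)
  up <- upper.tri(d)
  cmat[up] <- (beta / d[up])^(1 / alpha)
  if (noise_sd > 0 || dropout_rate > 0) {
    set.seed(seed)
    m <- sum(up)
    if (noise_sd > 0) cmat[up] <- cmat[up] * stats::rlnorm(m, 0, noise_sd)
    if (dropout_rate > 0) {
      cmat[up] <- cmat[up] * (stats::runif(m) >= dropout_rate)
    }
  }
  cmat <- cmat + t(cmat)
  bi <- structure$bin_index
  contact_matrix(cmat,
                 resolution = if (is.null(bi)) 40000 else bi$resolution,
                 chrom = if (is.null(bi)) "chrS" else bi$chrom,
                 start_offset = if (is.null(bi)) 0 else bi$start_offset)
}

#' Power-law decay contact matrix
#'
#' `c_ij = prefactor * |i - j|^(-exponent)` with a zero diagonal — the exact
#' fixture for [exponent_parameter()], which should return `exponent`.
#'
#' @param n Number of beads (`>= 4`).
#' @param exponent Decay exponent (`>= 0`).
#' @param prefactor Positive scale.
#' @inheritParams make_structure
#' @return A [contact_matrix()].
#' @export
make_power_law_matrix <- function(n, exponent = 1, prefactor = 1,
                                  resolution = 40000L, chrom = "chrS",
                                  start_offset = 0) {
  stopifnot(n >= 4, exponent >= 0, prefactor > 0)
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  cmat <- ifelse(s == 0, 0, prefactor * s^(-exponent))
  contact_matrix(cmat, resolution, chrom, start_offset)
}

#' Random feature tracks over a binned region
#'
#' Emulates peak/TSS tracks and signal tracks across `n_beads` bins: each
#' point feature draws a Poisson number of events per bead (expected
#' `rates[f]` per bead) placed uniformly within the bead as 1-bp intervals;
#' each signal feature gets one interval per bead with a lognormal value.
#'
#' @param n_beads Number of beads.
#' @param bin_index A [bin_index()].
#' @param rates Named numeric vector: expected events per bead for each
#'   point feature (e.g. `c(tss = 0.5, h3k4me3 = 1)`).
#' @param seed Integer seed.
#' @param signal Character vector of signal-track names (lognormal
#'   meanlog 0, sdlog 1 values, one interval per bead).
#' @return Named list of interval tibbles (columns `chrom`, `start`, `end`
#'   and `value` for signal tracks).
#' @export
make_feature_tracks <- function(n_beads, bin_index, rates, seed = 1L,
                                signal = character()) {
  stopifnot(all(rates >= 0))
  set.seed(seed)
  res <- bin_index$resolution
  off <- bin_index$start_offset
  out <- list()
  for (f in names(rates)) {
    counts <- stats::rpois(n_beads, rates[[f]])
    pos <- unlist(lapply(seq_len(n_beads), function(b) {
      if (counts[b] == 0) return(numeric(0))
      off + (b - 1) * res + floor(stats::runif(counts[b], 0, res - 1))
    }))
    out[[f]] <- tibble::tibble(chrom = bin_index$chrom, start = pos,
                               end = pos + 1)
  }
  for (f in signal) {
    out[[f]] <- tibble::tibble(
      chrom = bin_index$chrom,
      start = off + (seq_len(n_beads) - 1) * res,
      end = off + seq_len(n_beads) * res,
      value = stats::rlnorm(n_beads, 0, 1)
    )
  }
  out
}

#' Planted-block chromatin-state profiles
#'
#' Generates `t_n` state-enrichment profiles over `s_n` states organized in
#' `k_blocks` blocks: profiles in a block share a mean vector, plus seeded
#' Gaussian noise. Block centers are drawn uniformly and re-drawn until
#' every pair has absolute Pearson correlation below 0.4, so the planted
#' blocks stay distinguishable under a correlation-based affinity — the
#' defining property of a planted-partition fixture. The true block labels
#' are returned for adjusted-Rand scoring of clustering output.
#'
#' @param t_n Number of TADs (profiles).
#' @param s_n Number of chromatin states (`>= 3`).
#' @param k_blocks Number of planted blocks (`2 <= k_blocks <= t_n`).
#' @param seed Integer seed.
#' @param noise_sd Within-block Gaussian noise sd (default 0.05).
#' @return List with `profiles` (`t_n`-by-`s_n` matrix) and `labels`
#'   (integer vector of planted block memberships).
#' @export
make_planted_state_profiles <- function(t_n, s_n = 14L, k_blocks = 3L,
                                        seed = 1L, noise_sd = 0.05) {
  stopifnot(t_n >= k_blocks, k_blocks >= 2, s_n >= 3)
  set.seed(seed)
  centers <- matrix(0, k_blocks, s_n)
  centers[1, ] <- stats::runif(s_n, 0, 4)
  for (b in seq_len(k_blocks)[-1]) {
    repeat {
      cand <- stats::runif(s_n, 0, 4)
      sims <- abs(stats::cor(cand, t(centers[seq_len(b - 1), ,
                                             drop = FALSE])))
      if (max(sims) < 0.4) break
    }
    centers[b, ] <- cand
  }
  labels <- sort(rep_len(seq_len(k_blocks), t_n))
  profiles <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(t_n * s_n, 0, noise_sd), t_n, s_n)
  list(profiles = profiles, labels = labels)
}
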