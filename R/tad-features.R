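overlap_bp <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Feature enrichment of one TAD
#'
#' Two enrichment definitions are supported, both normalized by TAD length
#' in base pairs:
#' \describe{
#'   \item{`"count"`}{number of track intervals whose midpoint lies inside
#'     the TAD, divided by TAD length (peak-type features such as H3K4me3 or
#'     RNA polII; TSS density).}
#'   \item{`"log2mean"`}{mean of `log2(value)` over track intervals
#'     overlapping the TAD, divided by TAD length (signal-type features such
#'     as CTCF or H3K27me3). Non-positive values are excluded with a
#'     warning; no overlapping interval gives `NA`, not 0.}
#' }
#'
#' @param tad One-row tibble (or list) with `chrom`, `start`, `end`.
#' @param track Tibble of intervals from [read_bed()]; `log2mean` requires a
#'   `value` column.
#' @param mode `"count"` or `"log2mean"`.
#' @return Scalar enrichment (possibly `NA` for `log2mean`).
#' @export
feature_enrichment <- function(tad, track, mode = c("count", "log2mean")) {
  mode <- match.arg(mode)
  len <- tad$end - tad$start
  stopifnot(len > 0)
  on_chrom <- track[track$chrom == tad$chrom, , drop = FALSE]
  if (mode == "count") {
    mid <- (on_chrom$start + on_chrom$end) / 2
    return(sum(mid >= tad$start & mid < tad$end) / len)
  }
  ov <- overlap_bp(tad$start, tad$end, on_chrom$start, on_chrom$end) > 0
  vals <- on_chrom$value[ov]
  if (length(vals) == 0) return(NA_real_)
  bad <- vals <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive signal value(s) excluded from log2")
    vals <- vals[!bad]
    if (length(vals) == 0) return(NA_real_)
  }
  mean(log2(vals)) / len
}

#' Correlate a structural metric with a feature across TADs
#'
#' Plain Pearson correlation with a two-sided p-value from the
#' t-distribution (`n - 2` degrees of freedom). Pairs with a missing value
#' in either vector are dropped.
#'
#' @param metric_values,feature_values Equal-length numeric vectors (one
#'   entry per TAD).
#' @return One-row tibble with `r`, `p_value`, `n_used`. Zero variance (or
#'   fewer than 3 complete pairs) gives `NA` for both statistics.
#' @export
correlate_metric_feature <- function(metric_values, feature_values) {
  stopifnot(length(metric_values) == length(feature_values))
  ok <- stats::complete.cases(metric_values, feature_values)
  x <- metric_values[ok]
  y <- feature_values[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          n_used = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_used = length(x))
}

#' Chromatin-state fold enrichment per TAD
#'
#' For every TAD `t` and state `s`:
#' `fold = (fraction of t's bp covered by s) / (fraction of all segmented bp
#' covered by s)`. The background is the union of all segmentation intervals
#' supplied; a value of 1 means the TAD matches the genome-wide composition.
#'
#' @param tads Tibble of TAD intervals (`chrom`, `start`, `end`).
#' @param segmentation Tibble from `read_bed(kind = "bed4-name")`: a
#'   non-overlapping ChromHMM-style segmentation whose `name` column carries
#'   state labels.
#' @param states Character vector of state labels defining the columns;
#'   defaults to the sorted labels present. States absent genome-wide give
#'   `NA` columns.
#' @return T-by-S numeric matrix (rows = TADs, columns = states).
#' @export
state_fold_enrichment <- function(tads, segmentation, states = NULL) {
  if (is.null(states)) states <- sort(unique(segmentation$name))
  genome_bp <- sum(segmentation$end - segmentation$start)
  stopifnot(genome_bp > 0)
  state_bp <- vapply(states, function(s) {
    seg <- segmentation[segmentation$name == s, , drop = FALSE]
    sum(seg$end - seg$start)
  }, numeric(1))
  bg <- state_bp / genome_bp
  t_n <- nrow(tads)
  out <- matrix(NA_real_, t_n, length(states),
                dimnames = list(NULL, states))
  for (t in seq_len(t_n)) {
    len <- tads$end[t] - tads$start[t]
    seg_t <- segmentation[segmentation$chrom == tads$chrom[t], , drop = FALSE]
    for (si in seq_along(states)) {
      if (state_bp[si] == 0) next  # state absent genome-wide -> NA
      seg_s <- seg_t[seg_t$name == states[si], , drop = FALSE]
      cov <- sum(overlap_bp(tads$start[t], tads$end[t],
                            seg_s$start, seg_s$end))
      out[t, si] <- (cov / len) / bg[si]
    }
  }
  out
}

#' Similarity of TADs from their chromatin-state profiles
#'
#' Affinity between two TADs is the absolute Pearson correlation of their
#' state fold-enrichment profiles, giving values in `[0, 1]` with 1 on the
#' diagonal. A zero-variance profile gets zero off-diagonal affinity (with a
#' warning).
#'
#' @param profiles T-by-S matrix from [state_fold_enrichment()]; each row
#'   needs at least 3 non-missing entries.
#' @return Symmetric T-by-T affinity matrix.
#' @export
state_affinity <- function(profiles) {
  profiles <- as.matrix(profiles)
  t_n <- nrow(profiles)
  stopifnot(t_n >= 2)
  if (any(rowSums(!is.na(profiles)) < 3)) {
    stop("every profile needs at least 3 non-missing states")
  }
  sds <- apply(profiles, 1, stats::sd, na.rm = TRUE)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance profile(s); their affinities set to 0")
  }
  a <- abs(suppressWarnings(
    stats::cor(t(profiles), use = "pairwise.complete.obs")))
  a[is.na(a)] <- 0
  a[flat, ] <- 0
  a[, flat] <- 0
  diag(a) <- 1
  dimnames(a) <- NULL
  a
}

#' Spectral clustering of TADs from an affinity matrix
#'
#' Normalized-Laplacian spectral clustering: the affinity is symmetrically
#' normalized by node degree, the `k` leading eigenvectors form an embedding
#' whose rows are normalized to unit length, and seeded k-means assigns
#' cluster labels. Deterministic given `seed`. Each k-means restart is
#' initialized with k-means++ seeding (first center uniform, later centers
#' drawn proportional to squared distance from the chosen set): at larger
#' `k` (tens of clusters) plain uniform restarts frequently merge one pair
#' of clusters and split another even on well-separated embeddings.
#'
#' @param affinity Symmetric non-negative matrix (e.g. [state_affinity()]).
#' @param k Number of clusters, `2 <= k <= nrow(affinity)`.
#' @param seed Integer seed for the k-means restarts.
#' @param n_starts Number of k-means++ restarts (default 10).
#' @return Object of class `cluster_assignment`: list with `labels`
#'   (integers `1..k`), `k` and `seed`.
#' @export
spectral_cluster <- function(affinity, k, seed = 1L, n_starts = 10L) {
  a <- as.matrix(affinity)
  t_n <- nrow(a)
  stopifnot(ncol(a) == t_n, k >= 2)
  if (k > t_n) stop("k = ", k, " exceeds number of objects ", t_n)
  if (max(abs(a - t(a))) > 1e-9) stop("affinity must be symmetric")
  if (any(a < 0)) stop("affinity must be non-negative")
  deg <- rowSums(a)
  dis <- ifelse(deg > 0, 1 / sqrt(deg), 0)  # isolated nodes stay zero
  m <- a * outer(dis, dis)
  ev <- eigen(m, symmetric = TRUE)
  emb <- ev$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(norms > 0, norms, 1)
  kpp_centers <- function(x, k) {
    n <- nrow(x)
    centers <- integer(k)
    centers[1] <- sample.int(n, 1)
    d2 <- rowSums((x - x[rep(centers[1], n), , drop = FALSE])^2)
    for (j in seq_len(k)[-1]) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, rowSums((x - x[rep(centers[j], n), , drop = FALSE])^2))
    }
    x[centers, , drop = FALSE]
  }
  set.seed(seed)
  km <- NULL
  for (s in seq_len(n_starts)) {
    fit <- suppressWarnings(
      stats::kmeans(emb, centers = kpp_centers(emb, k), iter.max = 100))
    if (is.null(km) || fit$tot.withinss < km$tot.withinss) km <- fit
  }
  structure(list(labels = as.integer(km$cluster), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' Assign beads to TADs
#'
#' @param tads Tibble of TAD intervals on one chromosome, sorted and
#'   non-overlapping.
#' @param bin_index A [bin_index()].
#' @param n_beads Number of beads.
#' @return Integer vector of length `n_beads`: the TAD (row of `tads`)
#'   whose span contains the bead midpoint, or `NA` for beads outside every
#'   TAD.
#' @export
beads_to_tads <- function(tads, bin_index, n_beads) {
  mids <- bin_index$start_offset + (seq_len(n_beads) - 0.5) *
    bin_index$resolution
  out <- rep(NA_integer_, n_beads)
  for (t in seq_len(nrow(tads))) {
    hit <- tads$chrom[t] == bin_index$chrom &
      mids >= tads$start[t] & mids < tads$end[t]
    out[hit] <- t
  }
  out
}

#' Observed/expected normalization of inter-TAD contacts
#'
#' Aggregates bead-pair contacts to TAD pairs and normalizes by the
#' expectation `E_ij = R_i * R_j * N_inter`, where `N_inter` is the total
#' inter-TAD contact count and `R_i` the fraction of inter-TAD contacts
#' involving TAD `i`. Each inter-TAD contact is associated with both of its
#' TADs, so `sum_i R_i = 2` — the convention under which two TADs in
#' isolation get `O/E = 1`.
#'
#' @param matrix A bead-level [contact_matrix()].
#' @param tad_assignment Integer vector (length `n_beads`) mapping beads to
#'   TAD ids, as from [beads_to_tads()]; `NA` beads are ignored.
#' @return List of class `inter_tad_expectation` with `observed` (T-by-T),
#'   `r_frac` (sums to 2), `n_inter`, `expected`, and `oe`
#'   (observed/expected; `NA` where the expectation is 0).
#' @export
observed_expected_inter_tad <- function(matrix, tad_assignment) {
  stopifnot(inherits(matrix, "contact_matrix"),
            length(tad_assignment) == matrix$n_beads)
  ids <- sort(unique(tad_assignment[!is.na(tad_assignment)]))
  t_n <- length(ids)
  if (t_n < 2) stop("need at least 2 TADs")
  obs <- matrix(0, t_n, t_n)
  n <- matrix$n_beads
  grp <- match(tad_assignment, ids)
  for (i in seq_len(n - 1)) {
    if (is.na(grp[i])) next
    for (j in (i + 1):n) {
      if (is.na(grp[j]) || grp[i] == grp[j]) next
      obs[grp[i], grp[j]] <- obs[grp[i], grp[j]] + matrix$counts[i, j]
      obs[grp[j], grp[i]] <- obs[grp[i], grp[j]]
    }
  }
  n_inter <- sum(obs[upper.tri(obs)])
  if (n_inter == 0) stop("no inter-TAD reads: all contacts are intra-TAD")
  r_frac <- rowSums(obs) / n_inter
  expected <- outer(r_frac, r_frac) * n_inter
  diag(expected) <- 0
  oe <- ifelse(expected > 0, obs / expected, NA_real_)
  diag(oe) <- NA_real_
  structure(list(observed = obs, r_frac = r_frac, n_inter = n_inter,
                 expected = expected, oe = oe, tad_ids = ids),
            class = "inter_tad_expectation")
}

#' Distances from one bead to all beads
#'
#' The profile used to relate a locus of interest (e.g. a bead containing a
#' particular gene) to the rest of the reconstructed structure.
#'
#' @param structure A [structure3d()].
#' @param focus_bead 1-based bead index.
#' @return Numeric vector of length `n` of Euclidean distances; 0 at
#'   `focus_bead`.
#' @export
locus_distance_profile <- function(structure, focus_bead) {
  n <- structure$n_beads
  if (focus_bead < 1 || focus_bead > n) {
    stop("focus_bead must be in [1, ", n, "]")
  }
  diffs <- sweep(structure$coords, 2, structure$coords[focus_bead, ])
  sqrt(rowSums(diffs^2))
}
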