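#' Optimal superposition of two bead structures (Kabsch algorithm)
#'
#' Finds the proper rotation (and optionally a uniform scale) plus
#' translation minimizing the root-mean-square deviation between paired
#' points of `mobile` and `reference`. Reflections are excluded by flipping
#' the sign of the smallest singular value when the rotation determinant
#' would be negative.
#'
#' @param mobile,reference [structure3d()] objects (or n-by-3 matrices) with
#'   the same number of beads, `n >= 3`.
#' @param allow_scale Also fit a uniform scale factor (similarity transform);
#'   default `FALSE`. Useful when the overall scale of one structure is
#'   arbitrary, as after reconstruction with an arbitrary scale parameter.
#' @return List of class `superposition` with fields `rotation` (3-by-3,
#'   `det = +1`), `translation` (length-3), `scale` (1 when `allow_scale` is
#'   off), `rmsd`, and `degenerate` (`TRUE` when the points are collinear or
#'   coincident — the fit is still returned). The fitted transform maps
#'   `mobile` onto `reference` as `scale * mobile %*% t(rotation) +
#'   translation`.
#' @export
kabsch_superpose <- function(mobile, reference, allow_scale = FALSE) {
  a <- if (inherits(mobile, "structure3d")) mobile$coords else as.matrix(mobile)
  b <- if (inherits(reference, "structure3d")) reference$coords else
    as.matrix(reference)
  if (nrow(a) != nrow(b)) stop("structures have different bead counts")
  n <- nrow(a)
  if (n < 3) stop("superposition needs at least 3 beads")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite coordinates")
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)   # 3x3 covariance
  sv <- svd(h)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  if (sgn == 0) sgn <- 1
  dfix <- diag(c(1, 1, sgn))
  rot <- sv$v %*% dfix %*% t(sv$u)
  # degenerate when the point cloud has rank < 2 (rotation about the line
  # is unconstrained); detect via singular values of the centered coords
  degenerate <- sum(svd(a0)$d > 1e-9 * max(svd(a0)$d, 1e-300)) < 2 ||
    sum(svd(b0)$d > 1e-9 * max(svd(b0)$d, 1e-300)) < 2
  s <- 1
  if (allow_scale) {
    denom <- sum(a0^2)
    s <- if (denom > 0) sum(sv$d * diag(dfix)) / denom else 1
    if (s <= 0) s <- 1
  }
  fitted <- s * a0 %*% t(rot)
  rmsd <- sqrt(sum((fitted - b0)^2) / n)
  translation <- cb - as.vector(s * (rot %*% ca))
  structure(list(rotation = rot, translation = translation, scale = s,
                 rmsd = rmsd, degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd = ", signif(x$rmsd, 6),
      if (x$scale != 1) paste0(", scale = ", signif(x$scale, 6)),
      if (x$degenerate) " [degenerate point set]", "\n", sep = "")
  invisible(x)
}

#' Apply a fitted superposition to a structure
#'
#' @param structure A [structure3d()] (or n-by-3 matrix).
#' @param superposition A result of [kabsch_superpose()].
#' @return The transformed [structure3d()].
#' @export
apply_superposition <- function(structure, superposition) {
  a <- if (inherits(structure, "structure3d")) structure$coords else
    as.matrix(structure)
  out <- sweep(superposition$scale * a %*% t(superposition$rotation), 2,
               superposition$translation, "+")
  if (inherits(structure, "structure3d")) {
    structure3d(out, structure$bin_index, structure$provenance)
  } else {
    structure3d(out)
  }
}

#' Pairwise RMSD matrix between reconstructed structures
#'
#' Superposes every pair of structures with [kabsch_superpose()] and records
#' the minimum RMSD, mirroring distribution-of-RMSD comparisons between
#' reconstructions from different objective functions.
#'
#' @param structures List of [structure3d()] objects with equal bead counts.
#' @param allow_scale Passed to [kabsch_superpose()].
#' @return Symmetric matrix of RMSDs with zero diagonal.
#' @export
pairwise_structure_rmsd <- function(structures, allow_scale = FALSE) {
  k <- length(structures)
  ns <- vapply(structures, function(s) s$n_beads, numeric(1))
  if (length(unique(ns)) > 1) {
    stop("structures have different bead counts: ",
         paste(unique(ns), collapse = ", "))
  }
  out <- matrix(0, k, k)
  if (k < 2) return(out)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- kabsch_superpose(structures[[i]], structures[[j]],
                            allow_scale = allow_scale)$rmsd
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}
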