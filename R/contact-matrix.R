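#' Construct a Hi-C contact matrix object
#'
#' A `contact_matrix` holds a symmetric, non-negative matrix of interaction
#' counts between fixed-size genomic bins ("beads") of one chromosome or TAD,
#' together with the bin-to-genome mapping. The diagonal carries self-contacts
#' and is ignored by all downstream modelling.
#'
#' @param counts Square numeric matrix of non-negative contact counts.
#'   Must be symmetric to within an absolute tolerance of `1e-9`.
#' @param resolution Bin size in base pairs (one bead per bin).
#' @param chrom Chromosome label, e.g. `"chr6"`.
#' @param start_offset 0-based genomic coordinate of the first bead's start.
#'
#' @return An object of class `contact_matrix` with fields `counts`,
#'   `n_beads`, `resolution`, `chrom` and `start_offset`.
#' @seealso [read_dense_matrix()], [read_coo_matrix()], [ice_normalize()]
#' @export
#' @examples
#' m <- matrix(c(0, 2, 1, 2, 0, 4, 1, 4, 0), 3, 3)
#' cm <- contact_matrix(m, resolution = 40000, chrom = "chr6")
#' cm$n_beads
contact_matrix <- function(counts, resolution = 40000L, chrom = "chrU",
                           start_offset = 0) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square, got ", nrow(counts), "x", ncol(counts))
  }
  if (nrow(counts) < 2) stop("a contact matrix needs at least 2 beads")
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("contact matrix contains non-finite entries")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative contact count at (", bad[1], ",", bad[2], ")")
  }
  asym <- max(abs(counts - t(counts)))
  if (asym > 1e-9) {
    bad <- which(abs(counts - t(counts)) == asym, arr.ind = TRUE)[1, ]
    stop("contact matrix not symmetric: |c[", bad[1], ",", bad[2],
         "] - c[", bad[2], ",", bad[1], "]| = ", signif(asym, 3))
  }
  if (resolution <= 0) stop("resolution must be positive")
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, n_beads = nrow(counts),
         resolution = as.numeric(resolution), chrom = as.character(chrom),
         start_offset = as.numeric(start_offset)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  nz <- sum(x$counts[upper.tri(x$counts)] > 0)
  np <- x$n_beads * (x$n_beads - 1) / 2
  cat("<contact_matrix> ", x$chrom, ":", format(x$start_offset, big.mark = ","),
      "- , ", x$n_beads, " beads @ ", format(x$resolution, big.mark = ","),
      " bp\n", sep = "")
  cat("  nonzero off-diagonal pairs: ", nz, "/", np,
      " (", round(100 * nz / np, 1), "%)\n", sep = "")
  invisible(x)
}

#' Bin index: the mapping from bead numbers to genomic coordinates
#'
#' Bead `b` (0-based) covers the half-open interval
#' `[start_offset + b * resolution, start_offset + (b + 1) * resolution)`.
#'
#' @param resolution Bin size in base pairs; must be positive.
#' @param chrom Chromosome label.
#' @param start_offset 0-based start of bead 0.
#' @return An object of class `bin_index`.
#' @export
bin_index <- function(resolution = 40000L, chrom = "chrU", start_offset = 0) {
  if (resolution <= 0) stop("resolution must be positive")
  structure(list(resolution = as.numeric(resolution),
                 chrom = as.character(chrom),
                 start_offset = as.numeric(start_offset)),
            class = "bin_index")
}

#' Read a dense whitespace-delimited Hi-C matrix
#'
#' Reads a square numeric text matrix. Tiny numerical asymmetries (relative
#' magnitude up to `1e-6`) are repaired by averaging the matrix with its
#' transpose; anything larger is an error naming the worst cell.
#'
#' @param path Path to a whitespace-delimited numeric text file.
#' @inheritParams contact_matrix
#' @return A [contact_matrix()].
#' @export
read_dense_matrix <- function(path, resolution = 40000L, chrom = "chrU",
                              start_offset = 0) {
  rows <- utils::read.table(path, header = FALSE,
                            colClasses = "numeric", fill = FALSE)
  m <- as.matrix(rows)
  if (nrow(m) != ncol(m)) {
    stop("dense matrix file is not square: ", nrow(m), " rows x ",
         ncol(m), " columns in ", path)
  }
  if (anyNA(m)) stop("non-numeric or missing entries in ", path)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative entry at row ", bad[1], ", column ", bad[2], " in ", path)
  }
  asym <- abs(m - t(m))
  scale <- max(abs(m), 1e-300)
  if (max(asym) / scale > 1e-6) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("matrix asymmetric beyond tolerance at (", bad[1], ",", bad[2],
         "): ", m[bad[1], bad[2]], " vs ", m[bad[2], bad[1]])
  }
  contact_matrix((m + t(m)) / 2, resolution, chrom, start_offset)
}

#' Read a sparse "i j count" (COO) Hi-C matrix
#'
#' Indices are 0-based bead numbers. Each record `(i, j, count)` implies the
#' symmetric record `(j, i, count)`; duplicate records for a pair are summed.
#'
#' @param path Path to a 3-column whitespace-delimited text file.
#' @param n_beads Number of beads (matrix dimension); indices must be
#'   `< n_beads`.
#' @inheritParams contact_matrix
#' @return A [contact_matrix()].
#' @export
read_coo_matrix <- function(path, n_beads, resolution = 40000L, chrom = "chrU",
                            start_offset = 0) {
  d <- utils::read.table(path, header = FALSE, col.names = c("i", "j", "count"))
  if (ncol(d) != 3) stop("COO file must have 3 columns, got ", ncol(d))
  if (any(d$i < 0) || any(d$j < 0) || any(d$i >= n_beads) || any(d$j >= n_beads)) {
    bad <- which(d$i >= n_beads | d$j >= n_beads | d$i < 0 | d$j < 0)[1]
    stop("bead index out of range [0, ", n_beads - 1, ") at line ", bad,
         ": ", d$i[bad], " ", d$j[bad])
  }
  if (any(d$count < 0)) {
    stop("negative count at line ", which(d$count < 0)[1])
  }
  m <- matrix(0, n_beads, n_beads)
  for (r in seq_len(nrow(d))) {
    i <- d$i[r] + 1L
    j <- d$j[r] + 1L
    m[i, j] <- m[i, j] + d$count[r]
    if (i != j) m[j, i] <- m[j, i] + d$count[r]
  }
  contact_matrix(m, resolution, chrom, start_offset)
}

#' Iterative correction (ICE-style) balancing of a raw contact matrix
#'
#' Removes multiplicative per-bin coverage biases by repeatedly dividing rows
#' and columns by their marginal sums until the coefficient of variation of
#' the non-zero-row marginals falls below `tol`. All-zero rows are left zero
#' and excluded from the convergence check. The result is scaled so that the
#' mean marginal over non-zero rows equals 1.
#'
#' @param matrix A [contact_matrix()] of raw counts.
#' @param max_iter Maximum number of correction sweeps (default 200).
#' @param tol Convergence threshold on the marginal coefficient of variation
#'   (default `1e-5`).
#' @return A balanced [contact_matrix()]. If the loop stops without reaching
#'   `tol` a message is emitted; the partially balanced matrix is returned.
#' @export
ice_normalize <- function(matrix, max_iter = 200L, tol = 1e-5) {
  stopifnot(inherits(matrix, "contact_matrix"), max_iter >= 1, tol > 0)
  m <- matrix$counts
  nz <- rowSums(m) > 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    marg <- rowSums(m)
    mu <- mean(marg[nz])
    cv <- stats::sd(marg[nz]) / mu
    if (!is.na(cv) && cv < tol) {
      converged <- TRUE
      break
    }
    b <- ifelse(nz, marg / mu, 1)
    m <- m / outer(b, b)
  }
  if (!converged) {
    marg <- rowSums(m)
    cv <- stats::sd(marg[nz]) / mean(marg[nz])
    if (is.na(cv) || cv >= tol) {
      message("ice_normalize: not converged after ", max_iter,
              " iterations (marginal CV = ", signif(cv, 3), ")")
    }
  }
  # fix the overall scale: mean nonzero-row marginal = 1
  m <- m / mean(rowSums(m)[nz])
  m <- (m + t(m)) / 2
  contact_matrix(m, matrix$resolution, matrix$chrom, matrix$start_offset)
}

#' Heat-map of a contact matrix
#'
#' @param object A [contact_matrix()].
#' @param log1p Plot `log(1 + count)` instead of raw counts (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_matrix <- function(object, log1p = TRUE, ...) {
  n <- object$n_beads
  df <- tibble::tibble(
    i = rep(seq_len(n), times = n),
    j = rep(seq_len(n), each = n),
    count = as.vector(object$counts)
  )
  if (log1p) df$count <- log1p(df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = if (log1p) "log1p(count)" else "count") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bead", y = "bead",
                  title = paste0(object$chrom, " contact matrix")) +
    ggplot2::theme_minimal()
}
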