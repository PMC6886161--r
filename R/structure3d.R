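#' Construct a 3D bead-chain structure
#'
#' A `structure3d` is an n-by-3 matrix of bead coordinates plus the mapping
#' of beads back to genomic bins and, for reconstructed structures, the
#' provenance of the optimization run that produced it.
#'
#' @param coords Numeric n-by-3 matrix of bead coordinates (finite).
#' @param bin_index A [bin_index()] describing the bead-to-genome mapping.
#' @param provenance Optional list recording how the structure was made
#'   (objective name, seed, restart id, final objective value).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(coords, bin_index = NULL, provenance = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (nrow(coords) < 1) stop("structure needs at least one bead")
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("non-finite coordinate in structure")
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, n_beads = nrow(coords),
                 bin_index = bin_index, provenance = provenance),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", x$n_beads, " beads\n", sep = "")
  if (!is.null(x$provenance)) {
    p <- x$provenance
    cat("  objective ", p$objective, " = ", signif(p$value, 6),
        " (seed ", p$seed, ", restart ", p$restart, ")\n", sep = "")
  }
  invisible(x)
}

#' Pairwise Euclidean distances between beads
#'
#' @param structure A [structure3d()].
#' @return Symmetric n-by-n matrix of distances, zero diagonal.
#' @export
pairwise_distances <- function(structure) {
  as.matrix(stats::dist(structure$coords))
}

#' One row per bead of a 3D structure
#'
#' @param x A [structure3d()].
#' @param ... Unused.
#' @return Tibble with columns `bead` (1-based), `chrom`, `start`, `end`,
#'   `x`, `y`, `z`. Genomic columns are `NA` when no bin index is attached.
#' @export
tidy.structure3d <- function(x, ...) {
  n <- x$n_beads
  bi <- x$bin_index
  coords <- x$coords
  tibble::tibble(
    bead = seq_len(n),
    chrom = if (is.null(bi)) NA_character_ else bi$chrom,
    start = if (is.null(bi)) NA_real_ else bi$start_offset +
      (seq_len(n) - 1) * bi$resolution,
    end = if (is.null(bi)) NA_real_ else bi$start_offset +
      seq_len(n) * bi$resolution,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
}

#' Mirror image of a structure
#'
#' Negates the z axis. Pairwise distances — and therefore every MDS
#' objective — are blind to chirality, so a reconstruction may come out as
#' the enantiomer of the ground truth; recovery against a known truth is
#' assessed as the better of the structure and its mirror image under
#' proper-rotation superposition.
#'
#' @param structure A [structure3d()].
#' @return The mirrored [structure3d()].
#' @export
mirror_structure <- function(structure) {
  coords <- structure$coords
  coords[, 3] <- -coords[, 3]
  structure3d(coords, structure$bin_index, structure$provenance)
}

#' Write a 3D structure to disk
#'
#' Formats:
#' \describe{
#'   \item{`"xyz"`}{bead count, a comment line, then one `C x y z` line per
#'     bead.}
#'   \item{`"csv"`}{header `bead,chrom,start,end,x,y,z`, one row per bead.}
#'   \item{`"pdb-catrace"`}{one CA `ATOM` record per bead, residue number =
#'     bead index + 1; coordinates are rescaled when needed so the largest
#'     absolute value fits PDB's fixed-width 8.3 coordinate field.}
#' }
#'
#' @param structure A [structure3d()].
#' @param path Output file path.
#' @param format One of `"xyz"`, `"csv"`, `"pdb-catrace"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path,
                            format = c("xyz", "csv", "pdb-catrace")) {
  format <- match.arg(format)
  xyz <- structure$coords
  if (anyNA(xyz) || any(!is.finite(xyz))) stop("non-finite coordinate")
  n <- nrow(xyz)
  if (format == "xyz") {
    lines <- c(as.character(n), "tadstruct bead model",
               sprintf("C %.9g %.9g %.9g", xyz[, 1], xyz[, 2], xyz[, 3]))
    writeLines(lines, path)
  } else if (format == "csv") {
    utils::write.table(tidy(structure), path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    # PDB fixed columns allow at most 9999.999; rescale if out of range
    s <- max(abs(xyz))
    fac <- if (s > 999) 999 / s else 1
    m <- xyz * fac
    lines <- sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), seq_len(n), m[, 1], m[, 2], m[, 3])
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' Read a structure written by [write_structure()]
#'
#' @param path Input file path.
#' @param format One of `"xyz"`, `"csv"`, `"pdb-catrace"`.
#' @return A [structure3d()].
#' @export
read_structure <- function(path, format = c("xyz", "csv", "pdb-catrace")) {
  format <- match.arg(format)
  if (format == "xyz") {
    lines <- readLines(path)
    n <- as.integer(lines[1])
    parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    structure3d(xyz)
  } else if (format == "csv") {
    d <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
    bi <- NULL
    if (!anyNA(d$start) && nrow(d) >= 2) {
      bi <- bin_index(resolution = d$end[1] - d$start[1],
                      chrom = d$chrom[1], start_offset = d$start[1])
    }
    structure3d(as.matrix(d[, c("x", "y", "z")]), bin_index = bi)
  } else {
    lines <- grep("^ATOM", readLines(path), value = TRUE)
    xyz <- cbind(as.numeric(substr(lines, 31, 38)),
                 as.numeric(substr(lines, 39, 46)),
                 as.numeric(substr(lines, 47, 54)))
    structure3d(xyz)
  }
}

#' Plot a 3D bead chain as linked 2D projections
#'
#' @param object A [structure3d()].
#' @param ... Unused.
#' @return A ggplot object showing the xy, xz and yz projections of the
#'   chain, beads joined in genomic order and coloured by bead index.
#' @export
autoplot.structure3d <- function(object, ...) {
  td <- tidy(object)
  proj <- dplyr::bind_rows(
    tibble::tibble(panel = "xy", h = td$x, v = td$y, bead = td$bead),
    tibble::tibble(panel = "xz", h = td$x, v = td$z, bead = td$bead),
    tibble::tibble(panel = "yz", h = td$y, v = td$z, bead = td$bead)
  )
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$h, y = .data$v,
                                     colour = .data$bead)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_colour_viridis_c(name = "bead") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
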