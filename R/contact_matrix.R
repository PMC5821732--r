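#' Intra-chromosomal Hi-C contact matrix
#'
#' Construct a \code{contact_matrix}, the universal currency of the package:
#' a square, symmetric, non-negative matrix of contact counts (or normalized
#' real values) for one chromosome at a fixed bin size. Bins are 0-based,
#' half-open genomic intervals \code{[k*resolution, (k+1)*resolution)}.
#'
#' @param values Square numeric matrix of non-negative values.
#' @param resolution Bin size in base pairs (default 10000).
#' @param chrom Chromosome label.
#' @param is_normalized Logical; \code{TRUE} marks real-valued (normalized)
#'   matrices, \code{FALSE} raw integer counts.
#' @param symmetrize If \code{TRUE}, replace \code{values} by the average of
#'   itself and its transpose instead of rejecting asymmetric input.
#' @return An object of class \code{contact_matrix} with fields
#'   \code{chrom}, \code{resolution}, \code{n_bins}, \code{values},
#'   \code{is_normalized}.
#' @export
contact_matrix <- function(values, resolution = 10000L, chrom = "chrS",
                           is_normalized = FALSE, symmetrize = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    stop(sprintf("contact matrix must be square, got %d x %d",
                 nrow(values), ncol(values)))
  }
  if (anyNA(values)) stop("contact matrix contains missing values")
  if (any(values < 0)) stop("contact matrix contains negative entries")
  if (symmetrize) {
    values <- (values + t(values)) / 2
  } else if (!isTRUE(all.equal(values, t(values), tolerance = 1e-10,
                               check.attributes = FALSE))) {
    stop("contact matrix is not symmetric (set symmetrize = TRUE to average with the transpose)")
  }
  if (resolution <= 0) stop("`resolution` must be a positive number of bp")
  dimnames(values) <- NULL
  structure(
    list(chrom = as.character(chrom),
         resolution = as.numeric(resolution),
         n_bins = nrow(values),
         values = values,
         is_normalized = isTRUE(is_normalized)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %g bp (%s), total %g\n",
              x$chrom, x$n_bins, x$resolution,
              if (x$is_normalized) "normalized" else "raw counts",
              sum(x$values[upper.tri(x$values, diag = TRUE)])))
  invisible(x)
}

#' Read a dense whitespace-delimited contact matrix
#'
#' The file must contain one matrix row per line, all rows of equal length,
#' forming a square matrix. Lines starting with \code{#} are ignored.
#'
#' @param path File path.
#' @inheritParams contact_matrix
#' @return A \code{contact_matrix}.
#' @export
read_dense <- function(path, resolution = 10000L, chrom = "chrS",
                       is_normalized = FALSE, symmetrize = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("dense matrix file is empty: ", path)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("dense matrix file has ragged rows: ", path)
  }
  if (lens[1L] != length(rows)) {
    stop(sprintf("dense matrix file is not square (%d rows x %d columns): %s",
                 length(rows), lens[1L], path))
  }
  values <- do.call(rbind, rows)
  if (anyNA(values)) stop("dense matrix file has non-numeric entries: ", path)
  contact_matrix(values, resolution = resolution, chrom = chrom,
                 is_normalized = is_normalized, symmetrize = symmetrize)
}

#' Write a contact matrix as dense whitespace-delimited text
#'
#' @param m A \code{contact_matrix}.
#' @param path Output file path.
#' @param digits Significant digits used for real-valued matrices; integer
#'   count matrices are written exactly.
#' @export
write_dense <- function(m, path, digits = 17L) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  if (!m$is_normalized && is_whole(v)) {
    lines <- apply(v, 1L, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                            collapse = " "))
  } else {
    lines <- apply(v, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                            collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse triplet contact matrix
#'
#' Each non-comment line holds three whitespace-delimited columns
#' \code{bin_i bin_j value}. Every listed pair fills both \code{(i, j)} and
#' \code{(j, i)}; unlisted pairs are 0; duplicate lines for the same pair are
#' summed. \code{#} comment lines are ignored.
#'
#' @param path File path.
#' @param n_bins Number of bins of the (square) matrix.
#' @param index_base 0 (default) or 1; base of the bin indices in the file.
#' @inheritParams contact_matrix
#' @return A \code{contact_matrix}.
#' @export
read_triplets <- function(path, n_bins, resolution = 10000L, chrom = "chrS",
                          index_base = 0L, is_normalized = FALSE) {
  stopifnot(n_bins >= 1, index_base %in% c(0L, 1L))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  v <- matrix(0, n_bins, n_bins)
  if (any(keep)) {
    lineno <- which(keep)
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    bad <- which(lengths(fields) != 3L)
    if (length(bad) > 0L) {
      stop(sprintf("line %d: expected 3 columns (bin_i bin_j value)", lineno[bad[1L]]))
    }
    rec <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
    if (anyNA(rec)) {
      stop(sprintf("line %d: non-numeric field",
                   lineno[which(rowSums(is.na(rec)) > 0)[1L]]))
    }
    i <- rec[, 1L] - index_base
    j <- rec[, 2L] - index_base
    oob <- which(i < 0 | i >= n_bins | j < 0 | j >= n_bins)
    if (length(oob) > 0L) {
      stop(sprintf("line %d: bin index out of range [%d, %d]",
                   lineno[oob[1L]], index_base, n_bins - 1L + index_base))
    }
    if (any(rec[, 3L] < 0)) {
      stop(sprintf("line %d: negative count",
                   lineno[which(rec[, 3L] < 0)[1L]]))
    }
    # duplicates summed; each pair fills both triangles
    for (r in seq_len(nrow(rec))) {
      v[i[r] + 1L, j[r] + 1L] <- v[i[r] + 1L, j[r] + 1L] + rec[r, 3L]
    }
    v <- v + t(v)
    diag(v) <- diag(v) / 2
  }
  contact_matrix(v, resolution = resolution, chrom = chrom,
                 is_normalized = is_normalized)
}

#' Write a contact matrix as upper-triangle sparse triplets
#'
#' Emits one line \code{bin_i bin_j value} per non-zero entry with
#' \code{i <= j}.
#'
#' @inheritParams write_dense
#' @param index_base 0 (default) or 1; base of the emitted bin indices.
#' @export
write_triplets <- function(m, path, index_base = 0L) {
  stopifnot(inherits(m, "contact_matrix"), index_base %in% c(0L, 1L))
  v <- m$values
  ut <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  vals <- v[ut]
  lines <- paste(ut[, 1L] - 1L + index_base, ut[, 2L] - 1L + index_base,
                 formatC(vals, digits = 17L, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Zero all entries beyond a genomic distance band
#'
#' Entries with \code{|i - j| * resolution > max_dist} are set to 0; entries
#' within the band are unchanged. Only contacts within 2 Mb of the diagonal
#' are modelled by the enhancement network, so banding is applied throughout.
#'
#' @param m A \code{contact_matrix}.
#' @param max_dist Maximum genomic distance in bp (a non-negative multiple of
#'   the resolution).
#' @return A banded \code{contact_matrix}.
#' @export
band_mask <- function(m, max_dist) {
  stopifnot(inherits(m, "contact_matrix"))
  if (max_dist < 0) stop("`max_dist` must be non-negative")
  k <- max_dist / m$resolution
  if (!is_whole(k)) stop("`max_dist` must be a multiple of the resolution")
  v <- m$values
  v[bin_distance_matrix(m$n_bins) > round(k)] <- 0
  out <- m
  out$values <- v
  out
}
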