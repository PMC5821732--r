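#' Patch geometry for dividing and merging chromosome matrices
#'
#' The network consumes square input windows of side \code{N} bins and
#' emits predictions for the concentric \code{(N - padding)} window, the
#' border being consumed by the valid convolutions. With
#' \code{stride = N - padding} (the default) output windows tile the
#' chromosome seamlessly while input windows overlap by exactly
#' \code{padding} bins.
#'
#' @param N Input window side in bins (default 40, i.e. 0.4 Mb at 10 kb).
#' @param padding Total border loss in bins (default 12; must be even and
#'   smaller than \code{N}).
#' @param stride Step between window origins in bins.
#' @param max_dist_bins Band half-width in bins (default 200 = 2 Mb at
#'   10 kb); windows whose output contains no cell within the band are
#'   dropped.
#' @return An object of class \code{patch_geometry}.
#' @export
patch_geometry <- function(N = 40L, padding = 12L, stride = N - padding,
                           max_dist_bins = 200L) {
  N <- as.integer(N); padding <- as.integer(padding)
  stride <- as.integer(stride); max_dist_bins <- as.integer(max_dist_bins)
  if (padding %% 2L != 0L || padding <= 0L || padding >= N) {
    stop("`padding` must be even with 0 < padding < N")
  }
  if (stride < 1L) stop("`stride` must be >= 1")
  if (max_dist_bins < 0L) stop("`max_dist_bins` must be >= 0")
  structure(list(N = N, padding = padding, stride = stride,
                 max_dist_bins = max_dist_bins),
            class = "patch_geometry")
}

# Window origins: the lattice {0, stride, 2 stride, ...} plus a clamped
# final origin so the last window ends exactly at n_bins.
patch_origins <- function(n_bins, geom) {
  last <- n_bins - geom$N
  o <- seq.int(0L, last, by = geom$stride)
  if (o[length(o)] != last) o <- c(o, last)
  o
}

#' Divide a chromosome matrix into square training/prediction samples
#'
#' Input windows of side \code{geom$N} are placed on the origin lattice over
#' the upper triangle (\code{col_off >= row_off}); a window is kept iff its
#' output (target) region contains at least one cell within the genomic
#' distance band. When a companion high-depth matrix is given, each patch
#' carries the concentric \code{(N - padding)} target cut from it.
#'
#' @param low Low-depth \code{contact_matrix} supplying the inputs.
#' @param high Optional high-depth \code{contact_matrix} supplying the
#'   targets (prediction mode if absent).
#' @param geom A \code{\link{patch_geometry}}.
#' @return A list of patches (class \code{hic_patches}), each a list with
#'   \code{row_off}, \code{col_off} (0-based input-window origins),
#'   \code{input}, \code{target} (or \code{NULL}) and \code{chrom}.
#' @export
extract_patches <- function(low, high = NULL, geom = patch_geometry()) {
  stopifnot(inherits(low, "contact_matrix"), inherits(geom, "patch_geometry"))
  n <- low$n_bins
  if (n < geom$N) {
    stop(sprintf("matrix too small: %d bins < window size %d", n, geom$N))
  }
  if (!is.null(high)) {
    stopifnot(inherits(high, "contact_matrix"))
    if (high$n_bins != n) stop("`low` and `high` must have the same n_bins")
  }
  half <- geom$padding %/% 2L
  tside <- geom$N - geom$padding
  origins <- patch_origins(n, geom)
  patches <- list()
  for (r in origins) {
    for (cc in origins[origins >= r]) {
      # smallest |i - j| over the target window (0 if it straddles the
      # diagonal); windows entirely beyond the band are dropped
      min_d <- max(0L, (cc + half) - (r + half + tside - 1L))
      if (min_d > geom$max_dist_bins) next
      ri <- (r + 1L):(r + geom$N)
      ci <- (cc + 1L):(cc + geom$N)
      target <- if (!is.null(high)) {
        high$values[(r + half + 1L):(r + half + tside),
                    (cc + half + 1L):(cc + half + tside), drop = FALSE]
      }
      patches[[length(patches) + 1L]] <-
        list(row_off = r, col_off = cc,
             input = low$values[ri, ci, drop = FALSE],
             target = target, chrom = low$chrom)
    }
  }
  structure(patches, class = "hic_patches", geom = geom, n_bins = n,
            resolution = low$resolution)
}

#' Merge predicted patches back into a chromosome-wide matrix
#'
#' Each target cell is written at its absolute coordinates; cells covered by
#' several windows (clamped final windows, diagonal blocks seen from both
#' triangles) are averaged; the upper triangle is mirrored to the lower.
#' Cells never covered by any output window -- the border frame of width
#' \code{padding / 2} and the out-of-band region -- are filled from
#' \code{fallback} (normally the low-depth input), so the result is a
#' complete matrix. Negative predictions are clipped to 0.
#'
#' @param patches List of patches whose \code{target} holds predictions.
#' @param n_bins Side of the output matrix.
#' @param geom A \code{\link{patch_geometry}}.
#' @param fallback \code{contact_matrix} supplying uncovered cells.
#' @return A \code{contact_matrix}.
#' @export
merge_patches <- function(patches, n_bins, geom = attr(patches, "geom"),
                          fallback = NULL) {
  if (length(patches) == 0L) stop("no patches to merge")
  stopifnot(inherits(geom, "patch_geometry"), inherits(fallback, "contact_matrix"))
  if (fallback$n_bins != n_bins) stop("`fallback` shape mismatch")
  half <- geom$padding %/% 2L
  tside <- geom$N - geom$padding
  acc <- matrix(0, n_bins, n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  for (p in patches) {
    if (is.null(p$target)) stop("patch without a predicted target")
    if (!all(dim(p$target) == c(tside, tside))) {
      stop(sprintf("predicted target must be %d x %d", tside, tside))
    }
    ri <- (p$row_off + half + 1L):(p$row_off + half + tside)
    ci <- (p$col_off + half + 1L):(p$col_off + half + tside)
    acc[ri, ci] <- acc[ri, ci] + p$target
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  # pool (i, j) with (j, i) so both triangles inform the merged value
  accs <- acc + t(acc); diag(accs) <- diag(accs) / 2
  cnts <- cnt + t(cnt); diag(cnts) <- diag(cnts) / 2
  covered <- cnts > 0
  v <- fallback$values
  v[covered] <- pmax(0, accs[covered] / cnts[covered])
  contact_matrix(v, resolution = fallback$resolution, chrom = fallback$chrom,
                 is_normalized = TRUE, symmetrize = FALSE)
}

#' Coverage mask of the merged output region
#'
#' Logical matrix marking cells written by at least one output window for a
#' given chromosome size and geometry (after mirroring across the diagonal).
#'
#' @inheritParams merge_patches
#' @return An \code{n_bins x n_bins} logical matrix.
#' @export
patch_coverage <- function(n_bins, geom = patch_geometry()) {
  half <- geom$padding %/% 2L
  tside <- geom$N - geom$padding
  cnt <- matrix(0, n_bins, n_bins)
  for (r in patch_origins(n_bins, geom)) {
    for (cc in patch_origins(n_bins, geom)) {
      if (cc < r) next
      min_d <- max(0L, (cc + half) - (r + half + tside - 1L))
      if (min_d > geom$max_dist_bins) next
      ri <- (r + half + 1L):(r + half + tside)
      ci <- (cc + half + 1L):(cc + half + tside)
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  cnt + t(cnt) > 0
}
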