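#' Binomial read thinning of a contact matrix
#'
#' Simulates a shallower sequencing library: each upper-triangle count is
#' replaced by a draw from \code{Binomial(count, fraction)} and mirrored, so
#' that \code{E[out] = fraction * in}. Per-entry binomial thinning is
#' distributionally equivalent to subsampling individual reads when reads
#' are exchangeable. Diagonal entries are thinned like any other entry.
#'
#' @param m An integer-count \code{contact_matrix}
#'   (\code{is_normalized = FALSE}).
#' @param fraction Retention probability in (0, 1].
#' @param seed RNG seed (\code{NULL}: use the current RNG stream).
#' @return A thinned integer-count \code{contact_matrix}.
#' @export
downsample <- function(m, fraction, seed = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$is_normalized) {
    stop("downsampling is defined on raw read counts, not normalized matrices")
  }
  if (!is_whole(m$values)) {
    stop("downsampling requires integer counts")
  }
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  n <- m$n_bins
  ut <- upper.tri(matrix(0, n, n), diag = TRUE)
  counts <- round(m$values[ut])
  thinned <- if (fraction == 1) {
    counts
  } else {
    with_seed(seed, stats::rbinom(length(counts), size = counts, prob = fraction))
  }
  v <- matrix(0, n, n)
  v[ut] <- thinned
  v <- v + t(v)
  diag(v) <- diag(v) / 2
  out <- m
  out$values <- v
  out
}

#' Effective sequencing-depth ratio between two matrices
#'
#' Ratio of upper-triangle band sums, the quantity used to pick the
#' enhancement tier for a candidate matrix relative to the training matrix.
#' The band covers genomic distances \code{d_min} to \code{d_max}
#' inclusive; a lower bound that is not a multiple of the resolution is
#' rounded up to the first fully included distance (25 kb at 10 kb
#' resolution gives bins 3..100).
#'
#' @param candidate,reference \code{contact_matrix} objects at the same
#'   resolution.
#' @param d_min,d_max Genomic distance band in bp.
#' @return The scalar depth ratio.
#' @export
effective_depth_ratio <- function(candidate, reference,
                                  d_min = 25000, d_max = 1000000) {
  stopifnot(inherits(candidate, "contact_matrix"),
            inherits(reference, "contact_matrix"))
  if (candidate$resolution != reference$resolution) {
    stop("matrices must share a resolution")
  }
  if (d_min >= d_max) stop("`d_min` must be smaller than `d_max`")
  res <- candidate$resolution
  kmin <- ceiling(d_min / res)
  kmax <- floor(d_max / res)
  band_sum <- function(m) {
    d <- bin_distance_matrix(m$n_bins)
    sel <- upper.tri(d) & d >= kmin & d <= kmax
    sum(m$values[sel])
  }
  denom <- band_sum(reference)
  if (denom == 0) stop("reference matrix has zero signal in the band; ratio undefined")
  band_sum(candidate) / denom
}

#' Select the enhancement model tier for a depth ratio
#'
#' Tiers are (threshold, tag) pairs ordered by descending threshold; the
#' first tier whose threshold is <= the ratio wins, and ratios below every
#' threshold fall through to the deepest-enhancement tier (e.g. a candidate
#' below 1/16 of the training depth still uses the x16 model).
#'
#' @param ratio Effective depth ratio
#'   (see \code{\link{effective_depth_ratio}}).
#' @param tiers Data frame with columns \code{threshold} (descending) and
#'   \code{tag}.
#' @return The selected tag.
#' @export
select_model_tier <- function(ratio,
                              tiers = data.frame(
                                threshold = c(1 / 4, 1 / 8, 1 / 16),
                                tag = c("x4", "x8", "x16"))) {
  tiers <- as.data.frame(tiers)
  if (nrow(tiers) == 0L) stop("tier list is empty")
  if (!all(c("threshold", "tag") %in% names(tiers))) {
    stop("`tiers` needs columns threshold and tag")
  }
  if (is.unsorted(rev(tiers$threshold), strictly = TRUE) && nrow(tiers) > 1L) {
    stop("`tiers` must be ordered by descending threshold")
  }
  hit <- which(tiers$threshold <= ratio)
  if (length(hit) == 0L) {
    return(as.character(tiers$tag[nrow(tiers)]))
  }
  as.character(tiers$tag[hit[1L]])
}
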