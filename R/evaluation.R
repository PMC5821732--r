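#' Distance-stratified Pearson and Spearman correlation
#'
#' For each genomic distance \code{d = k * resolution},
#' \code{k = 0 .. max_dist / resolution}, collects the k-th upper diagonal
#' of both matrices and computes Pearson and Spearman correlations over
#' those bin pairs. Diagonals with fewer than two pairs, or zero variance
#' in either matrix, yield \code{NA} (recorded but excluded from
#' summaries).
#'
#' @param a,b \code{contact_matrix} objects of identical shape and
#'   resolution.
#' @param max_dist Maximum genomic distance in bp (default 2 Mb).
#' @return A data frame with columns \code{distance} (bp), \code{pearson},
#'   \code{spearman}, \code{n_pairs}.
#' @export
correlation_by_distance <- function(a, b, max_dist = 2e6) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (a$n_bins != b$n_bins || a$resolution != b$resolution) {
    stop("matrices must share shape and resolution")
  }
  n <- a$n_bins
  kmax <- min(n - 1L, floor(max_dist / a$resolution))
  ks <- 0:kmax
  pear <- spear <- rep(NA_real_, length(ks))
  npairs <- integer(length(ks))
  for (t in seq_along(ks)) {
    k <- ks[t]
    idx <- cbind(seq_len(n - k), seq_len(n - k) + k)
    x <- a$values[idx]
    y <- b$values[idx]
    npairs[t] <- length(x)
    if (length(x) >= 2L && stats::sd(x) > 0 && stats::sd(y) > 0) {
      pear[t] <- stats::cor(x, y)
      spear[t] <- stats::cor(x, y, method = "spearman")
    }
  }
  data.frame(distance = ks * a$resolution, pearson = pear,
             spearman = spear, n_pairs = npairs)
}

#' Compare several candidate matrices against a reference
#'
#' Runs \code{\link{correlation_by_distance}} for each named candidate and
#' also reports each method's mean correlation over the distances where it
#' is defined.
#'
#' @param truth Reference \code{contact_matrix}.
#' @param candidates Named list of \code{contact_matrix} candidates.
#' @param max_dist Maximum genomic distance in bp.
#' @return A list with \code{by_distance} (long data frame: distance,
#'   method, pearson, spearman, n_pairs) and \code{summary} (one row per
#'   method with mean_pearson / mean_spearman).
#' @export
summarize_methods <- function(truth, candidates, max_dist = 2e6) {
  stopifnot(inherits(truth, "contact_matrix"), is.list(candidates),
            length(candidates) > 0L, !is.null(names(candidates)),
            all(nzchar(names(candidates))))
  rows <- lapply(names(candidates), function(nm) {
    dc <- correlation_by_distance(candidates[[nm]], truth, max_dist)
    cbind(method = nm, dc)
  })
  by_distance <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(candidates), function(nm) {
    dc <- by_distance[by_distance$method == nm, ]
    data.frame(method = nm,
               mean_pearson = mean(dc$pearson, na.rm = TRUE),
               mean_spearman = mean(dc$spearman, na.rm = TRUE),
               n_distances = sum(!is.na(dc$pearson)))
  }))
  list(by_distance = by_distance, summary = summary)
}

#' Virtual 4C track anchored at one bin
#'
#' Extracts row \code{anchor} of the matrix as a one-dimensional
#' interaction profile with genomic coordinates -- the contact frequency of
#' every bin with the anchor.
#'
#' @param m A \code{contact_matrix}.
#' @param anchor 0-based anchor bin index.
#' @return A data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{value} (BED-like).
#' @export
virtual_4c <- function(m, anchor) {
  stopifnot(inherits(m, "contact_matrix"))
  anchor <- as.integer(anchor)
  if (anchor < 0L || anchor >= m$n_bins) {
    stop(sprintf("anchor bin %d out of range [0, %d]", anchor, m$n_bins - 1L))
  }
  bins <- 0:(m$n_bins - 1L)
  data.frame(chrom = m$chrom,
             start = bins * m$resolution,
             end = (bins + 1L) * m$resolution,
             value = m$values[anchor + 1L, ])
}
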