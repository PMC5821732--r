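#' Parametric description of a simulated chromosome
#'
#' A \code{synthetic_spec} describes the statistical structure the
#' enhancement network assumes in real Hi-C data: a power-law decay of
#' contact intensity with genomic distance, block-structured topologically
#' associating domains (TADs) enriched for self-interaction, focal loop
#' peaks between distal anchor pairs, and integer counts that scale linearly
#' with sequencing depth.
#'
#' The default spec is a 4 Mb chromosome at 10 kb resolution (400 bins) with
#' 8 TADs of heterogeneous size (300 kb to 1.1 Mb, spanning the range
#' typically reported for mammalian domains), 12 loops at anchor separations
#' from 150 kb to 1.5 Mb, and an expected in-band depth of 5e5 read pairs --
#' small enough for minute-scale CPU training yet structured at every
#' genomic distance the evaluation band covers.
#'
#' @param n_bins Number of bins.
#' @param resolution Bin size in bp.
#' @param decay_exponent Power-law exponent alpha of the distance decay
#'   \code{(1 + |i - j|)^-alpha} (default 1, the classic fractal-globule
#'   scaling).
#' @param baseline_intensity Multiplicative baseline of the intensity.
#' @param tad_boundaries Strictly increasing interior bin indices in
#'   \code{(0, n_bins)} partitioning the chromosome into TADs.
#' @param tad_enrichment Multiplicative contact enrichment (> 1) for bin
#'   pairs inside the same TAD.
#' @param loops Data frame with columns \code{anchor_i}, \code{anchor_j},
#'   \code{amplitude}, \code{width} (bins); each loop adds an isotropic 2D
#'   Gaussian bump at (anchor_i, anchor_j), mirrored.
#' @param depth Expected total number of in-band upper-triangle read pairs.
#' @param max_dist Band width in bp within which counts are simulated.
#' @param seed RNG seed used by \code{\link{make_pair}}.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_bins = 400L,
                           resolution = 10000L,
                           decay_exponent = 1,
                           baseline_intensity = 1,
                           tad_boundaries = NULL,
                           tad_enrichment = 3,
                           loops = NULL,
                           depth = 5e5,
                           max_dist = 2e6,
                           seed = 1L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L, resolution > 0, decay_exponent > 0,
            baseline_intensity > 0, tad_enrichment >= 1, depth > 0)
  if (is.null(tad_boundaries)) {
    # 8 domains: sizes 35,45,110,40,30,60,50,30 bins scaled to n_bins
    frac <- cumsum(c(35, 45, 110, 40, 30, 60, 50)) / 400
    tad_boundaries <- unique(pmin(n_bins - 1L, pmax(1L, round(frac * n_bins))))
  }
  tad_boundaries <- as.integer(tad_boundaries)
  if (length(tad_boundaries) > 0L) {
    if (any(diff(tad_boundaries) <= 0L) ||
        any(tad_boundaries < 0L | tad_boundaries > n_bins)) {
      stop("`tad_boundaries` must be strictly increasing within [0, n_bins]")
    }
  }
  if (is.null(loops)) {
    loops <- default_loops(n_bins, baseline_intensity, decay_exponent)
  }
  loops <- as.data.frame(loops)
  if (nrow(loops) > 0L) {
    needed <- c("anchor_i", "anchor_j", "amplitude", "width")
    if (!all(needed %in% names(loops))) {
      stop("`loops` needs columns anchor_i, anchor_j, amplitude, width")
    }
    if (any(loops$anchor_i < 0 | loops$anchor_j <= loops$anchor_i |
            loops$anchor_j >= n_bins)) {
      stop("loop anchors must satisfy 0 <= anchor_i < anchor_j < n_bins")
    }
    if (any(loops$amplitude < 0) || any(loops$width <= 0)) {
      stop("loop amplitudes must be >= 0 and widths > 0")
    }
  }
  structure(
    list(n_bins = n_bins, resolution = as.numeric(resolution),
         decay_exponent = decay_exponent,
         baseline_intensity = baseline_intensity,
         tad_boundaries = tad_boundaries,
         tad_enrichment = tad_enrichment,
         loops = loops, depth = depth, max_dist = max_dist,
         seed = seed),
    class = "synthetic_spec"
  )
}

# Fixed default loop set: anchors at separations 15..150 bins, amplitudes
# ~6x the local decay background so peaks are clearly focal but not
# dominant, width 1 bin (sharp corner-peak appearance).
default_loops <- function(n_bins, baseline, alpha) {
  anchors <- matrix(c(
     10,  30,   45,  70,   90, 140,  100, 180,
    150, 185,  195, 225,  210, 290,  235, 255,
    270, 330,  300, 345,  325, 390,  350, 395
  ), ncol = 2L, byrow = TRUE)
  anchors <- round(anchors * n_bins / 400)
  anchors[, 1L] <- pmax(0L, anchors[, 1L])
  anchors[, 2L] <- pmin(n_bins - 1L, anchors[, 2L])
  keep <- anchors[, 1L] < anchors[, 2L]
  anchors <- anchors[keep, , drop = FALSE]
  sep <- anchors[, 2L] - anchors[, 1L]
  data.frame(anchor_i = as.integer(anchors[, 1L]),
             anchor_j = as.integer(anchors[, 2L]),
             amplitude = 6 * baseline * (1 + sep)^(-alpha),
             width = 1)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d bins @ %g bp, alpha=%g, %d TADs (x%g), %d loops, depth %g\n",
    x$n_bins, x$resolution, x$decay_exponent,
    length(x$tad_boundaries) + 1L, x$tad_enrichment, nrow(x$loops), x$depth))
  invisible(x)
}

#' Expected contact intensity of a synthetic chromosome
#'
#' Computes the noise-free intensity surface
#' \deqn{\lambda_{ij} = b\,(1+|i-j|)^{-\alpha}\, E_{ij} +
#'   \sum_{loops} A \exp\{-((i-a_i)^2+(j-a_j)^2)/(2 w^2)\}}
#' where \eqn{E_{ij}} equals \code{tad_enrichment} when bins i and j lie in
#' the same TAD and 1 otherwise, and each loop bump is mirrored across the
#' diagonal. This surface is the ground truth that count sampling and all
#' recovery tests are measured against.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A real-valued \code{contact_matrix} (\code{is_normalized = TRUE}).
#' @export
ground_truth_intensity <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_bins
  d <- bin_distance_matrix(n)
  lambda <- spec$baseline_intensity * (1 + d)^(-spec$decay_exponent)
  if (length(spec$tad_boundaries) > 0L) {
    # TAD id per 0-based bin; boundaries are the first bin of the next TAD.
    # An empty boundary list means no domain structure at all.
    tad <- findInterval(0:(n - 1L), spec$tad_boundaries)
    same <- outer(tad, tad, "==")
    lambda[same] <- lambda[same] * spec$tad_enrichment
  }
  if (nrow(spec$loops) > 0L) {
    bins <- 0:(n - 1L)
    for (r in seq_len(nrow(spec$loops))) {
      ai <- spec$loops$anchor_i[r]; aj <- spec$loops$anchor_j[r]
      A <- spec$loops$amplitude[r]; w <- spec$loops$width[r]
      gi <- exp(-(bins - ai)^2 / (2 * w^2))
      gj <- exp(-(bins - aj)^2 / (2 * w^2))
      bump <- A * outer(gi, gj)
      lambda <- lambda + bump + t(bump)
    }
  }
  contact_matrix(lambda, resolution = spec$resolution, chrom = "chrS",
                 is_normalized = TRUE, symmetrize = TRUE)
}

#' Sample integer contact counts from an intensity surface
#'
#' The intensity is scaled so the expected in-band upper-triangle total
#' equals \code{depth}; upper-triangle entries are then drawn independently
#' from Poisson distributions and mirrored. Out-of-band entries are 0.
#'
#' @param intensity A real-valued \code{contact_matrix} of positive
#'   intensities.
#' @param depth Expected total in-band upper-triangle count.
#' @param max_dist Band width in bp.
#' @param seed RNG seed (\code{NULL}: use the current RNG stream).
#' @return An integer-count \code{contact_matrix}.
#' @export
sample_counts <- function(intensity, depth, max_dist, seed = NULL) {
  stopifnot(inherits(intensity, "contact_matrix"), depth > 0)
  n <- intensity$n_bins
  k <- floor(max_dist / intensity$resolution)
  d <- bin_distance_matrix(n)
  band_ut <- upper.tri(d, diag = TRUE) & d <= k
  lam <- intensity$values
  tot <- sum(lam[band_ut])
  if (tot <= 0) stop("intensity must be positive within the band")
  s <- depth / tot
  counts <- matrix(0, n, n)
  counts[band_ut] <- with_seed(seed, stats::rpois(sum(band_ut), s * lam[band_ut]))
  counts <- counts + t(counts)
  diag(counts) <- diag(counts) / 2
  contact_matrix(counts, resolution = intensity$resolution,
                 chrom = intensity$chrom, is_normalized = FALSE)
}

#' Simulate a deep/shallow Hi-C matrix pair
#'
#' Draws a deeply sequenced matrix at \code{spec$depth} and derives the
#' shallow companion by binomial read thinning (\code{\link{downsample}})
#' with the given fraction -- the train/enhance data regime of the method.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param fraction Thinning fraction in (0, 1].
#' @param seed RNG seed; defaults to \code{spec$seed}.
#' @return A list with elements \code{high}, \code{low} (both
#'   \code{contact_matrix}) and \code{truth} (the intensity surface).
#' @export
make_pair <- function(spec, fraction = 1 / 16, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"),
            fraction > 0, fraction <= 1)
  truth <- ground_truth_intensity(spec)
  with_seed(seed, {
    high <- sample_counts(truth, spec$depth, spec$max_dist, seed = NULL)
    low <- downsample(high, fraction, seed = NULL)
    list(high = high, low = low, truth = truth)
  })
}
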