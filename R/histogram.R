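#' Bivariate T1w/FLAIR intensity histogram
#'
#' Container for the binned joint intensity distribution of one imaging
#' session: uniform bin edges on each axis and a `bins x bins` count matrix
#' (rows index T1 bins, columns FLAIR bins).
#'
#' @param counts nonnegative numeric matrix, T1 bins x FLAIR bins.
#' @param t1_edges,flair_edges strictly increasing numeric bin-edge vectors,
#'   length `nrow(counts) + 1` / `ncol(counts) + 1`.
#' @param n_voxels total mass; defaults to `sum(counts)`.
#' @return Object of class `bihist`.
#' @export
bihist <- function(counts, t1_edges, flair_edges, n_voxels = sum(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("histogram counts must be nonnegative")
  if (length(t1_edges) != nrow(counts) + 1L ||
      length(flair_edges) != ncol(counts) + 1L)
    stop("bin-edge lengths do not match count matrix dimensions")
  if (any(diff(t1_edges) <= 0) || any(diff(flair_edges) <= 0))
    stop("bin edges must be strictly increasing")
  structure(list(counts = counts,
                 t1_edges = as.numeric(t1_edges),
                 flair_edges = as.numeric(flair_edges),
                 n_voxels = n_voxels),
            class = "bihist")
}

#' @export
print.bihist <- function(x, ...) {
  cat(sprintf("<bihist> %d x %d bins, mass %.6g\n", nrow(x$counts),
              ncol(x$counts), sum(x$counts)))
  cat(sprintf("  T1    range [%.3g, %.3g]\n", min(x$t1_edges), max(x$t1_edges)))
  cat(sprintf("  FLAIR range [%.3g, %.3g]\n", min(x$flair_edges), max(x$flair_edges)))
  invisible(x)
}

#' Robust intensity range of a masked image pair
#'
#' Percentile range (default 0.5-99.5) of in-mask T1 and FLAIR intensities;
#' used to fix the histogram frame so outlier voxels do not stretch the axes.
#'
#' @param t1,flair numeric arrays on the same grid.
#' @param mask logical array, same grid.
#' @param probs length-2 probability vector.
#' @return list with `t1` and `flair` length-2 ranges.
#' @export
intensity_range <- function(t1, flair, mask, probs = c(0.005, 0.995)) {
  check_same_grid(t1, flair, mask)
  m <- as.logical(mask) & is.finite(t1) & is.finite(flair)
  if (!any(m)) stop("empty mask: no finite in-mask voxels")
  list(t1 = unname(quantile(t1[m], probs)),
       flair = unname(quantile(flair[m], probs)))
}

check_same_grid <- function(...) {
  dims <- lapply(list(...), function(a) if (is.null(dim(a))) length(a) else dim(a))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("volumes are not on the same grid: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "))
  invisible(TRUE)
}

# clamp values into edge bins: index in 1..bins for every finite value
.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin.int(pmax.int(i, 1L), length(edges) - 1L)
}

#' Build the bivariate intensity histogram of a session
#'
#' Counts in-mask (T1, FLAIR) voxel pairs on a uniform 2-D grid. Voxels
#' outside `intensity_range` are clipped into the edge bins so histogram mass
#' always equals the number of in-mask voxels.
#'
#' @param t1,flair co-registered numeric arrays on the same grid.
#' @param mask logical array selecting brain voxels.
#' @param bins bins per axis (default 256).
#' @param intensity_range optional list with `t1`, `flair` length-2 ranges
#'   (e.g. a reference frame); defaults to the session's own robust range via
#'   [intensity_range()].
#' @return A [bihist].
#' @export
build_histogram <- function(t1, flair, mask, bins = 256L,
                            intensity_range = NULL) {
  check_same_grid(t1, flair, mask)
  m <- as.logical(mask)
  m[is.na(m)] <- FALSE
  if (!any(m)) stop("empty mask")
  x <- t1[m]; y <- flair[m]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) stop("empty mask: all in-mask voxels are non-finite")
  if (is.null(intensity_range))
    intensity_range <- list(t1 = unname(quantile(x, c(0.005, 0.995))),
                            flair = unname(quantile(y, c(0.005, 0.995))))
  bins <- as.integer(bins)
  stopifnot(bins >= 2L)
  t1_edges <- seq(intensity_range$t1[1], intensity_range$t1[2], length.out = bins + 1L)
  flair_edges <- seq(intensity_range$flair[1], intensity_range$flair[2], length.out = bins + 1L)
  ix <- .bin_index(x, t1_edges)
  iy <- .bin_index(y, flair_edges)
  counts <- matrix(tabulate(ix + (iy - 1L) * bins, nbins = bins * bins), bins, bins)
  bihist(counts, t1_edges, flair_edges, n_voxels = length(x))
}

#' Histogram frame (bin edges) shared by a population
#'
#' @param h a [bihist] supplying the frame.
#' @return list with `t1_edges`, `flair_edges`, `bins`.
#' @export
hist_frame <- function(h) {
  stopifnot(inherits(h, "bihist"))
  list(t1_edges = h$t1_edges, flair_edges = h$flair_edges,
       bins = nrow(h$counts))
}

# weighted point representation: centers of nonzero bins + their counts
hist_points <- function(h) {
  stopifnot(inherits(h, "bihist"))
  nz <- which(h$counts > 0, arr.ind = TRUE)
  tc <- (h$t1_edges[-1] + h$t1_edges[-length(h$t1_edges)]) / 2
  fc <- (h$flair_edges[-1] + h$flair_edges[-length(h$flair_edges)]) / 2
  list(pts = cbind(tc[nz[, 1]], fc[nz[, 2]]), w = h$counts[nz])
}

#' Re-bin a histogram onto a target frame, optionally through an affine
#'
#' Maps the weighted nonzero bin centers of `h` through `transform` (identity
#' if `NULL`) and accumulates them on `frame`. Out-of-frame mass is clipped
#' into the edge bins, so total mass is conserved exactly.
#'
#' @param h a [bihist].
#' @param frame a frame from [hist_frame()].
#' @param transform optional [iaffine2] applied to intensities first.
#' @return A [bihist] on `frame`.
#' @export
rebin_histogram <- function(h, frame, transform = NULL) {
  hp <- hist_points(h)
  pts <- hp$pts
  if (!is.null(transform)) pts <- affine_apply(transform, pts)
  bins <- frame$bins
  ix <- .bin_index(pts[, 1], frame$t1_edges)
  iy <- .bin_index(pts[, 2], frame$flair_edges)
  cnt <- numeric(bins * bins)
  idx <- ix + (iy - 1L) * bins
  agg <- rowsum(hp$w, idx)
  cnt[as.integer(rownames(agg))] <- agg[, 1]
  bihist(matrix(cnt, bins, bins), frame$t1_edges, frame$flair_edges,
         n_voxels = h$n_voxels)
}

# Gaussian smoothing kernel used by the registration cost
gauss_kernel <- function(sigma_bins = 2) {
  r <- max(1L, ceiling(3 * sigma_bins))
  k <- exp(-((-r):r)^2 / (2 * sigma_bins^2))
  k / sum(k)
}
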