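#' Specification of a paired T1w/FLAIR digital phantom
#'
#' Defines the geometry and tissue model of a synthetic image pair: a
#' rectangular brain mask containing a CSF slab, a WM slab, and a grey
#' matter slab tiled by `n_regions` axis-aligned labelled blocks. Voxel
#' intensities in each compartment follow a bivariate Gaussian, giving the
#' whole-brain joint histogram the three-mode CSF/GM/WM structure that makes
#' 2-D histogram registration identifiable. Realistic anatomy is irrelevant
#' to correctness here; speed and known ground truth are the point.
#'
#' @param grid_shape voxels per axis (default `c(64, 64, 64)`).
#' @param n_regions number of labelled grey-matter regions (default 80).
#' @param region_table parcellation metadata, defaults to
#'   [default_region_table()] truncated/expanded to `n_regions`.
#' @param scanner_affine an [iaffine2] emulating the arbitrary per-scanner
#'   intensity scale applied to every in-mask (T1, FLAIR) pair.
#' @param noise_sd extra iid intensity noise added to both channels.
#' @param rho within-tissue correlation between T1 and FLAIR draws.
#' @param voxel_size mm, metadata only.
#' @return list of class `phantom_spec` with the label map, mask and tissue
#'   parameter table precomputed.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), n_regions = 80L,
                         region_table = NULL,
                         scanner_affine = affine_identity(),
                         noise_sd = 0, rho = 0.25, voxel_size = 1) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            inherits(scanner_affine, "iaffine2"), noise_sd >= 0,
            rho > -1, rho < 1)
  n_regions <- as.integer(n_regions)
  if (is.null(region_table)) region_table <- default_region_table(n_regions)
  stopifnot(nrow(region_table) == n_regions)

  dims <- as.integer(grid_shape)
  border <- 2L
  lo <- rep(border + 1L, 3L)
  hi <- dims - border
  iz <- hi[3] - lo[3] + 1L
  z_csf <- max(2L, round(0.15 * iz))
  z_wm <- max(2L, round(0.30 * iz))
  z_gm <- iz - z_csf - z_wm
  if (z_gm < 1L) stop("grid too small for the three-compartment layout")

  labels <- array(0L, dims)          # 0 = background / CSF / WM
  tissue <- array(0L, dims)          # 0 bg, 1 CSF, 2 WM, 3 GM
  tissue[lo[1]:hi[1], lo[2]:hi[2], lo[3]:(lo[3] + z_csf - 1L)] <- 1L
  tissue[lo[1]:hi[1], lo[2]:hi[2], (lo[3] + z_csf):(lo[3] + z_csf + z_wm - 1L)] <- 2L
  gm_z0 <- lo[3] + z_csf + z_wm

  # tile the GM slab with n_regions near-cubic blocks
  f <- .factor3(n_regions)
  nx <- hi[1] - lo[1] + 1L; ny <- hi[2] - lo[2] + 1L
  if (f[1] > nx || f[2] > ny || f[3] > z_gm)
    stop("grid too small to tile ", n_regions, " regions")
  cx <- .cuts(nx, f[1]); cy <- .cuts(ny, f[2]); cz <- .cuts(z_gm, f[3])
  r <- 0L
  for (k in seq_len(f[3])) for (j in seq_len(f[2])) for (i in seq_len(f[1])) {
    r <- r + 1L
    xs <- (lo[1] + cx[i]):(lo[1] + cx[i + 1] - 1L)
    ys <- (lo[2] + cy[j]):(lo[2] + cy[j + 1] - 1L)
    zs <- (gm_z0 + cz[k]):(gm_z0 + cz[k + 1] - 1L)
    labels[xs, ys, zs] <- r
    tissue[xs, ys, zs] <- 3L
  }
  mask <- tissue > 0L

  structure(list(grid_shape = dims, n_regions = n_regions,
                 region_table = region_table,
                 tissue_params = .region_tissue_params(region_table),
                 csf = c(t1_mu = 30, t1_sd = 8, flair_mu = 20, flair_sd = 8),
                 wm = c(t1_mu = 160, t1_sd = 10, flair_mu = 90, flair_sd = 10),
                 scanner_affine = scanner_affine,
                 noise_sd = noise_sd, rho = rho, voxel_size = voxel_size,
                 labels = labels, tissue = tissue, mask = mask),
            class = "phantom_spec")
}

# split n into 3 factors with product exactly n, as cubic as possible
.factor3 <- function(n) {
  best <- c(n, 1L, 1L)
  for (a in seq_len(floor(n^(1 / 3)) + 1L)) {
    if (n %% a) next
    m <- n %/% a
    for (b in seq_len(floor(sqrt(m)) + 1L)) {
      if (m %% b) next
      cand <- sort(c(a, b, m %/% b), decreasing = TRUE)
      if (cand[1] / cand[3] < best[1] / best[3]) best <- cand
    }
  }
  as.integer(best)
}

.cuts <- function(n, k) round(seq(0, n, length.out = k + 1L))

# correlated bivariate normal draws: n x 2
.biv_draw <- function(n, mu1, sd1, mu2, sd2, rho) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(mu1 + sd1 * z1,
        mu2 + sd2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Simulate one paired T1w/FLAIR phantom session
#'
#' Draws voxel intensities per compartment from the phantom's bivariate
#' tissue model, shifts affected grey-matter regions according to the
#' effect model at the visit's EYO (carriers only), then applies the
#' scanner intensity affine to every in-mask (T1, FLAIR) pair. The true
#' pre-scanner regional parameters are returned for oracle tests.
#'
#' @param visit list or one-row data frame with `eyo` and `mutation_status`.
#' @param spec a [phantom_spec()].
#' @param effect an [effect_model()].
#' @param seed integer seed.
#' @param scanner_affine optional override of `spec$scanner_affine`.
#' @return list: `t1`, `flair` (arrays), `labels`, `mask`,
#'   `truth` (data frame of true pre-scanner per-region t1_mu/t1_sd/
#'   flair_mu/flair_sd), `spec`.
#' @export
simulate_phantom_pair <- function(visit, spec, effect = effect_model(),
                                  seed = 1L, scanner_affine = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(scanner_affine)) scanner_affine <- spec$scanner_affine
  eyo <- visit$eyo
  carrier <- identical(as.character(visit$mutation_status), "carrier")
  set.seed(as.integer(seed))

  d <- effect_deltas(effect, eyo, carrier, spec$tissue_params$region_id)
  truth <- data.frame(
    region_id = spec$tissue_params$region_id,
    t1_mu = spec$tissue_params$t1_mu + d$t1_mu,
    t1_sd = pmax(0.5, spec$tissue_params$t1_sd + d$t1_sigma),
    flair_mu = spec$tissue_params$flair_mu + d$flair_mu,
    flair_sd = pmax(0.5, spec$tissue_params$flair_sd + d$flair_sigma))

  t1 <- array(0, spec$grid_shape)
  fl <- array(0, spec$grid_shape)
  for (cls in 1:2) {
    idx <- which(spec$tissue == cls)
    prm <- if (cls == 1) spec$csf else spec$wm
    v <- .biv_draw(length(idx), prm["t1_mu"], prm["t1_sd"],
                   prm["flair_mu"], prm["flair_sd"], spec$rho)
    t1[idx] <- v[, 1]; fl[idx] <- v[, 2]
  }
  for (r in seq_len(spec$n_regions)) {
    idx <- which(spec$labels == r)
    v <- .biv_draw(length(idx), truth$t1_mu[r], truth$t1_sd[r],
                   truth$flair_mu[r], truth$flair_sd[r], spec$rho)
    t1[idx] <- v[, 1]; fl[idx] <- v[, 2]
  }
  if (spec$noise_sd > 0) {
    idx <- which(spec$mask)
    t1[idx] <- t1[idx] + rnorm(length(idx), 0, spec$noise_sd)
    fl[idx] <- fl[idx] + rnorm(length(idx), 0, spec$noise_sd)
  }
  # scanner intensity distortion
  idx <- which(spec$mask)
  v <- affine_apply(scanner_affine, cbind(t1[idx], fl[idx]))
  t1[idx] <- v[, 1]; fl[idx] <- v[, 2]

  list(t1 = t1, flair = fl, labels = spec$labels, mask = spec$mask,
       truth = truth, spec = spec)
}

#' Draw weighted samples from the phantom's reference intensity mixture
#'
#' Samples (T1, FLAIR) pairs from the CSF/WM/GM mixture with the phantom's
#' default (reference) parameters - useful for building reference atlases
#' and planted-affine experiments without simulating full volumes.
#'
#' @param n number of samples.
#' @param spec a [phantom_spec()] supplying the tissue model.
#' @param seed integer seed.
#' @return n x 2 matrix of (T1, FLAIR) samples.
#' @export
sample_reference_mixture <- function(n, spec = phantom_spec(grid_shape = c(16, 16, 16), n_regions = 8L),
                                     seed = 1L) {
  set.seed(as.integer(seed))
  w <- c(csf = 0.15, wm = 0.35, gm = 0.5)
  n_cls <- c(round(n * w[1]), round(n * w[2]))
  n_cls <- c(n_cls, n - sum(n_cls))
  out <- matrix(NA_real_, n, 2)
  at <- 0L
  prms <- list(spec$csf, spec$wm)
  for (k in 1:2) {
    m <- n_cls[k]
    out[at + seq_len(m), ] <- .biv_draw(m, prms[[k]]["t1_mu"], prms[[k]]["t1_sd"],
                                        prms[[k]]["flair_mu"], prms[[k]]["flair_sd"],
                                        spec$rho)
    at <- at + m
  }
  reg <- sample(seq_len(spec$n_regions), n_cls[3], replace = TRUE)
  tp <- spec$tissue_params
  out[at + seq_len(n_cls[3]), ] <- .biv_draw(n_cls[3], tp$t1_mu[reg], tp$t1_sd[reg],
                                             tp$flair_mu[reg], tp$flair_sd[reg],
                                             spec$rho)
  out
}

#' Histogram of an intensity sample matrix
#'
#' Convenience wrapper treating an n x 2 sample matrix as a fully in-mask
#' "image", for reference-building and registration experiments.
#'
#' @param samples n x 2 matrix of (T1, FLAIR) intensities.
#' @param bins bins per axis.
#' @param intensity_range optional frame range, as in [build_histogram()].
#' @return a [bihist].
#' @export
histogram_from_samples <- function(samples, bins = 256L, intensity_range = NULL) {
  build_histogram(samples[, 1], samples[, 2],
                  rep(TRUE, nrow(samples)), bins = bins,
                  intensity_range = intensity_range)
}
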