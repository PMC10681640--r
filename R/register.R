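#' Options for bivariate histogram registration
#'
#' The registration cost is the negative Pearson correlation between the
#' Gaussian-smoothed, log-compressed subject histogram (re-binned on the
#' reference frame after pushing its mass through the candidate affine) and
#' the reference treated the same way. It is minimized by Nelder-Mead over
#' the 6-parameter affine chart (2 scales, 2 shears, 2 offsets) from a small
#' deterministic multi-start schedule: identity plus axis-wise scale
#' perturbations of +/-20 percent.
#'
#' @param sigma_bins Gaussian smoothing width in bins (default 2).
#' @param maxit evaluation budget per start (default 2000).
#' @param reltol relative convergence tolerance on the cost (default 1e-6).
#' @param starts matrix of starting parameter vectors, one row per start.
#' @param early_stop_cost skip remaining starts once a start reaches this
#'   cost (negative correlation; default -0.99, i.e. NCC >= 0.99).
#' @param min_similarity final normalized correlation below which the result
#'   is flagged as non-converged (default 0.2).
#' @param coarse_factor histogram downsampling factor for the multi-start
#'   search stage (coarse-to-fine schedule; 1 disables). The incumbent from
#'   the coarse stage is always refined at full resolution.
#' @return list of options for [register_histogram()].
#' @export
reg_options <- function(sigma_bins = 2, maxit = 2000, reltol = 1e-6,
                        starts = NULL, early_stop_cost = -0.99,
                        min_similarity = 0.2, coarse_factor = 2) {
  if (is.null(starts)) {
    starts <- rbind(rep(0, 6),
                    c( 0.2, 0, 0, 0, 0, 0),
                    c(-0.2, 0, 0, 0, 0, 0),
                    c(0,  0.2, 0, 0, 0, 0),
                    c(0, -0.2, 0, 0, 0, 0))
  }
  list(sigma_bins = sigma_bins, maxit = maxit, reltol = reltol,
       starts = starts, early_stop_cost = early_stop_cost,
       min_similarity = min_similarity, coarse_factor = coarse_factor)
}

.as_bihist <- function(reference) {
  if (inherits(reference, "ref_atlas")) reference$histogram
  else if (inherits(reference, "bihist")) reference
  else stop("reference must be a 'bihist' or 'ref_atlas'")
}

#' Affine-register a session histogram to a reference histogram
#'
#' Recovers the 2-D intensity-space affine that maps the subject's joint
#' (T1w, FLAIR) intensity distribution onto the reference distribution. This
#' is the core of bispectral intensity normalization: the arbitrary per
#' scanner/session intensity scale appears as an affine distortion of the
#' joint histogram, and registering histograms undoes it without any spatial
#' correspondence.
#'
#' @param subject a [bihist] for the session (any frame).
#' @param reference a [bihist] or `ref_atlas`; its frame defines the target
#'   intensity space.
#' @param options from [reg_options()].
#' @return list of class `iim_registration` with elements `transform`
#'   ([iaffine2] mapping subject intensities to reference intensities),
#'   `cost` (negative normalized correlation at the optimum), `cost_identity`,
#'   `converged`, and `start_used`.
#' @export
register_histogram <- function(subject, reference, options = reg_options()) {
  stopifnot(inherits(subject, "bihist"))
  ref <- .as_bihist(reference)
  frame <- hist_frame(ref)
  # overlapping supports sanity check
  if (max(subject$t1_edges) < min(frame$t1_edges) ||
      min(subject$t1_edges) > max(frame$t1_edges))
    warning("subject and reference T1 intensity supports barely overlap")

  hp <- hist_points(subject)
  W <- sum(hp$w)
  kernel <- gauss_kernel(options$sigma_bins)
  ref_scaled <- ref$counts / sum(ref$counts) * W
  ref_smooth <- cpp_smooth2d(log1p(ref_scaled), kernel)

  t1_lo <- frame$t1_edges[1]
  t1_step <- diff(frame$t1_edges[1:2])
  f_lo <- frame$flair_edges[1]
  f_step <- diff(frame$flair_edges[1:2])
  span_t1 <- diff(range(frame$t1_edges))
  span_f <- diff(range(frame$flair_edges))

  cost_fn <- function(par)
    cpp_reg_cost(par, hp$pts, hp$w, t1_lo, t1_step, f_lo, f_step,
                 frame$bins, kernel, ref_smooth)

  parscale <- c(0.1, 0.1, 0.1, 0.1, 0.05 * span_t1, 0.05 * span_f)
  cost_id <- cost_fn(rep(0, 6))

  # coarse stage: the affine chart is expressed in intensity units, so the
  # same parameter vector is valid at every histogram resolution
  cf <- max(1L, as.integer(options$coarse_factor))
  search_fn <- cost_fn
  if (cf > 1L && frame$bins %% cf == 0L) {
    bins_c <- frame$bins %/% cf
    frame_c <- list(t1_edges = frame$t1_edges[seq(1, frame$bins + 1, by = cf)],
                    flair_edges = frame$flair_edges[seq(1, frame$bins + 1, by = cf)],
                    bins = bins_c)
    kernel_c <- gauss_kernel(max(0.5, options$sigma_bins / cf))
    ref_c <- rebin_histogram(ref, frame_c)
    ref_smooth_c <- cpp_smooth2d(log1p(ref_c$counts / sum(ref_c$counts) * W),
                                 kernel_c)
    search_fn <- function(par)
      cpp_reg_cost(par, hp$pts, hp$w, frame_c$t1_edges[1], t1_step * cf,
                   frame_c$flair_edges[1], f_step * cf, bins_c, kernel_c,
                   ref_smooth_c)
  }
  best <- NULL
  start_used <- NA_integer_
  for (s in seq_len(nrow(options$starts))) {
    fit <- stats::optim(options$starts[s, ], search_fn, method = "Nelder-Mead",
                        control = list(maxit = options$maxit,
                                       reltol = options$reltol,
                                       parscale = parscale))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      start_used <- s
    }
    if (best$value <= options$early_stop_cost) break
  }
  # full-resolution refinement from the coarse incumbent
  best <- stats::optim(best$par, cost_fn, method = "Nelder-Mead",
                       control = list(maxit = options$maxit,
                                      reltol = options$reltol,
                                      parscale = parscale / 4))
  # polish: restart the simplex at the incumbent optimum (Nelder-Mead
  # restarts recover from degenerate simplexes cheaply)
  for (k in 1:2) {
    fit <- stats::optim(best$par, cost_fn, method = "Nelder-Mead",
                        control = list(maxit = options$maxit,
                                       reltol = options$reltol,
                                       parscale = parscale / 10))
    improved <- best$value - fit$value
    if (fit$value < best$value) best <- fit
    if (improved < 10 * options$reltol) break
  }
  # convergence code 10 is simplex degeneracy, benign at an optimum
  converged <- best$convergence %in% c(0L, 10L) &&
    -best$value >= options$min_similarity
  if (!converged)
    warning(sprintf(paste0("histogram registration flagged as non-converged ",
                           "(optim code %d, similarity %.3f)"),
                    best$convergence, -best$value))
  structure(list(transform = affine_from_params(best$par),
                 cost = best$value,
                 cost_identity = cost_id,
                 converged = converged,
                 start_used = start_used),
            class = "iim_registration")
}

#' @export
print.iim_registration <- function(x, ...) {
  cat(sprintf("<iim_registration> similarity %.4f (identity %.4f), %s\n",
              -x$cost, -x$cost_identity,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}

#' Build a normative reference histogram from a healthy population
#'
#' Iterative register-and-average construction: initialize the reference as
#' the normalized mean of the member histograms (re-binned on a common
#' frame); then on each iteration register every member to the current
#' reference, average the transformed histograms, and renormalize to unit
#' mass. Members whose registration is flagged non-converged are dropped with
#' a warning.
#'
#' @param histograms list of [bihist] objects (at least 2).
#' @param n_iterations register-average iterations (default 3).
#' @param frame optional target frame ([hist_frame()]); defaults to the
#'   frame of the first member.
#' @param options registration options, see [reg_options()].
#' @return list of class `ref_atlas`: `histogram` (unit-mass [bihist]),
#'   `provenance` (member ids used), `dropped`, `n_iterations`.
#' @export
build_reference <- function(histograms, n_iterations = 3, frame = NULL,
                            options = reg_options()) {
  stopifnot(is.list(histograms), length(histograms) >= 2L)
  ids <- names(histograms)
  if (is.null(ids)) ids <- as.character(seq_along(histograms))
  if (is.null(frame)) frame <- hist_frame(histograms[[1]])

  norm_mean <- function(hists) {
    acc <- Reduce(`+`, lapply(hists, function(h) h$counts / sum(h$counts)))
    bihist(acc / sum(acc), frame$t1_edges, frame$flair_edges, n_voxels = 1)
  }
  members <- lapply(histograms, rebin_histogram, frame = frame)
  ref <- norm_mean(members)
  dropped <- character(0)
  active <- seq_along(histograms)

  for (it in seq_len(n_iterations)) {
    transformed <- list()
    still <- integer(0)
    for (i in active) {
      reg <- withCallingHandlers(
        register_histogram(histograms[[i]], ref, options),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!reg$converged) {
        dropped <- union(dropped, ids[i])
        next
      }
      transformed[[length(transformed) + 1L]] <-
        rebin_histogram(histograms[[i]], frame, transform = reg$transform)
      still <- c(still, i)
    }
    if (length(transformed) < 2L)
      stop("reference construction failed: fewer than 2 members registered")
    active <- still
    ref <- norm_mean(transformed)
  }
  if (length(dropped))
    warning("dropped from reference construction (registration failure): ",
            paste(dropped, collapse = ", "))
  structure(list(histogram = ref, provenance = ids[active],
                 dropped = dropped, n_iterations = n_iterations),
            class = "ref_atlas")
}

#' @export
print.ref_atlas <- function(x, ...) {
  cat(sprintf("<ref_atlas> %d contributing sessions, %d iterations\n",
              length(x$provenance), x$n_iterations))
  print(x$histogram)
  invisible(x)
}
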