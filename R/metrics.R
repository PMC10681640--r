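#' Extract regional image-intensity metrics (IIM) from a normalized session
#'
#' For every region in the parcellation, computes the mean and the
#' population standard deviation (divide by n) of the in-region, non-missing
#' normalized T1w and FLAIR intensities: T1-mu, T1-sigma, FLAIR-mu,
#' FLAIR-sigma. Out-of-mask voxels carry the NaN/NA sentinel from
#' [apply_transform()] and never contribute. Regions with fewer than
#' `min_voxels` usable voxels are flagged missing (metrics set to `NA`)
#' rather than reported as zeros.
#'
#' @param t1_norm,flair_norm normalized intensity arrays.
#' @param label_map integer-coded parcellation array on the same grid.
#' @param region_table data frame with `region_id` (and optionally `name`,
#'   `hemisphere`, `class`); defaults to the standard 80-region set.
#' @param min_voxels minimum usable voxels per region (default 10).
#' @param session_id id recorded on each output row.
#' @return data frame with one row per region: `session_id`, `region_id`,
#'   `n_voxels`, `t1_mu`, `t1_sigma`, `flair_mu`, `flair_sigma`, `missing`.
#' @export
extract_iim <- function(t1_norm, flair_norm, label_map,
                        region_table = default_region_table(),
                        min_voxels = 10L, session_id = NA_character_) {
  check_same_grid(t1_norm, flair_norm, label_map)
  stopifnot("region_id" %in% names(region_table))
  lab <- as.integer(label_map)
  known <- c(0L, region_table$region_id)
  stray <- setdiff(unique(lab), known)
  if (length(stray)) {
    warning("label map contains labels absent from region_table (excluded): ",
            paste(sort(stray), collapse = ", "))
    lab[lab %in% stray] <- 0L
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- lapply(region_table$region_id, function(r) {
    idx <- which(lab == r)
    x <- t1_norm[idx]; y <- flair_norm[idx]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < min_voxels)
      data.frame(session_id = session_id, region_id = r, n_voxels = n,
                 t1_mu = NA_real_, t1_sigma = NA_real_,
                 flair_mu = NA_real_, flair_sigma = NA_real_,
                 missing = TRUE, stringsAsFactors = FALSE)
    else
      data.frame(session_id = session_id, region_id = r, n_voxels = n,
                 t1_mu = mean(x), t1_sigma = pop_sd(x),
                 flair_mu = mean(y), flair_sigma = pop_sd(y),
                 missing = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
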