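#' Apply an intensity affine to an image pair
#'
#' Pushes every in-mask (T1, FLAIR) voxel pair jointly through the affine.
#' Out-of-mask voxels are set to `NA` (written as NaN in floating-point
#' NIfTI output), so downstream regional statistics can ignore them.
#'
#' @param t1,flair numeric arrays on the same grid.
#' @param affine an [iaffine2] (must be invertible, which the class enforces).
#' @param mask logical array on the same grid.
#' @return list with `t1` and `flair` arrays of the input shape.
#' @export
apply_transform <- function(t1, flair, affine, mask) {
  stopifnot(inherits(affine, "iaffine2"))
  check_same_grid(t1, flair, mask)
  m <- as.logical(mask)
  m[is.na(m)] <- FALSE
  out_t1 <- array(NA_real_, dim = dim(t1))
  out_fl <- array(NA_real_, dim = dim(flair))
  v <- affine_apply(affine, cbind(t1[m], flair[m]))
  out_t1[m] <- v[, 1]
  out_fl[m] <- v[, 2]
  list(t1 = out_t1, flair = out_fl)
}

#' Normalize one imaging session against a reference atlas
#'
#' Composes the full bispectral normalization for a session: build the joint
#' (T1w, FLAIR) histogram, affine-register it to the normative reference,
#' and apply the recovered intensity transform to both images.
#'
#' @param t1,flair co-registered numeric arrays.
#' @param mask logical brain mask on the same grid.
#' @param reference a `ref_atlas` (or [bihist]) defining the target frame.
#' @param options registration options, see [reg_options()].
#' @param session_id optional id recorded in the QC record.
#' @return list with `t1`, `flair` (normalized arrays), `transform`
#'   ([iaffine2]), `registration` and `qc` (one-row data frame: session,
#'   similarity, convergence, transform parameters).
#' @export
normalize_session <- function(t1, flair, mask, reference,
                              options = reg_options(),
                              session_id = NA_character_) {
  ref <- .as_bihist(reference)
  h <- build_histogram(t1, flair, mask, bins = nrow(ref$counts))
  reg <- register_histogram(h, reference, options)
  imgs <- apply_transform(t1, flair, reg$transform, mask)
  par <- affine_params(reg$transform)
  qc <- data.frame(session_id = session_id,
                   similarity = -reg$cost,
                   similarity_identity = -reg$cost_identity,
                   converged = reg$converged,
                   scale_t1 = 1 + par[1], scale_flair = 1 + par[2],
                   shear_t1 = par[3], shear_flair = par[4],
                   offset_t1 = par[5], offset_flair = par[6],
                   stringsAsFactors = FALSE)
  list(t1 = imgs$t1, flair = imgs$flair, transform = reg$transform,
       registration = reg, qc = qc)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti that keep double precision so that generated
#' volumes round-trip bit-exactly.
#'
#' @param vol numeric 3-D array (or logical/integer for masks and label maps).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   plain array.
#' @export
write_volume <- function(vol, path) {
  storage <- if (is.logical(vol) || is.integer(vol)) "int32" else "double"
  RNifti::writeNifti(RNifti::asNifti(vol * 1), path, datatype = storage)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}
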