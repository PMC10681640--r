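#' 2-D intensity-space affine transform
#'
#' An affine map of the joint (T1w, FLAIR) intensity plane,
#' \eqn{v' = L v + b} with \eqn{L} a 2x2 matrix and \eqn{b} a length-2
#' offset, both in intensity units. These transforms are what histogram
#' registration recovers and what [apply_transform()] pushes voxel pairs
#' through.
#'
#' @param linear 2x2 numeric matrix; must be invertible.
#' @param offset numeric length-2 offset (T1, FLAIR intensity units).
#' @return An object of class `iaffine2`.
#' @examples
#' a <- iaffine2(diag(c(1.2, 0.9)), c(10, -5))
#' affine_apply(a, cbind(100, 130))
#' @export
iaffine2 <- function(linear = diag(2), offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 2L)
  if (!all(is.finite(linear)) || !all(is.finite(offset)))
    stop("affine parameters must be finite")
  if (abs(det(linear)) < .Machine$double.eps * 100)
    stop("singular linear part: intensity affine must be invertible")
  structure(list(linear = linear, offset = offset), class = "iaffine2")
}

#' @export
print.iaffine2 <- function(x, ...) {
  cat("<iaffine2>  v' = L v + b\n")
  cat(sprintf("  L = [%8.4f %8.4f; %8.4f %8.4f]\n",
              x$linear[1, 1], x$linear[1, 2], x$linear[2, 1], x$linear[2, 2]))
  cat(sprintf("  b = [%8.3f %8.3f]\n", x$offset[1], x$offset[2]))
  invisible(x)
}

#' Identity intensity affine
#' @return `iaffine2` identity transform.
#' @export
affine_identity <- function() iaffine2(diag(2), c(0, 0))

#' Compose two intensity affines
#'
#' Returns the transform "`a` after `b`": `x -> a(b(x))`.
#' @param a,b `iaffine2` objects.
#' @return `iaffine2`.
#' @export
affine_compose <- function(a, b) {
  stopifnot(inherits(a, "iaffine2"), inherits(b, "iaffine2"))
  iaffine2(a$linear %*% b$linear, as.vector(a$linear %*% b$offset) + a$offset)
}

#' Invert an intensity affine
#' @param a `iaffine2`.
#' @return `iaffine2` with `affine_compose(a, affine_invert(a))` = identity.
#' @export
affine_invert <- function(a) {
  stopifnot(inherits(a, "iaffine2"))
  li <- solve(a$linear)
  iaffine2(li, -as.vector(li %*% a$offset))
}

#' Apply an intensity affine to (T1, FLAIR) pairs
#' @param a `iaffine2`.
#' @param xy n x 2 numeric matrix of (T1, FLAIR) intensities.
#' @return n x 2 matrix of transformed intensities.
#' @export
affine_apply <- function(a, xy) {
  stopifnot(inherits(a, "iaffine2"))
  xy <- matrix(as.numeric(xy), ncol = 2L)
  sweep(xy %*% t(a$linear), 2L, a$offset, "+")
}

# 6-parameter chart around the identity used by the optimizer:
# par = (s1, s2, sh1, sh2, o1, o2),  L = [[1+s1, sh1], [sh2, 1+s2]], b = (o1, o2)
affine_from_params <- function(par) {
  stopifnot(length(par) == 6L)
  iaffine2(matrix(c(1 + par[1], par[4], par[3], 1 + par[2]), 2, 2),
           c(par[5], par[6]))
}

affine_params <- function(a) {
  stopifnot(inherits(a, "iaffine2"))
  c(a$linear[1, 1] - 1, a$linear[2, 2] - 1, a$linear[1, 2], a$linear[2, 1],
    a$offset[1], a$offset[2])
}

#' Serialize / deserialize an intensity affine as JSON
#'
#' The linear part is stored row-major together with the offset, so the file
#' is readable by any downstream tool.
#' @param a `iaffine2`.
#' @param path file path.
#' @return `affine_write_json` returns `path` invisibly; `affine_read_json`
#'   returns an `iaffine2`.
#' @export
affine_write_json <- function(a, path) {
  stopifnot(inherits(a, "iaffine2"))
  obj <- list(linear_row_major = as.vector(t(a$linear)), offset = a$offset)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname affine_write_json
#' @export
affine_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  iaffine2(matrix(obj$linear_row_major, 2, 2, byrow = TRUE), obj$offset)
}
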