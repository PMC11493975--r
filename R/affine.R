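#' Affine transform between MIMS and EM pixel coordinates
#'
#' @param A 2x2 linear part (invertible).
#' @param b Length-2 offset.
#' @return Object of class `affine_transform`.
#' @export
affine_transform <- function(A, b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  stopifnot(length(b) == 2L, all(is.finite(A)), all(is.finite(b)))
  if (abs(det(A)) <= 1e-12) stop("linear part is singular")
  structure(list(A = A, b = b), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("Affine transform: x' = A x + b\n")
  print(cbind(x$A, b = x$b))
  invisible(x)
}

#' Fit an affine transform from fiducial point pairs
#'
#' Least-squares estimate of the 2D affine map taking MIMS fiducial
#' coordinates onto their EM counterparts (the 32S fiducials projected on the
#' SEM image). Each output coordinate is a linear model in the two input
#' coordinates plus an intercept, solved by ordinary least squares.
#'
#' @param src n x 2 matrix of MIMS points (n >= 3, non-collinear).
#' @param dst n x 2 matrix of matching EM points.
#' @return An `affine_transform` with attributes `residuals` (n x 2) and
#'   `rms_residual`.
#' @export
fit_fiducial_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst))
  if (nrow(src) < 3L) stop("need at least 3 fiducial pairs")
  X <- cbind(1, src)
  if (qr(X)$rank < 3L) stop("fiducials are collinear: geometry is degenerate")
  coefs <- qr.solve(X, dst)          # 3 x 2: intercepts then linear terms
  b <- coefs[1, ]
  A <- t(coefs[2:3, , drop = FALSE]) # rows: output dims, cols: input dims
  tr <- affine_transform(A, b)
  fitted <- X %*% coefs
  res <- dst - fitted
  attr(tr, "residuals") <- res
  attr(tr, "rms_residual") <- sqrt(mean(res^2))
  tr
}

#' Apply an affine transform to points
#'
#' Maps each row of an n x 2 point matrix as `x' = A x + b`.
#'
#' @param transform An `affine_transform`.
#' @param points n x 2 numeric matrix of (row, col) coordinates.
#' @return Transformed n x 2 matrix.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "affine_transform"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, is.numeric(points))
  sweep(points %*% t(transform$A), 2, transform$b, "+")
}

#' Apply an affine transform to a label mask
#'
#' Maps every labelled pixel of a label matrix into a target raster with
#' nearest-neighbour rounding; pixels mapped outside the target are dropped.
#'
#' @param transform An `affine_transform`.
#' @param labels Integer label matrix (0 = background).
#' @param out_dim Output raster dimensions (defaults to `dim(labels)`).
#' @return Transformed integer label matrix.
#' @export
apply_transform_mask <- function(transform, labels, out_dim = dim(labels)) {
  stopifnot(inherits(transform, "affine_transform"), is.matrix(labels))
  out <- matrix(0L, out_dim[1], out_dim[2])
  px <- which(labels > 0L)
  if (length(px) == 0L) return(out)
  rc <- cbind((px - 1L) %% nrow(labels) + 1L,
              (px - 1L) %/% nrow(labels) + 1L)
  mapped <- round(apply_transform(transform, rc))
  ok <- mapped[, 1] >= 1 & mapped[, 1] <= out_dim[1] &
        mapped[, 2] >= 1 & mapped[, 2] <= out_dim[2]
  out[cbind(mapped[ok, 1], mapped[ok, 2])] <- labels[px[ok]]
  out
}

#' Invert an affine transform
#'
#' @param transform An `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  affine_transform(Ai, -Ai %*% transform$b)
}
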