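#' In-plane rigid transform
#'
#' A 2-D rigid transform (translation + rotation) mapping one section's pixel
#' frame onto another's. Coordinates are 0-based pixel indices with the origin
#' at the centre of the top-left pixel, `x` = column, `y` = row. Rotation is in
#' degrees, counter-clockwise in the x-y frame, about the image centre
#' `((W-1)/2, (H-1)/2)`. A point `p` maps to `R(theta) (p - c) + c + t`.
#'
#' Because every transform rotates about the same image centre, composition and
#' inversion have exact closed forms that do not involve the centre.
#'
#' @param tx,ty translation in pixels.
#' @param theta rotation in degrees, counter-clockwise.
#' @return an object of class `rigid_transform2d`.
#' @examples
#' t1 <- rigid_transform(5, -3, 2)
#' rt_compose(t1, rt_inverse(t1))  # identity
#' @export
rigid_transform <- function(tx = 0, ty = 0, theta = 0) {
  stopifnot(is.numeric(tx), is.numeric(ty), is.numeric(theta),
            length(tx) == 1L, length(ty) == 1L, length(theta) == 1L,
            is.finite(tx), is.finite(ty), is.finite(theta))
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty),
                 theta = as.numeric(theta)),
            class = "rigid_transform2d")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(0, 0, 0)

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("rigid_transform2d: tx = %.4f px, ty = %.4f px, theta = %.4f deg\n",
              x$tx, x$ty, x$theta))
  invisible(x)
}

rot_matrix <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

#' Compose two rigid transforms
#'
#' Returns the transform that maps a point as `a(b(point))`.
#'
#' @param a,b `rigid_transform2d` objects.
#' @return a `rigid_transform2d`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform2d"), inherits(b, "rigid_transform2d"))
  Ra <- rot_matrix(a$theta)
  t_new <- Ra %*% c(b$tx, b$ty) + c(a$tx, a$ty)
  rigid_transform(t_new[1L], t_new[2L], a$theta + b$theta)
}

#' Invert a rigid transform
#'
#' `rt_compose(t, rt_inverse(t))` is the identity to machine precision.
#'
#' @param t a `rigid_transform2d`.
#' @return a `rigid_transform2d`.
#' @export
rt_inverse <- function(t) {
  stopifnot(inherits(t, "rigid_transform2d"))
  Rinv <- rot_matrix(-t$theta)
  t_new <- -(Rinv %*% c(t$tx, t$ty))
  rigid_transform(t_new[1L], t_new[2L], -t$theta)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform2d`.
#' @param pts n x 2 matrix of 0-based (x, y) pixel coordinates.
#' @param center rotation centre (x, y); for an image of width W and height H
#'   this is `c((W - 1) / 2, (H - 1) / 2)`.
#' @return n x 2 matrix of transformed coordinates.
#' @export
rt_apply <- function(t, pts, center) {
  stopifnot(inherits(t, "rigid_transform2d"))
  pts <- matrix(as.numeric(pts), ncol = 2L)
  R <- rot_matrix(t$theta)
  out <- sweep(pts, 2L, center) %*% t(R)
  sweep(out, 2L, center + c(t$tx, t$ty), "+")
}

image_center <- function(img) {
  c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
}

#' Resample an image under a rigid transform
#'
#' Produces `out(p) = img(t^{-1}(p))` by bilinear interpolation, so image
#' content moves by `t`. Out-of-bounds samples are filled with `fill`.
#' Applied once per section from the absolute transform; never chained.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param t a `rigid_transform2d`.
#' @param fill fill value for samples outside the source image.
#' @return numeric matrix of the same shape.
#' @export
warp_rigid <- function(img, t, fill = 0) {
  stopifnot(is.matrix(img), inherits(t, "rigid_transform2d"))
  h <- nrow(img); w <- ncol(img)
  tinv <- rt_inverse(t)
  ctr <- image_center(img)
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  src <- rt_apply(tinv, cbind(xs, ys), ctr)
  sx <- src[, 1L]; sy <- src[, 2L]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  # bilinear corners; out-of-range corners contribute `fill`
  corner <- function(cx, cy) {
    ok <- cx >= 0 & cx <= w - 1 & cy >= 0 & cy <= h - 1
    v <- rep(fill, length(cx))
    v[ok] <- img[cbind(cy[ok] + 1, cx[ok] + 1)]
    v
  }
  v <- corner(x0, y0) * (1 - fx) * (1 - fy) +
       corner(x0 + 1, y0) * fx * (1 - fy) +
       corner(x0, y0 + 1) * (1 - fx) * fy +
       corner(x0 + 1, y0 + 1) * fx * fy
  matrix(v, nrow = h, ncol = w)
}

#' @keywords internal
#' Normalized cross-correlation of two equally-shaped numeric arrays.
#' Returns 0 when either input has zero variance.
ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

round_half_up <- function(x) floor(x + 0.5)

#' @keywords internal
#' Quantize to unsigned 8-bit: round half up then clip to [0, 255].
quantize8 <- function(x) {
  x <- round_half_up(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
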