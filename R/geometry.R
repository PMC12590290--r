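#' Normalized center-form bounding boxes
#'
#' Particle boxes are held in the DETR-family normalized center form
#' `(cx, cy, w, h)`: the box center and its width/height, all expressed as
#' fractions of the image size, so `cx, cy` lie in `[0, 1]` and `w, h` in
#' `(0, 1]`. A set of boxes is a numeric matrix with one row per box and
#' columns `cx, cy, w, h`.
#'
#' @param cx,cy Box centers as fractions of image width/height.
#' @param w,h Box width and height as fractions of image width/height.
#' @return A numeric matrix of class `norm_box` with columns `cx, cy, w, h`.
#' @examples
#' norm_box(0.5, 0.5, 0.2, 0.2)
#' @export
norm_box <- function(cx, cy, w, h) {
  b <- cbind(cx = as.numeric(cx), cy = as.numeric(cy),
             w = as.numeric(w), h = as.numeric(h))
  validate_norm_box(b)
  class(b) <- c("norm_box", class(b))
  b
}

validate_norm_box <- function(b) {
  stopifnot(is.numeric(b), ncol(b) == 4)
  if (any(!is.finite(b))) stop("box coordinates must be finite")
  if (any(b[, 1] < 0 | b[, 1] > 1 | b[, 2] < 0 | b[, 2] > 1))
    stop("box centers must lie in [0, 1]")
  if (any(b[, 3] <= 0 | b[, 4] <= 0))
    stop("degenerate box: width and height must be strictly positive")
  if (any(b[, 3] > 1 | b[, 4] > 1))
    stop("box width/height must not exceed 1")
  invisible(b)
}

#' Pixel-space corner-form boxes
#'
#' Pixel boxes use 0-based pixel coordinates with the origin at the top-left
#' corner, x increasing rightward and y downward, and are half-open on their
#' max edges (`x_min <= x < x_max`), matching image-array indexing. A set of
#' boxes is a matrix with columns `x_min, y_min, x_max, y_max`.
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates in pixels.
#' @return A numeric matrix of class `pixel_box`.
#' @export
pixel_box <- function(x_min, y_min, x_max, y_max) {
  b <- cbind(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
             x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) stop("box coordinates must be finite")
  if (any(b[, 3] <= b[, 1] | b[, 4] <= b[, 2]))
    stop("degenerate box: x_min < x_max and y_min < y_max required")
  class(b) <- c("pixel_box", class(b))
  b
}

#' Convert normalized boxes to pixel corner boxes
#'
#' No clamping to the image bounds is applied: a normalized box that
#' overhangs the frame maps to a pixel box that overhangs the frame.
#'
#' @param b A `norm_box` matrix.
#' @param width,height Image size in pixels.
#' @return A `pixel_box` matrix.
#' @export
box_to_pixels <- function(b, width, height) {
  stopifnot(width > 0, height > 0)
  validate_norm_box(b)
  pixel_box((b[, 1] - b[, 3] / 2) * width,
            (b[, 2] - b[, 4] / 2) * height,
            (b[, 1] + b[, 3] / 2) * width,
            (b[, 2] + b[, 4] / 2) * height)
}

#' Convert pixel corner boxes to normalized center form
#'
#' Inverse of [box_to_pixels()]; the round trip is the identity to floating
#' point precision for a fixed image size.
#'
#' @param p A `pixel_box` matrix.
#' @param width,height Image size in pixels.
#' @return A `norm_box` matrix.
#' @export
box_from_pixels <- function(p, width, height) {
  stopifnot(width > 0, height > 0)
  norm_box((p[, 1] + p[, 3]) / 2 / width,
           (p[, 2] + p[, 4]) / 2 / height,
           (p[, 3] - p[, 1]) / width,
           (p[, 4] - p[, 2]) / height)
}

## corner-form helpers used internally by matching and loss; inputs are plain
## n x 4 matrices (x_min, y_min, x_max, y_max), vectorized row-wise.
box_area <- function(b) pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])

#' Intersection over union of two boxes
#'
#' @param a,b `pixel_box` matrices (or plain corner-form matrices) with the
#'   same number of rows; IoU is computed row-wise.
#' @return Numeric vector in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  ix <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  iy <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- ix * iy
  union <- box_area(a) + box_area(b) - inter
  unname(inter / union)
}

#' Generalized intersection over union
#'
#' `GIoU = IoU - (area(enclosure) - area(union)) / area(enclosure)` where the
#' enclosure is the smallest axis-aligned box containing both inputs. Unlike
#' IoU it keeps discriminating (and providing gradient) between disjoint
#' boxes, tending to -1 as they separate; range `[-1, 1]`.
#'
#' @inheritParams iou
#' @return Numeric vector in `[-1, 1]`.
#' @export
giou <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  ix <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  iy <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- ix * iy
  union <- box_area(a) + box_area(b) - inter
  encl <- (pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])) *
    (pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2]))
  unname(inter / union - (encl - union) / encl)
}

## GIoU and its gradient with respect to the FIRST (predicted) box's corners.
## Subgradient convention at ties: the indicator max/min picks the first
## argument on exact equality, matching the forward computation.
giou_with_grad <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  n <- nrow(a)
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  area_a <- wa * ha
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])

  ix1 <- pmax(a[, 1], b[, 1]); iy1 <- pmax(a[, 2], b[, 2])
  ix2 <- pmin(a[, 3], b[, 3]); iy2 <- pmin(a[, 4], b[, 4])
  iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
  inter <- iw * ih
  union <- area_a + area_b - inter

  ex1 <- pmin(a[, 1], b[, 1]); ey1 <- pmin(a[, 2], b[, 2])
  ex2 <- pmax(a[, 3], b[, 3]); ey2 <- pmax(a[, 4], b[, 4])
  ew <- ex2 - ex1; eh <- ey2 - ey1
  encl <- ew * eh

  g <- inter / union - (encl - union) / encl

  overlap <- iw > 0 & ih > 0
  # dI/dcorner: active only when the corner is binding and overlap exists
  dI <- matrix(0, n, 4)
  dI[, 1] <- ifelse(overlap & a[, 1] >= b[, 1], -ih, 0)
  dI[, 2] <- ifelse(overlap & a[, 2] >= b[, 2], -iw, 0)
  dI[, 3] <- ifelse(overlap & a[, 3] <= b[, 3], ih, 0)
  dI[, 4] <- ifelse(overlap & a[, 4] <= b[, 4], iw, 0)
  dA <- cbind(-ha, -wa, ha, wa)
  dU <- dA - dI
  dE <- matrix(0, n, 4)
  dE[, 1] <- ifelse(a[, 1] <= b[, 1], -eh, 0)
  dE[, 2] <- ifelse(a[, 2] <= b[, 2], -ew, 0)
  dE[, 3] <- ifelse(a[, 3] >= b[, 3], eh, 0)
  dE[, 4] <- ifelse(a[, 4] >= b[, 4], ew, 0)

  # GIoU = I/U - 1 + U/E
  dG <- dI / union - inter * dU / union^2 + dU / encl - union * dE / encl^2
  list(giou = g, grad = dG)
}

## Pairwise m x n GIoU matrix between two corner-form box sets (used by the
## matching cost; loops the smaller side, vectorizes the larger).
giou_pairwise <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    bj <- matrix(b[j, ], nrow(a), 4, byrow = TRUE)
    out[, j] <- giou(a, bj)
  }
  out
}
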