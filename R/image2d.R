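#' 2D image with physical pixel size
#'
#' Thin matrix-backed container used throughout the pipeline. The matrix is
#' indexed `[row, col]`; each axis carries a physical coordinate in
#' nanometers. Pixel indices are mapped to the coordinates of pixel
#' *centers*: the center of pixel `[1, 1]` sits at `origin_nm`, and the
#' center of pixel `[i, j]` at `origin_nm + (c(i, j) - 1) * pixel_size_nm`.
#'
#' For a `"longitudinal"` view the row axis is the axial coordinate z
#' (z = 0 at the inner-segment/connecting-cilium interface, distal
#' positive) and the column axis is the transverse coordinate x. For a
#' `"cross_section"` view the row axis is y and the column axis is x.
#'
#' @param data numeric matrix of pixel intensities (counts).
#' @param pixel_size_nm physical size of one pixel, nm (> 0).
#' @param origin_nm length-2 numeric, nm coordinate of the center of pixel
#'   `[1, 1]` along the (row, column) axes.
#' @param view `"longitudinal"` or `"cross_section"`.
#' @return an object of class `image2d`.
#' @export
image2d <- function(data, pixel_size_nm, origin_nm = c(0, 0),
                    view = c("longitudinal", "cross_section")) {
  view <- match.arg(view)
  data <- as.matrix(data)
  stopifnot(is.numeric(data), nrow(data) >= 1, ncol(data) >= 1,
            is.numeric(pixel_size_nm), length(pixel_size_nm) == 1,
            pixel_size_nm > 0, length(origin_nm) == 2)
  structure(data,
            pixel_size_nm = as.numeric(pixel_size_nm),
            origin_nm = as.numeric(origin_nm),
            view = view,
            class = c("image2d", "matrix", "array"))
}

#' @rdname image2d
#' @param x an `image2d`.
#' @export
pixel_size <- function(x) attr(x, "pixel_size_nm")

#' @rdname image2d
#' @export
image_origin <- function(x) attr(x, "origin_nm")

#' Physical coordinates of pixel centers
#'
#' @param img an `image2d`.
#' @param axis `"row"` or `"col"`.
#' @return numeric vector of nm positions, one per pixel along `axis`.
#' @export
pixel_centers <- function(img, axis = c("row", "col")) {
  axis <- match.arg(axis)
  n <- if (axis == "row") nrow(img) else ncol(img)
  k <- if (axis == "row") 1L else 2L
  image_origin(img)[k] + (seq_len(n) - 1) * pixel_size(img)
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.3g nm/px, view = %s, origin = (%g, %g) nm\n",
              nrow(x), ncol(x), pixel_size(x), attr(x, "view"),
              image_origin(x)[1], image_origin(x)[2]))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x), max(x), sum(x)))
  invisible(x)
}

#' Bilinear interpolation of image intensity at physical positions
#'
#' Positions outside the pixel-center grid return `NA`.
#'
#' @param img an `image2d`.
#' @param row_nm,col_nm numeric vectors (recycled to common length) of nm
#'   positions along the row and column axes.
#' @return numeric vector of interpolated intensities.
#' @export
interp_bilinear <- function(img, row_nm, col_nm) {
  px <- pixel_size(img)
  o <- image_origin(img)
  # continuous pixel index (1-based, centers at integers)
  ri <- (row_nm - o[1]) / px + 1
  ci <- (col_nm - o[2]) / px + 1
  n <- max(length(ri), length(ci))
  ri <- rep_len(ri, n); ci <- rep_len(ci, n)
  out <- rep(NA_real_, n)
  ok <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
  if (!any(ok)) return(out)
  r0k <- pmax(pmin(floor(ri[ok]), nrow(img) - 1L), 1L)
  c0k <- pmax(pmin(floor(ci[ok]), ncol(img) - 1L), 1L)
  frk <- ri[ok] - r0k; fck <- ci[ok] - c0k
  r1k <- pmin(r0k + 1L, nrow(img)); c1k <- pmin(c0k + 1L, ncol(img))
  m <- unclass(img)
  v00 <- m[cbind(r0k, c0k)]
  v10 <- m[cbind(r1k, c0k)]
  v01 <- m[cbind(r0k, c1k)]
  v11 <- m[cbind(r1k, c1k)]
  out[ok] <- v00 * (1 - frk) * (1 - fck) + v10 * frk * (1 - fck) +
    v01 * (1 - frk) * fck + v11 * frk * fck
  out
}
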