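#' Imaging model
#'
#' Describes how an emitter set is turned into pixels. SIM-like imaging
#' is emulated as Gaussian-PSF imaging of the reconstructed-resolution
#' regime (default FWHM 120 nm at 40 nm/px) — the commercial
#' structured-illumination reconstruction itself is out of scope and the
#' measurements operate on reconstructed images only.
#'
#' @param modality `"widefield"`, `"SIM_like"` or `"STORM_render"`.
#' @param psf_fwhm lateral PSF full width at half maximum, nm.
#' @param pixel_size nm per pixel (default 40).
#' @param poisson_on apply Poisson shot noise.
#' @param read_sigma Gaussian read noise sd, counts.
#' @param background constant background, counts per pixel.
#' @param view `"longitudinal"` (row axis = z) or `"cross_section"`
#'   (row axis = y).
#' @return object of class `imaging_model`.
#' @export
imaging_model <- function(modality = c("SIM_like", "widefield", "STORM_render"),
                          psf_fwhm = 120, pixel_size = 40,
                          poisson_on = TRUE, read_sigma = 2, background = 10,
                          view = c("longitudinal", "cross_section")) {
  modality <- match.arg(modality)
  view <- match.arg(view)
  stopifnot(psf_fwhm > 0, pixel_size > 0, read_sigma >= 0, background >= 0)
  structure(list(modality = modality, psf_fwhm = psf_fwhm,
                 pixel_size = pixel_size, poisson_on = poisson_on,
                 read_sigma = read_sigma, background = background,
                 view = view),
            class = "imaging_model")
}

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Add integrated-Gaussian spots to a matrix. Rows/cols carry physical
# coordinates row0 + (i-1)*px. Each spot deposits `photons` distributed as
# an isotropic Gaussian integrated over pixel bins (photon-conserving as
# long as the field of view covers the spot).
.add_spots <- function(mat, row_nm, col_nm, photons, sigma, px, origin) {
  nr <- nrow(mat); nc <- ncol(mat)
  half <- max(1L, ceiling(5 * sigma / px))
  for (i in seq_along(row_nm)) {
    ri <- (row_nm[i] - origin[1]) / px + 1
    ci <- (col_nm[i] - origin[2]) / px + 1
    r0 <- max(1L, floor(ri) - half); r1 <- min(nr, ceiling(ri) + half)
    c0 <- max(1L, floor(ci) - half); c1 <- min(nc, ceiling(ci) + half)
    if (r0 > r1 || c0 > c1) next
    # pixel bin edges in index units: pixel j spans [j-0.5, j+0.5]
    wr <- diff(stats::pnorm((seq(r0 - 0.5, r1 + 0.5) - ri) * px / sigma))
    wc <- diff(stats::pnorm((seq(c0 - 0.5, c1 + 0.5) - ci) * px / sigma))
    mat[r0:r1, c0:c1] <- mat[r0:r1, c0:c1] + photons[i] * (wr %o% wc)
  }
  mat
}

.apply_noise <- function(mat, poisson_on, read_sigma, background) {
  mat <- mat + background
  if (poisson_on) mat[] <- stats::rpois(length(mat), lambda = pmax(mat, 0))
  if (read_sigma > 0) mat <- mat + stats::rnorm(length(mat), 0, read_sigma)
  mat
}

#' Render an emitter set into a 2D image
#'
#' Projects the 3D emitter set onto the imaging plane (`longitudinal`:
#' (x, z), axis along the image rows; `cross_section`: (x, y)), deposits
#' each emitter as an isotropic Gaussian of FWHM `imaging$psf_fwhm`
#' carrying its photon budget, then applies camera noise.
#'
#' @param emitters an `emitter_set`.
#' @param imaging an [imaging_model].
#' @param seed integer seed for the noise draw.
#' @param fov optional list with `row_nm` and `col_nm`, each a length-2
#'   physical range; defaults to the emitter bounding box padded by 3
#'   PSF FWHM.
#' @return an [image2d] (counts) with pixel-size metadata.
#' @export
render_image <- function(emitters, imaging, seed = 1L, fov = NULL) {
  stopifnot(inherits(imaging, "imaging_model"))
  px <- imaging$pixel_size
  if (imaging$view == "longitudinal") {
    rpos <- emitters$z; cpos <- emitters$x
  } else {
    rpos <- emitters$y; cpos <- emitters$x
  }
  if (is.null(fov)) {
    pad <- 3 * imaging$psf_fwhm
    if (nrow(emitters) == 0)
      fov <- list(row_nm = c(0, 10 * px), col_nm = c(0, 10 * px))
    else
      fov <- list(row_nm = range(rpos) + c(-pad, pad),
                  col_nm = range(cpos) + c(-pad, pad))
  }
  origin <- c(floor(fov$row_nm[1] / px) * px, floor(fov$col_nm[1] / px) * px)
  nr <- max(1L, ceiling((fov$row_nm[2] - origin[1]) / px) + 1L)
  nc <- max(1L, ceiling((fov$col_nm[2] - origin[2]) / px) + 1L)
  mat <- matrix(0, nr, nc)
  inside <- rpos >= origin[1] - px / 2 & rpos <= origin[1] + (nr - 0.5) * px &
    cpos >= origin[2] - px / 2 & cpos <= origin[2] + (nc - 0.5) * px
  if (nrow(emitters) > 0 && !any(inside))
    warning("field of view excludes all emitters; returning background-only image")
  sigma <- .fwhm_to_sigma(imaging$psf_fwhm)
  if (nrow(emitters) > 0)
    mat <- .add_spots(mat, rpos, cpos, emitters$photons, sigma, px, origin)
  set.seed(as.integer(seed))
  mat <- .apply_noise(mat, imaging$poisson_on, imaging$read_sigma,
                      imaging$background)
  image2d(mat, pixel_size_nm = px, origin_nm = origin, view = imaging$view)
}

#' Blinking model for STORM raw-frame simulation
#'
#' Two-state blinking: in every frame each fluorophore is "on"
#' independently with `on_probability`; an on event emits a
#' Gaussian-distributed photon count rendered at the raw camera pixel
#' size with the raw-frame PSF. Defaults follow a typical acquisition of
#' this kind (50,000 frames at ~56 fps; raw EMCCD pixel 160 nm).
#'
#' @param frames number of frames (default 50000; tests use far fewer).
#' @param on_probability per-frame on probability in `[0, 1)`.
#' @param photons_mean,photons_sd integrated counts per on event (camera
#'   gain 1: counts = detected photons). The default keeps the typical
#'   fitted PSF amplitude, `photons * pixel^2 / (2 pi sigma^2)` ~ 900
#'   counts, inside the published 400-65,636 count acceptance window.
#' @param raw_pixel_size raw camera pixel size, nm.
#' @param psf_fwhm raw-frame PSF FWHM, nm.
#' @param background counts per pixel per frame.
#' @param read_sigma Gaussian read noise sd, counts.
#' @param poisson_on apply Poisson shot noise.
#' @return object of class `blinking_model`.
#' @export
blinking_model <- function(frames = 50000L, on_probability = 0.005,
                           photons_mean = 5000, photons_sd = 800,
                           raw_pixel_size = 160, psf_fwhm = 350,
                           background = 5, read_sigma = 1,
                           poisson_on = TRUE) {
  stopifnot(frames >= 1, on_probability >= 0, on_probability < 1,
            photons_mean > 0, raw_pixel_size > 0, psf_fwhm > 0)
  structure(list(frames = as.integer(frames),
                 on_probability = on_probability,
                 photons_mean = photons_mean, photons_sd = photons_sd,
                 raw_pixel_size = raw_pixel_size, psf_fwhm = psf_fwhm,
                 background = background, read_sigma = read_sigma,
                 poisson_on = poisson_on),
            class = "blinking_model")
}

#' Simulate a STORM raw frame stack with ground-truth events
#'
#' @param emitters an `emitter_set` (positions projected as in
#'   [render_image()] longitudinal view: rows = z, cols = x).
#' @param blinking a [blinking_model].
#' @param seed integer seed.
#' @param fov optional field of view as in [render_image()].
#' @param view projection, as in [imaging_model()].
#' @return a `frame_stack`: list with `frames` (3D array rows x cols x
#'   frame), `pixel_size_nm`, `origin_nm`, `view`, and `events`, the
#'   ground-truth event table (columns `frame`, `row_nm`, `col_nm`,
#'   `photons`, `emitter`) with event positions equal to the emitter
#'   positions (no drift is simulated).
#' @export
simulate_storm_frames <- function(emitters, blinking, seed = 1L, fov = NULL,
                                  view = c("longitudinal", "cross_section")) {
  stopifnot(inherits(blinking, "blinking_model"))
  view <- match.arg(view)
  px <- blinking$raw_pixel_size
  if (view == "longitudinal") { rpos <- emitters$z; cpos <- emitters$x }
  else { rpos <- emitters$y; cpos <- emitters$x }
  if (is.null(fov)) {
    pad <- 3 * blinking$psf_fwhm
    if (nrow(emitters) == 0)
      fov <- list(row_nm = c(0, 10 * px), col_nm = c(0, 10 * px))
    else
      fov <- list(row_nm = range(rpos) + c(-pad, pad),
                  col_nm = range(cpos) + c(-pad, pad))
  }
  origin <- c(floor(fov$row_nm[1] / px) * px, floor(fov$col_nm[1] / px) * px)
  nr <- max(1L, ceiling((fov$row_nm[2] - origin[1]) / px) + 1L)
  nc <- max(1L, ceiling((fov$col_nm[2] - origin[2]) / px) + 1L)
  set.seed(as.integer(seed))
  sigma <- .fwhm_to_sigma(blinking$psf_fwhm)
  n_em <- nrow(emitters)
  stack <- array(0, dim = c(nr, nc, blinking$frames))
  ev_frame <- integer(0); ev_em <- integer(0); ev_ph <- numeric(0)
  for (f in seq_len(blinking$frames)) {
    mat <- matrix(0, nr, nc)
    if (n_em > 0) {
      on <- which(stats::runif(n_em) < blinking$on_probability)
      if (length(on) > 0) {
        ph <- pmax(1, stats::rnorm(length(on), blinking$photons_mean,
                                   blinking$photons_sd))
        mat <- .add_spots(mat, rpos[on], cpos[on], ph, sigma, px, origin)
        ev_frame <- c(ev_frame, rep.int(f, length(on)))
        ev_em <- c(ev_em, on)
        ev_ph <- c(ev_ph, ph)
      }
    }
    stack[, , f] <- .apply_noise(mat, blinking$poisson_on,
                                 blinking$read_sigma, blinking$background)
  }
  events <- data.frame(frame = ev_frame,
                       row_nm = rpos[ev_em], col_nm = cpos[ev_em],
                       photons = ev_ph, emitter = ev_em)
  structure(list(frames = stack, pixel_size_nm = px, origin_nm = origin,
                 view = view, events = events),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px at %g nm/px; %d true events\n",
              d[3], d[1], d[2], x$pixel_size_nm, nrow(x$events)))
  invisible(x)
}

#' Extract one frame of a stack as an image
#'
#' @param stack a `frame_stack`.
#' @param i frame index.
#' @return an [image2d].
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "frame_stack"), i >= 1, i <= dim(stack$frames)[3])
  image2d(stack$frames[, , i], pixel_size_nm = stack$pixel_size_nm,
          origin_nm = stack$origin_nm, view = stack$view)
}
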