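#' STORM event acceptance settings
#'
#' The acceptance rules applied to fitted single-molecule point-spread
#' functions, with defaults equal to the published identification
#' settings: minimum PSF height 400 counts, maximum PSF height 65,636
#' counts, PSF width between 200 and 700 nm, initial fit width 350 nm,
#' maximum axial ratio 2.5, maximum displacement 1 pixel. Widths are
#' full widths at half maximum by default (`width_convention = "fwhm"`);
#' a `"sigma"` convention is available since fitting software does not
#' always document which it reports.
#'
#' @param min_psf_height,max_psf_height fitted amplitude bounds, counts.
#' @param min_psf_width,max_psf_width fitted width bounds, nm.
#' @param initial_fit_width fit initialization width, nm.
#' @param max_axial_ratio maximum `max(wx, wy)/min(wx, wy)`.
#' @param max_displacement frame-linking radius, raw pixels.
#' @param width_convention `"fwhm"` or `"sigma"`.
#' @return object of class `storm_settings`.
#' @export
storm_settings <- function(min_psf_height = 400, max_psf_height = 65636,
                           min_psf_width = 200, max_psf_width = 700,
                           initial_fit_width = 350, max_axial_ratio = 2.5,
                           max_displacement = 1,
                           width_convention = c("fwhm", "sigma")) {
  width_convention <- match.arg(width_convention)
  stopifnot(min_psf_height < max_psf_height, min_psf_width < max_psf_width,
            max_axial_ratio >= 1, max_displacement >= 0,
            initial_fit_width > 0)
  structure(list(min_psf_height = min_psf_height,
                 max_psf_height = max_psf_height,
                 min_psf_width = min_psf_width,
                 max_psf_width = max_psf_width,
                 initial_fit_width = initial_fit_width,
                 max_axial_ratio = max_axial_ratio,
                 max_displacement = max_displacement,
                 width_convention = width_convention),
            class = "storm_settings")
}

# width reported by fit_psf (internally sigma) in the settings' convention
.width_out <- function(sigma, settings) {
  if (settings$width_convention == "fwhm") sigma * 2 * sqrt(2 * log(2))
  else sigma
}

#' Detect candidate events in one raw frame
#'
#' Local maxima above `background + detect_threshold`, where background
#' is the frame median, non-maximum suppressed within one initial fit
#' width. The detection threshold is a configuration value (the
#' published settings do not include one); the default suits the
#' simulator's photon regime.
#'
#' @param frame an [image2d] raw frame.
#' @param detect_threshold counts above background required of a local
#'   maximum.
#' @param settings a [storm_settings] (for the suppression radius).
#' @return data.frame with columns `row`, `col` (pixel indices) and
#'   `row_nm`, `col_nm` (physical positions), ordered by decreasing
#'   intensity.
#' @export
detect_candidates <- function(frame, detect_threshold = 50,
                              settings = storm_settings()) {
  stopifnot(inherits(frame, "image2d"))
  m <- unclass(frame)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(.empty_candidates())
  bg <- stats::median(m)
  thr <- bg + detect_threshold
  core <- m[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core >= m[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(.empty_candidates())
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  vals <- m[cbind(rows, cols)]
  o <- order(vals, decreasing = TRUE)
  rows <- rows[o]; cols <- cols[o]
  # non-maximum suppression within one initial fit width
  rad_px <- settings$initial_fit_width / pixel_size(frame)
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (i == 1) { keep[1] <- TRUE; next }
    ks <- which(keep[seq_len(i - 1)])
    d2 <- (rows[ks] - rows[i])^2 + (cols[ks] - cols[i])^2
    keep[i] <- all(d2 > rad_px^2)
  }
  rows <- rows[keep]; cols <- cols[keep]
  o <- image_origin(frame); px <- pixel_size(frame)
  data.frame(row = rows, col = cols,
             row_nm = o[1] + (rows - 1) * px,
             col_nm = o[2] + (cols - 1) * px)
}

.empty_candidates <- function() {
  data.frame(row = integer(0), col = integer(0),
             row_nm = numeric(0), col_nm = numeric(0))
}

#' Fit an elliptical 2D Gaussian to one candidate
#'
#' Least-squares fit of
#' `bg + A * exp(-(u - u0)^2 / (2 sx^2) - (v - v0)^2 / (2 sy^2))`
#' over a square region of interest around the candidate, initialized at
#' `initial_fit_width`. Non-convergence yields a rejected fit with
#' reason `"fit_failure"`, never an exception.
#'
#' @param frame an [image2d] raw frame.
#' @param candidate one row of [detect_candidates()] output (or a list
#'   with `row` and `col` pixel indices).
#' @param settings a [storm_settings].
#' @param frame_index frame number recorded in the fit.
#' @return one-row data.frame (a `psf_fit`): `frame`, `row_nm`,
#'   `col_nm`, `height`, `wx_nm`, `wy_nm` (widths in the settings'
#'   convention), `background`, `residual`, `status`
#'   (`"accepted"`/`"rejected"`; fresh fits are `"unfiltered"`), `reason`.
#' @export
fit_psf <- function(frame, candidate, settings = storm_settings(),
                    frame_index = 1L) {
  stopifnot(inherits(frame, "image2d"))
  px <- pixel_size(frame)
  r <- candidate$row[1]; c <- candidate$col[1]
  margin <- 3L
  if (r <= margin || c <= margin || r > nrow(frame) - margin ||
      c > ncol(frame) - margin)
    stop("candidate too close to the frame edge (needs a ", margin,
         "-pixel margin)")
  half <- max(margin, ceiling(2 * settings$initial_fit_width / px))
  r0 <- max(1L, r - half); r1 <- min(nrow(frame), r + half)
  c0 <- max(1L, c - half); c1 <- min(ncol(frame), c + half)
  roi <- unclass(frame)[r0:r1, c0:c1]
  u <- (r0:r1 - r) * px   # nm offsets from the candidate pixel
  v <- (c0:c1 - c) * px
  U <- matrix(u, length(u), length(v))
  V <- matrix(v, length(u), length(v), byrow = TRUE)
  bg0 <- stats::median(roi)
  a0 <- max(roi) - bg0
  s0 <- if (settings$width_convention == "fwhm")
    .fwhm_to_sigma(settings$initial_fit_width) else settings$initial_fit_width
  model <- function(p)
    p[5] + p[1] * exp(-(U - p[2])^2 / (2 * p[3]^2) -
                        (V - p[4])^2 / (2 * p[6]^2))
  obj <- function(p) sum((roi - model(p))^2)
  # Nelder-Mead for robustness, a quasi-Newton polish for precision, then
  # one variance-weighted refit (weights from the shot-noise model) that
  # takes unweighted least squares to near the Poisson maximum-likelihood
  # precision at high photon counts
  fit <- tryCatch({
    nm <- stats::optim(c(a0, 0, s0, 0, bg0, s0), obj, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10))
    ls <- stats::optim(nm$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    w <- 1 / pmax(model(ls$par), 1)
    objw <- function(p) sum(w * (roi - model(p))^2)
    wf <- tryCatch(stats::optim(ls$par, objw, method = "BFGS",
                                control = list(maxit = 500, reltol = 1e-12)),
                   error = function(e) NULL)
    # convergence is judged on the robust stage; the weighted polish is
    # kept when it produced finite parameters
    if (!is.null(wf) && all(is.finite(wf$par))) ls$par <- wf$par
    ls
  }, error = function(e) NULL)
  o <- image_origin(frame)
  fail <- function() data.frame(
    frame = frame_index, row_nm = o[1] + (r - 1) * px,
    col_nm = o[2] + (c - 1) * px, height = NA_real_, wx_nm = NA_real_,
    wy_nm = NA_real_, background = NA_real_, residual = NA_real_,
    photons = NA_real_, status = "rejected", reason = "fit_failure")
  if (is.null(fit) || fit$convergence != 0 || !all(is.finite(fit$par)))
    return(fail())
  p <- fit$par
  sx <- abs(p[3]); sy <- abs(p[6])
  if (p[1] <= 0 || sx <= 0 || sy <= 0 ||
      abs(p[2]) > half * px || abs(p[4]) > half * px)
    return(fail())
  data.frame(
    frame = frame_index,
    row_nm = o[1] + (r - 1) * px + p[2],
    col_nm = o[2] + (c - 1) * px + p[4],
    height = p[1],
    wx_nm = .width_out(sy, settings),  # wx = width along the column (x) axis
    wy_nm = .width_out(sx, settings),
    background = p[5],
    residual = fit$value,
    photons = 2 * pi * p[1] * sx * sy / px^2,
    status = "unfiltered", reason = "")
}

#' Apply the event acceptance rules to fitted PSFs
#'
#' A converged fit is accepted iff its height lies within
#' `[min_psf_height, max_psf_height]`, both widths within
#' `[min_psf_width, max_psf_width]`, and the axial ratio
#' `max(wx, wy)/min(wx, wy)` does not exceed `max_axial_ratio`. The
#' first failed rule (in that order) is recorded as the rejection
#' reason; fit failures keep their `"fit_failure"` code so acceptance
#' statistics stay auditable.
#'
#' @param fits data.frame of fits from [fit_psf()] (any number of rows).
#' @param settings a [storm_settings].
#' @return the same data.frame with `status` and `reason` filled in.
#' @export
apply_filters <- function(fits, settings = storm_settings()) {
  if (nrow(fits) == 0) return(fits)
  for (i in seq_len(nrow(fits))) {
    if (fits$status[i] == "rejected" && fits$reason[i] == "fit_failure") next
    h <- fits$height[i]; wx <- fits$wx_nm[i]; wy <- fits$wy_nm[i]
    reason <-
      if (h < settings$min_psf_height) "height_below_min"
      else if (h > settings$max_psf_height) "height_above_max"
      else if (min(wx, wy) < settings$min_psf_width) "width_below_min"
      else if (max(wx, wy) > settings$max_psf_width) "width_above_max"
      else if (max(wx, wy) / min(wx, wy) > settings$max_axial_ratio) "axial_ratio"
      else ""
    fits$status[i] <- if (reason == "") "accepted" else "rejected"
    fits$reason[i] <- reason
  }
  fits
}

#' Link accepted events across consecutive frames
#'
#' Accepted fits in consecutive frames whose centers differ by at most
#' `max_displacement` raw pixels are merged into one chain (one
#' fluorophore on for several frames); the chain position is the
#' photon-weighted mean of its member positions.
#'
#' @param fits filtered fit table from [apply_filters()].
#' @param settings a [storm_settings].
#' @param pixel_size_nm raw pixel size used to express the displacement
#'   bound, nm.
#' @return list with `fits` (input plus a `chain_id` column, `NA` for
#'   rejected fits) and `chains` (one row per chain: `chain_id`,
#'   `row_nm`, `col_nm`, `photons`, `n_frames`, `first_frame`).
#' @export
link_events <- function(fits, settings = storm_settings(),
                        pixel_size_nm = 160) {
  fits$chain_id <- rep(NA_integer_, nrow(fits))
  acc <- which(fits$status == "accepted")
  maxd <- settings$max_displacement * pixel_size_nm
  next_id <- 0L
  if (length(acc) > 0) {
    acc <- acc[order(fits$frame[acc])]
    open <- data.frame(idx = integer(0), frame = integer(0),
                       row_nm = numeric(0), col_nm = numeric(0),
                       id = integer(0))
    for (i in acc) {
      f <- fits$frame[i]
      cand <- open[open$frame == f - 1, , drop = FALSE]
      hit <- NA_integer_
      if (nrow(cand) > 0) {
        d <- sqrt((cand$row_nm - fits$row_nm[i])^2 +
                    (cand$col_nm - fits$col_nm[i])^2)
        j <- which.min(d)
        if (d[j] <= maxd) hit <- cand$id[j]
      }
      if (is.na(hit)) {
        next_id <- next_id + 1L
        hit <- next_id
      }
      fits$chain_id[i] <- hit
      open <- open[open$id != hit, , drop = FALSE]
      open <- rbind(open, data.frame(idx = i, frame = f,
                                     row_nm = fits$row_nm[i],
                                     col_nm = fits$col_nm[i], id = hit))
      open <- open[open$frame >= f - 1, , drop = FALSE]
    }
  }
  mem <- fits[!is.na(fits$chain_id), , drop = FALSE]
  if (nrow(mem) == 0) {
    chains <- data.frame(chain_id = integer(0), row_nm = numeric(0),
                         col_nm = numeric(0), photons = numeric(0),
                         n_frames = integer(0), first_frame = integer(0))
  } else {
    w <- ifelse(is.finite(mem$photons) & mem$photons > 0, mem$photons, 1)
    chains <- do.call(rbind, lapply(split(seq_len(nrow(mem)), mem$chain_id),
      function(ii) {
        wi <- w[ii]
        data.frame(chain_id = mem$chain_id[ii[1]],
                   row_nm = sum(mem$row_nm[ii] * wi) / sum(wi),
                   col_nm = sum(mem$col_nm[ii] * wi) / sum(wi),
                   photons = sum(mem$photons[ii]),
                   n_frames = length(ii),
                   first_frame = min(mem$frame[ii]))
      }))
    chains <- chains[order(chains$chain_id), , drop = FALSE]
    rownames(chains) <- NULL
  }
  list(fits = fits, chains = chains)
}

#' Render a localization table as a super-resolution image
#'
#' Each chain deposits a unit-mass isotropic Gaussian of sd
#' `render_sigma` at its position; the rendering is additive in the
#' table.
#'
#' @param chains chain table from [link_events()] (needs `row_nm`,
#'   `col_nm`).
#' @param render_sigma rendering Gaussian sd, nm.
#' @param pixel_size_nm output pixel size, nm.
#' @param fov optional field of view as in [render_image()].
#' @return an [image2d].
#' @export
render_storm <- function(chains, render_sigma = 15, pixel_size_nm = 10,
                         fov = NULL) {
  px <- pixel_size_nm
  if (is.null(fov)) {
    pad <- 5 * render_sigma
    if (nrow(chains) == 0) fov <- list(row_nm = c(0, 10 * px),
                                       col_nm = c(0, 10 * px))
    else fov <- list(row_nm = range(chains$row_nm) + c(-pad, pad),
                     col_nm = range(chains$col_nm) + c(-pad, pad))
  }
  origin <- c(floor(fov$row_nm[1] / px) * px, floor(fov$col_nm[1] / px) * px)
  nr <- max(1L, ceiling((fov$row_nm[2] - origin[1]) / px) + 1L)
  nc <- max(1L, ceiling((fov$col_nm[2] - origin[2]) / px) + 1L)
  mat <- matrix(0, nr, nc)
  if (nrow(chains) > 0)
    mat <- .add_spots(mat, chains$row_nm, chains$col_nm,
                      rep(1, nrow(chains)), render_sigma, px, origin)
  image2d(mat, pixel_size_nm = px, origin_nm = origin, view = "longitudinal")
}

#' Localize a whole frame stack
#'
#' Detection, fitting, filtering and linking over every frame of a
#' stack; the all-in-one driver behind the command-line `localize` step.
#'
#' @param stack a `frame_stack` from [simulate_storm_frames()] (or read
#'   from disk).
#' @param settings a [storm_settings].
#' @param detect_threshold see [detect_candidates()].
#' @return list with `fits`, `chains` (as in [link_events()]) and
#'   `counts`, a named vector of accepted/rejected-by-reason tallies.
#' @export
localize_stack <- function(stack, settings = storm_settings(),
                           detect_threshold = 50) {
  stopifnot(inherits(stack, "frame_stack"))
  nfr <- dim(stack$frames)[3]
  fits <- list()
  for (f in seq_len(nfr)) {
    fr <- get_frame(stack, f)
    cand <- detect_candidates(fr, detect_threshold, settings)
    if (nrow(cand) == 0) next
    margin <- 3L
    ok <- cand$row > margin & cand$col > margin &
      cand$row <= nrow(fr) - margin & cand$col <= ncol(fr) - margin
    cand <- cand[ok, , drop = FALSE]
    for (i in seq_len(nrow(cand)))
      fits[[length(fits) + 1L]] <- fit_psf(fr, cand[i, ], settings, f)
  }
  fits <- if (length(fits) == 0) .empty_fit_table() else do.call(rbind, fits)
  fits <- apply_filters(fits, settings)
  linked <- link_events(fits, settings, stack$pixel_size_nm)
  tab <- table(ifelse(linked$fits$status == "accepted", "accepted",
                      paste0("rejected_", linked$fits$reason)))
  list(fits = linked$fits, chains = linked$chains,
       counts = stats::setNames(as.integer(tab), names(tab)))
}

.empty_fit_table <- function() {
  data.frame(frame = integer(0), row_nm = numeric(0), col_nm = numeric(0),
             height = numeric(0), wx_nm = numeric(0), wy_nm = numeric(0),
             background = numeric(0), residual = numeric(0),
             photons = numeric(0), status = character(0),
             reason = character(0))
}
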