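#' Sample ground-truth fluorophore positions for one channel
#'
#' Draws an emitter set from a channel's labeling law inside a cilium
#' geometry. The emitter count is Poisson with mean
#' `density x axial extent (um) x labeling efficiency`; axial positions
#' are uniform over `z_range`; radial positions follow the channel's
#' `radial_kind`; azimuthal angles are uniform or von Mises
#' (concentration `azimuthal_asymmetry`, mean angle 0, i.e. toward +x).
#'
#' Coordinates are in the cilium frame: z axial (0 at the IS/CC
#' interface, distal positive), x and y transverse.
#'
#' @param geometry a [cilium_geometry].
#' @param channel a [channel_model].
#' @param seed integer seed; identical seeds give identical emitter sets.
#' @param n optional fixed emitter count, overriding the Poisson draw.
#' @return an `emitter_set`: data.frame with columns `x`, `y`, `z` (nm),
#'   `channel`, `photons`.
#' @export
sample_emitters <- function(geometry, channel, seed = 1L, n = NULL) {
  stopifnot(inherits(geometry, "cilium_geometry"),
            inherits(channel, "channel_model"))
  set.seed(as.integer(seed))
  extent_um <- diff(channel$z_range) / 1000
  if (is.null(n)) {
    lambda <- channel$emitter_density * extent_um * channel$labeling_efficiency
    n <- if (lambda <= 0) 0L else stats::rpois(1, lambda)
  }
  if (n == 0)
    return(empty_emitter_set(channel$marker_name))
  z <- stats::runif(n, channel$z_range[1], channel$z_range[2])
  theta <- .sample_azimuth(n, channel$azimuthal_asymmetry)
  p <- channel$radial_params
  rk <- channel$radial_kind
  if (rk == "lumen_fill" || rk == "basal_patch") {
    outer <- if (!is.null(p$outer)) p$outer else geometry$lumen_radius
    r <- outer * sqrt(stats::runif(n))
    x <- r * cos(theta); y <- r * sin(theta)
  } else if (rk == "annulus") {
    r <- sqrt(stats::runif(n, p$inner^2, p$outer^2))
    x <- r * cos(theta); y <- r * sin(theta)
  } else if (rk == "membrane_shell") {
    outer <- if (!is.null(p$outer)) p$outer else geometry$membrane_radius
    thick <- if (!is.null(p$thickness)) p$thickness else 0
    r <- stats::runif(n, outer - thick / 2, outer + thick / 2)
    x <- r * cos(theta); y <- r * sin(theta)
  } else { # doublet_ring
    sig <- if (!is.null(p$cluster_sigma)) p$cluster_sigma else 10
    k <- sample.int(geometry$doublet_count, n, replace = TRUE)
    # doublet azimuths; the von Mises draw biases which doublet is hit
    phi0 <- 2 * pi * (k - 1) / geometry$doublet_count
    if (channel$azimuthal_asymmetry > 0) {
      # keep the doublet whose azimuth is nearest the asymmetric draw
      k <- vapply(theta, function(t) {
        d <- abs(((phi <- 2 * pi * (seq_len(geometry$doublet_count) - 1) /
                     geometry$doublet_count) - t + pi) %% (2 * pi) - pi)
        which.min(d)
      }, integer(1))
      phi0 <- 2 * pi * (k - 1) / geometry$doublet_count
    }
    cx <- geometry$axoneme_ring_radius * cos(phi0)
    cy <- geometry$axoneme_ring_radius * sin(phi0)
    x <- cx + stats::rnorm(n, 0, sig)
    y <- cy + stats::rnorm(n, 0, sig)
  }
  em <- data.frame(x = geometry$axis_origin[1] + x,
                   y = geometry$axis_origin[2] + y,
                   z = z,
                   channel = channel$marker_name,
                   photons = rep(channel$photon_budget, n))
  class(em) <- c("emitter_set", "data.frame")
  em
}

#' @rdname sample_emitters
#' @param marker_name channel label for the empty set.
#' @export
empty_emitter_set <- function(marker_name = "none") {
  em <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                   channel = character(0), photons = numeric(0))
  class(em) <- c("emitter_set", "data.frame")
  em
}

# Von Mises sampling (mean 0, concentration kappa) by the Best-Fisher
# rejection algorithm; kappa = 0 falls back to the uniform circle.
.sample_azimuth <- function(n, kappa) {
  if (kappa <= 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

#' Bend a straight cilium onto a circular arc
#'
#' Maps the straight axis (along z) onto a circle of radius
#' `1/curvature` in the x-z plane, preserving arc length along the axis
#' and radial offsets perpendicular to it. Used to build bent test
#' fixtures whose straightened profiles should match the straight
#' render. `curvature = 0` is the identity.
#'
#' @param emitters an `emitter_set` from [sample_emitters()].
#' @param curvature signed curvature in 1/nm; the total bend angle
#'   `|curvature| * cc_length` must be below pi (no self-overlap).
#' @param cc_length axial extent used for the self-overlap check, nm.
#' @return emitter set with mapped `x`, `z` (y untouched).
#' @export
bend_axis <- function(emitters, curvature, cc_length = max(emitters$z, 0)) {
  if (curvature == 0) return(emitters)
  if (abs(curvature) * cc_length >= pi)
    stop("self-overlapping bend: |curvature| * cc_length must be < pi")
  R <- 1 / curvature
  phi <- emitters$z / R           # signed bend angle at each axial position
  x <- emitters$x
  # circle center at (R, 0) in the x-z plane; offsets ride the rotating normal
  emitters$x <- R * (1 - cos(phi)) + x * cos(phi)
  emitters$z <- (R - x) * sin(phi)
  emitters
}

#' Arc centerline of a bent cilium
#'
#' The image of the straight axis under [bend_axis()], sampled at
#' `step_nm` arc-length steps — the known centerline handed to
#' [straighten()] in round-trip tests.
#'
#' @param cc_length axial extent, nm.
#' @param curvature same value passed to [bend_axis()].
#' @param step_nm arc-length sampling step, nm.
#' @param z_min proximal end of the centerline, nm.
#' @return data.frame with nm columns `x`, `z` (polyline vertices).
#' @export
bent_centerline <- function(cc_length, curvature, step_nm = 20,
                            z_min = 0) {
  s <- seq(z_min, cc_length, by = step_nm)
  if (curvature == 0) return(data.frame(x = 0 * s, z = s))
  R <- 1 / curvature
  phi <- s / R
  data.frame(x = R * (1 - cos(phi)), z = R * sin(phi))
}
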