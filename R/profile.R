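#' Intensity profile
#'
#' An ordered vector of intensity samples with physical spacing: a row
#' (longitudinal) or column (transverse) average of a straightened
#' cilium image, the 1D signal on which all edges are called.
#'
#' @param values numeric intensities (>= 3 samples).
#' @param spacing_nm sample spacing, nm (> 0).
#' @param origin_nm physical position of the first sample, nm.
#' @param axis `"longitudinal"` or `"transverse"`.
#' @return object of class `intensity_profile`.
#' @export
intensity_profile <- function(values, spacing_nm, origin_nm = 0,
                              axis = c("longitudinal", "transverse")) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(values), length(values) >= 3, spacing_nm > 0)
  structure(list(values = as.numeric(values), spacing_nm = spacing_nm,
                 origin_nm = origin_nm, axis = axis),
            class = "intensity_profile")
}

#' @rdname intensity_profile
#' @param p an `intensity_profile`.
#' @export
profile_positions <- function(p) {
  p$origin_nm + (seq_along(p$values) - 1) * p$spacing_nm
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples at %g nm (%s), origin %g nm, max %.4g\n",
              length(x$values), x$spacing_nm, x$axis, x$origin_nm,
              max(x$values)))
  invisible(x)
}

#' Straighten an image along a centerline
#'
#' Resamples the image at equal arc-length steps along a polyline
#' centerline, and perpendicular to it out to `+/- half_width`, with
#' bilinear interpolation — the digital equivalent of the ImageJ
#' Straighten step applied to curved or bent cilia before profiling.
#' Output rows run along the centerline (row axis = arc length from the
#' first vertex), columns across it; output spacing equals the input
#' pixel size.
#'
#' @param image an [image2d].
#' @param centerline data.frame of polyline vertices in nm with columns
#'   `x` (column axis) and `z` or `y` (row axis), at least 2 vertices.
#' @param half_width transverse half extent, nm (> 0).
#' @return an [image2d], `view = "longitudinal"`, with column origin
#'   `-half_width` (centerline at transverse position 0).
#' @export
straighten <- function(image, centerline, half_width) {
  stopifnot(inherits(image, "image2d"), half_width > 0)
  rn <- if (!is.null(centerline$z)) centerline$z else centerline$y
  cn <- centerline$x
  stopifnot(!is.null(rn), !is.null(cn), length(rn) >= 2)
  px <- pixel_size(image)
  rlim <- range(pixel_centers(image, "row"))
  clim <- range(pixel_centers(image, "col"))
  if (any(rn < rlim[1] | rn > rlim[2] | cn < clim[1] | cn > clim[2]))
    stop("centerline exits the image")
  # resample the polyline at equal arc-length steps of one pixel
  seg <- sqrt(diff(rn)^2 + diff(cn)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate centerline (zero length)")
  s <- seq(0, total, by = px)
  rr <- stats::approx(cum, rn, xout = s, ties = "ordered")$y
  cc <- stats::approx(cum, cn, xout = s, ties = "ordered")$y
  n <- length(s)
  # unit tangents by central differences, one-sided at the ends
  tr <- c(rr[2] - rr[1], (rr[-(1:2)] - rr[seq_len(n - 2)]) / 2,
          rr[n] - rr[n - 1])
  tc <- c(cc[2] - cc[1], (cc[-(1:2)] - cc[seq_len(n - 2)]) / 2,
          cc[n] - cc[n - 1])
  norm <- sqrt(tr^2 + tc^2)
  tr <- tr / norm; tc <- tc / norm
  # normal = tangent rotated by 90 degrees
  nr_ <- -tc; nc_ <- tr
  offs <- seq(-half_width, half_width, by = px)
  out <- matrix(0, n, length(offs))
  for (j in seq_along(offs)) {
    vals <- interp_bilinear(image, rr + offs[j] * nr_, cc + offs[j] * nc_)
    vals[is.na(vals)] <- 0
    out[, j] <- vals
  }
  image2d(out, pixel_size_nm = px, origin_nm = c(0, -half_width),
          view = "longitudinal")
}

#' Row and column average profiles
#'
#' `row_average_profile` plots the average intensity across the width
#' of the region for each row of pixels along its length;
#' `column_average_profile` is the transpose (per-column mean), the
#' transverse profile used for radius measurements.
#'
#' @param image an [image2d].
#' @return an [intensity_profile].
#' @export
row_average_profile <- function(image) {
  stopifnot(inherits(image, "image2d"))
  intensity_profile(rowMeans(image), pixel_size(image),
                    origin_nm = image_origin(image)[1],
                    axis = "longitudinal")
}

#' @rdname row_average_profile
#' @export
column_average_profile <- function(image) {
  stopifnot(inherits(image, "image2d"))
  intensity_profile(colMeans(image), pixel_size(image),
                    origin_nm = image_origin(image)[2],
                    axis = "transverse")
}

# fraction of the (background-subtracted) maximum for a threshold rule
.rule_fraction <- function(rule) {
  if (is.numeric(rule)) {
    stopifnot(rule > 0, rule < 1)
    return(rule)
  }
  switch(match.arg(rule, c("frac_033", "FWHM", "inv_e")),
         frac_033 = 0.33, FWHM = 0.5, inv_e = exp(-1))
}

#' Call signal edges on a profile at a fractional threshold
#'
#' The threshold is `background + f * (max - background)` with
#' `f = 0.33` (`"frac_033"`, the criterion used for connecting cilia),
#' `0.5` (`"FWHM"`, used for hRPE-1 primary cilia) or `1/e`
#' (`"inv_e"`, used for STORM cluster edges); a bare numeric fraction
#' is also accepted. The proximal edge is the outermost
#' threshold crossing on the left of the global maximum (the first
#' sample position from the profile start at which the signal reaches
#' the threshold), the distal edge the outermost crossing on the right;
#' both are located sub-sample by linear interpolation between the
#' bracketing samples. A side that never falls below the threshold is
#' clamped to the profile end and flagged truncated.
#'
#' @param profile an [intensity_profile].
#' @param rule `"frac_033"`, `"FWHM"`, `"inv_e"`, or a fraction in (0, 1).
#' @param background baseline counts subtracted before applying the
#'   fraction (default 0, the literal published rule).
#' @return list with `proximal_nm`, `distal_nm`, `threshold`,
#'   `max_position_nm` (ties averaged), `truncated` (logical, length 2).
#' @export
find_edges <- function(profile, rule = "frac_033", background = 0) {
  stopifnot(inherits(profile, "intensity_profile"))
  v <- profile$values
  mx <- max(v)
  if (mx <= background)
    stop("no signal above background: profile maximum (", signif(mx, 4),
         ") does not exceed background (", background, ")")
  f <- .rule_fraction(rule)
  thr <- background + f * (mx - background)
  pos <- profile_positions(profile)
  imax <- which(v == mx)
  max_pos <- mean(pos[imax])
  iL <- imax[1]; iR <- imax[length(imax)]
  # left/proximal: first sample from the start at or above threshold
  above <- v >= thr
  li <- which(above[seq_len(iL)])[1]
  truncated_l <- li == 1L
  prox <- if (truncated_l) pos[1] else {
    # interpolate between sample li-1 (below) and li (at/above)
    pos[li - 1] + (thr - v[li - 1]) / (v[li] - v[li - 1]) * profile$spacing_nm
  }
  nv <- length(v)
  ri <- iR - 1L + rev(which(above[iR:nv]))[1]
  truncated_r <- ri == nv
  dist <- if (truncated_r) pos[nv] else {
    pos[ri] + (thr - v[ri]) / (v[ri + 1] - v[ri]) * profile$spacing_nm
  }
  list(proximal_nm = prox, distal_nm = dist, threshold = thr,
       max_position_nm = max_pos, truncated = c(truncated_l, truncated_r))
}

# one-row measurement record shared by all measuring operations
.record <- function(kind, value, rule, reference_channel = NA_character_,
                    target_channel = NA_character_, cilium_id = NA_character_,
                    genotype = NA_character_, side_a = NA_real_,
                    side_b = NA_real_, flags = "") {
  rule_lab <- if (is.numeric(rule)) sprintf("frac_%g", rule) else rule
  data.frame(cilium_id = cilium_id, genotype = genotype,
             target = target_channel, reference = reference_channel,
             kind = kind, rule = rule_lab, value_nm = value,
             side_a_nm = side_a, side_b_nm = side_b, flags = flags,
             stringsAsFactors = FALSE)
}

#' Measure labeled length from the IS/CC interface
#'
#' The origin is the distal edge of the origin channel (CEP164, marking
#' the transition fibers at the inner-segment/connecting-cilium
#' interface); the length is the distance from that origin (or the
#' target's own proximal edge, whichever is more distal) to the target's
#' distal edge. Connecting-cilium measurements are restricted to a
#' 1.1 um longitudinal window just above the basal body; a distal edge
#' beyond the window is clamped and flagged `"overrun"`. Set
#' `window_nm = Inf` for primary-cilium (hRPE-1) mode.
#'
#' @param target longitudinal [intensity_profile] of the measured channel.
#' @param origin_profile longitudinal profile of the origin channel
#'   (same spacing/alignment), or `NULL` to use the target's own
#'   proximal edge as origin.
#' @param rule,background see [find_edges()].
#' @param window_nm longitudinal analysis window, nm (default 1100).
#' @param origin_mode `"distal_edge"` (default) or `"max"`: whether the
#'   origin channel's distal threshold edge or its intensity maximum
#'   marks the interface.
#' @param ... record metadata (`target_channel`, `reference_channel`,
#'   `cilium_id`, `genotype`) passed to the output row.
#' @return one-row measurement record data.frame (`kind = "length"`).
#' @export
measure_length <- function(target, origin_profile = NULL, rule = "frac_033",
                           background = 0, window_nm = 1100,
                           origin_mode = c("distal_edge", "max"), ...) {
  origin_mode <- match.arg(origin_mode)
  te <- find_edges(target, rule, background)
  if (is.null(origin_profile)) {
    origin <- te$proximal_nm
  } else {
    stopifnot(inherits(origin_profile, "intensity_profile"),
              isTRUE(all.equal(origin_profile$spacing_nm, target$spacing_nm)))
    oe <- find_edges(origin_profile, rule, background)
    origin <- if (origin_mode == "max") oe$max_position_nm else oe$distal_nm
  }
  prox <- max(te$proximal_nm, origin)
  dist <- te$distal_nm
  flags <- character(0)
  if (any(te$truncated)) flags <- c(flags, "truncated")
  if (dist > origin + window_nm) {
    dist <- origin + window_nm
    flags <- c(flags, "overrun")
  }
  .record("length", max(dist - prox, 0), rule,
          side_a = prox, side_b = dist,
          flags = paste(flags, collapse = ";"), ...)
}

#' Measure the maximum labeling radius from a reference center
#'
#' The cilium center is the position of the reference channel's
#' transverse maximum (ties are averaged); the radius on each lateral
#' side is the distance from that center to the target channel's
#' fractional-threshold boundary, and the record's value is the larger
#' side (the maximum radius). Both sides are retained.
#'
#' @param target_transverse,reference_transverse transverse
#'   [intensity_profile]s from the same straightened cilium.
#' @param rule,background see [find_edges()].
#' @param ... record metadata, as in [measure_length()].
#' @return one-row measurement record (`kind = "radius"`, `side_a_nm` /
#'   `side_b_nm` = left/right radii).
#' @export
measure_radius <- function(target_transverse, reference_transverse,
                           rule = "frac_033", background = 0, ...) {
  re <- find_edges(reference_transverse, rule, background)
  center <- re$max_position_nm
  te <- find_edges(target_transverse, rule, background)
  side_a <- abs(te$proximal_nm - center)
  side_b <- abs(te$distal_nm - center)
  flags <- if (any(te$truncated)) "truncated" else ""
  .record("radius", max(side_a, side_b), rule, side_a = side_a,
          side_b = side_b, flags = flags, ...)
}

#' Signed edge offset between two channels
#'
#' Compares homologous fractional-threshold edges of two aligned
#' profiles. For `"distal_vs_distal"` the offset is positive when
#' channel A's distal edge lies further distal than channel B's; for
#' `"proximal_vs_proximal"` it is positive when channel A extends
#' further proximal. Negative values therefore read as in the source
#' convention (e.g. a distal edge "on average more proximal" than the
#' reference gives a negative distal offset).
#'
#' @param channel_a,channel_b aligned longitudinal [intensity_profile]s.
#' @param which `"distal_vs_distal"` or `"proximal_vs_proximal"`.
#' @param rule,background see [find_edges()].
#' @param ... record metadata.
#' @return one-row measurement record (`kind = "edge_offset"`, signed nm).
#' @export
edge_offset <- function(channel_a, channel_b,
                        which = c("distal_vs_distal", "proximal_vs_proximal"),
                        rule = "frac_033", background = 0, ...) {
  which <- match.arg(which)
  ea <- find_edges(channel_a, rule, background)
  eb <- find_edges(channel_b, rule, background)
  value <- if (which == "distal_vs_distal") ea$distal_nm - eb$distal_nm
  else eb$proximal_nm - ea$proximal_nm
  flags <- if (any(ea$truncated) || any(eb$truncated)) "truncated" else ""
  .record("edge_offset", value, rule, side_a = ea$distal_nm,
          side_b = eb$distal_nm, flags = flags, ...)
}

#' Transverse asymmetry index
#'
#' Signed distance (nm) from the reference channel's maximum position to
#' the target channel's intensity centroid: 0 for a signal symmetric
#' about the central axis, nonzero when the label is shifted to one side
#' of the cilium, as observed for CEP290.
#'
#' @param target_transverse,reference_transverse transverse profiles, as
#'   in [measure_radius()].
#' @param background baseline subtracted before the centroid (default 0).
#' @param ... record metadata.
#' @return one-row measurement record (`kind = "asymmetry"`, signed nm).
#' @export
asymmetry_index <- function(target_transverse, reference_transverse,
                            background = 0, ...) {
  re <- find_edges(reference_transverse, "FWHM", background)
  v <- pmax(target_transverse$values - background, 0)
  tot <- sum(v)
  if (tot <= 0) stop("zero total intensity in target profile")
  centroid <- sum(profile_positions(target_transverse) * v) / tot
  .record("asymmetry", centroid - re$max_position_nm, "centroid", ...)
}

#' Shortest cross-section diameter, TEM rule
#'
#' Fits the principal axes of an annotated cross-section region
#' (second-moment eigenvectors), measures the two perpendicular
#' diameters along them as projection extents, and returns the shorter —
#' cross-sections are not perfectly circular, and the shortest of two
#' intersecting measurements is the one used.
#'
#' @param annotation either a binary mask [image2d] (nonzero = region)
#'   or a data.frame of boundary points with nm columns `x`, `y`
#'   (>= 4 points).
#' @param ... record metadata.
#' @return one-row measurement record (`kind = "diameter"`,
#'   `side_a_nm`/`side_b_nm` = the two perpendicular diameters).
#' @export
tem_shortest_diameter <- function(annotation, ...) {
  if (inherits(annotation, "image2d")) {
    idx <- which(unclass(annotation) != 0, arr.ind = TRUE)
    if (nrow(idx) < 4) stop("mask annotation too small")
    px <- pixel_size(annotation)
    o <- image_origin(annotation)
    pts <- cbind(x = o[2] + (idx[, 2] - 1) * px,
                 y = o[1] + (idx[, 1] - 1) * px)
    footprint <- px  # pixel footprint: centers underestimate extent by 1 px
  } else {
    stopifnot(!is.null(annotation$x), !is.null(annotation$y))
    pts <- cbind(x = annotation$x, y = annotation$y)
    if (nrow(pts) < 4) stop("need at least 4 boundary points")
    footprint <- 0
  }
  ctr <- colMeans(pts)
  cv <- stats::cov(sweep(pts, 2, ctr))
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] <= 1e-9 * max(ev$values[1], 1))
    stop("degenerate (collinear) annotation")
  proj1 <- pts %*% ev$vectors[, 1]
  proj2 <- pts %*% ev$vectors[, 2]
  d1 <- diff(range(proj1)) + footprint
  d2 <- diff(range(proj2)) + footprint
  .record("diameter", min(d1, d2), "tem_shortest",
          side_a = min(d1, d2), side_b = max(d1, d2), ...)
}

#' Integrated layer intensity fractions
#'
#' Splits an image into horizontal layers (retinal layers: outer
#' segment, inner segment, outer nuclear layer, inner nuclear layer)
#' at the given row positions and returns each layer's integrated
#' intensity normalized by the total signal.
#'
#' @param image an [image2d].
#' @param layer_boundaries ordered row positions, nm: either the
#'   `n_layers - 1` internal boundaries (image edges complete them) or
#'   all `n_layers + 1` boundaries.
#' @param n_layers number of layers (default 4).
#' @param layer_names optional labels for the records.
#' @param ... record metadata.
#' @return measurement record data.frame, one row per layer
#'   (`kind = "layer_fraction"`, value in `[0, 1]`, summing to 1).
#' @export
layer_intensity_fractions <- function(image, layer_boundaries, n_layers = 4,
                                      layer_names = NULL, ...) {
  stopifnot(inherits(image, "image2d"))
  b <- sort(as.numeric(layer_boundaries))
  rows <- pixel_centers(image, "row")
  px <- pixel_size(image)
  if (length(b) == n_layers - 1) {
    b <- c(min(rows) - px / 2, b, max(rows) + px / 2)
  } else if (length(b) != n_layers + 1) {
    stop("layer_boundaries must have n_layers - 1 or n_layers + 1 entries")
  }
  if (b[1] > max(rows) || b[length(b)] < min(rows))
    stop("layer boundaries fall outside the image")
  sums <- numeric(n_layers)
  rs <- rowSums(image)
  for (i in seq_len(n_layers)) {
    inlayer <- rows >= b[i] & rows < b[i + 1]
    if (i == n_layers) inlayer <- rows >= b[i] & rows <= b[i + 1]
    sums[i] <- sum(rs[inlayer])
  }
  total <- sum(sums)
  if (total <= 0) stop("zero total intensity")
  if (is.null(layer_names)) layer_names <- paste0("layer_", seq_len(n_layers))
  recs <- lapply(seq_len(n_layers), function(i)
    .record("layer_fraction", sums[i] / total, "integrated",
            target_channel = layer_names[i], ...))
  do.call(rbind, recs)
}
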