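# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no find_edges/apply_filters calls inside).

# Random unimodal profile on a 40 nm grid: a smooth bump with random
# width/asymmetry/amplitude and strictly monotone flanks.
random_unimodal_profile <- function(spacing = 40, n = 61) {
  pos <- (seq_len(n) - 1) * spacing
  center <- stats::runif(1, 0.3, 0.7) * max(pos)
  wl <- stats::runif(1, 60, 400)   # left flank width
  wr <- stats::runif(1, 60, 400)   # right flank width
  amp <- stats::runif(1, 5, 500)
  shape <- ifelse(pos < center, exp(-(pos - center)^2 / (2 * wl^2)),
                  exp(-(pos - center)^2 / (2 * wr^2)))
  intensity_profile(amp * shape, spacing, origin_nm = 0, axis = "longitudinal")
}

# Dense-linear-scan edge oracle: linearly interpolate the sampled profile
# onto a fine grid and scan for the outermost grid points at/above the
# threshold on each side of the maximum.
edges_dense_scan <- function(values, spacing, f, background = 0,
                             step = 0.01) {
  pos <- (seq_along(values) - 1) * spacing
  grid <- seq(0, max(pos), by = step)
  dense <- stats::approx(pos, values, xout = grid)$y
  thr <- background + f * (max(values) - background)
  above <- which(dense >= thr)
  c(proximal = grid[above[1]], distal = grid[above[length(above)]])
}

# Noiseless profile of a top-hat of length L centered at `center`
# convolved with a Gaussian of sd sigma (difference of normal CDFs).
erf_profile <- function(x, L, sigma, center = 0) {
  a <- center - L / 2; b <- center + L / 2
  stats::pnorm((x - a) / sigma) - stats::pnorm((x - b) / sigma)
}

# Length of the erf profile at fraction f of its maximum, by root finding
# on the continuous function (the numeric oracle for the broadening grid).
erf_length_oracle <- function(L, sigma, f) {
  peak <- erf_profile(0, L, sigma)
  thr <- f * peak
  g <- function(x) erf_profile(x, L, sigma) - thr
  lo <- -L / 2 - 10 * sigma - 1
  left <- stats::uniroot(g, c(lo, 0), tol = 1e-10)$root
  -2 * left  # symmetric about 0
}

# Independent acceptance rule table for STORM fits (same rules, coded
# flat over vectors, independent of apply_filters' control flow).
rule_table_decide <- function(height, wx, wy, s) {
  ok <- height >= s$min_psf_height & height <= s$max_psf_height &
    pmin(wx, wy) >= s$min_psf_width & pmax(wx, wy) <= s$max_psf_width &
    pmax(wx, wy) / pmin(wx, wy) <= s$max_axial_ratio
  ifelse(ok, "accepted", "rejected")
}

# Randomized fit table spanning both sides of every rule boundary.
random_fit_table <- function(n) {
  data.frame(frame = seq_len(n),
             row_nm = stats::runif(n, 0, 1000),
             col_nm = stats::runif(n, 0, 1000),
             height = stats::runif(n, 0, 80000),
             wx_nm = stats::runif(n, 50, 900),
             wy_nm = stats::runif(n, 50, 900),
             background = stats::runif(n, 0, 20),
             residual = stats::runif(n),
             photons = stats::runif(n, 100, 5000),
             status = rep("unfiltered", n), reason = rep("", n),
             stringsAsFactors = FALSE)
}

# Frame with one elliptical Gaussian evaluated at pixel centers (the
# exact model fit_psf assumes), plus constant background.
gaussian_frame <- function(nr = 21, nc = 21, px = 160, height = 2000,
                           r0 = 11, c0 = 11, sr = 130, sc = 130, bg = 5,
                           droff = 0, dcoff = 0) {
  u <- ((seq_len(nr)) - r0) * px - droff
  v <- ((seq_len(nc)) - c0) * px - dcoff
  m <- bg + height * exp(-outer(u^2 / (2 * sr^2), v^2 / (2 * sc^2), "+"))
  image2d(m, pixel_size_nm = px, origin_nm = c(0, 0), view = "longitudinal")
}
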