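# Straightening, average profiles, fractional-threshold edges, radii,
# offsets, asymmetry, TEM diameters and layer fractions.

test_that("straightening along a vertical line reproduces the crop", {
  set.seed(3)
  # smooth random image so bilinear interpolation is exact on the grid
  m <- matrix(rnorm(60 * 40, 100, 20), 60, 40)
  img <- image2d(m, pixel_size_nm = 40, origin_nm = c(0, 0))
  cl <- data.frame(x = 800, z = c(200, 1600))
  out <- straighten(img, cl, half_width = 400)
  rows <- 200 / 40 + 1 + seq_len(nrow(out)) - 1
  cols <- (800 - 400) / 40 + 1 + seq_len(ncol(out)) - 1
  expect_lt(max(abs(unclass(out) - m[rows, cols])), 1e-6)

  const <- image2d(matrix(7, 50, 50), pixel_size_nm = 40)
  wav <- straighten(const, data.frame(x = c(600, 800, 1000),
                                      z = c(300, 900, 1500)),
                    half_width = 200)
  expect_true(all(abs(wav - 7) < 1e-9))
  expect_error(straighten(img, data.frame(x = -500, z = c(0, 100)), 200),
               "exits the image")
})

test_that("row and column averages are per-line means", {
  m <- matrix(0, 8, 6)
  img <- image2d(m + 3, pixel_size_nm = 40)
  expect_true(all(row_average_profile(img)$values == 3))
  m2 <- m; m2[5, ] <- 10
  p <- row_average_profile(image2d(m2, pixel_size_nm = 40))
  expect_equal(which(p$values != 0), 5)
  expect_equal(p$values[5], 10)
  # checkerboard of 0/8 averages to 4 everywhere
  chk <- outer(1:8, 1:6, function(i, j) 8 * ((i + j) %% 2))
  expect_true(all(row_average_profile(image2d(chk, 40))$values == 4))
  expect_true(all(column_average_profile(image2d(chk, 40))$values == 4))
})

test_that("edge calls interpolate sub-sample at the fractional threshold", {
  p <- intensity_profile(c(0, 0, 3, 9, 9, 3, 0, 0), 40)
  e <- find_edges(p, rule = 1 / 3)
  expect_equal(e$threshold, 3)
  expect_equal(e$proximal_nm, 80)
  expect_equal(e$distal_nm, 200)
  expect_false(any(e$truncated))
  expect_equal(e$max_position_nm, mean(c(120, 160)))  # tied maxima averaged

  # FWHM rule on an exactly symmetric triangle: edges at samples 1 and 3
  tri <- intensity_profile(c(0, 4, 8, 4, 0), 40)
  ef <- find_edges(tri, "FWHM")
  expect_equal(ef$proximal_nm, 40)
  expect_equal(ef$distal_nm, 120)
  expect_equal(ef$distal_nm - ef$proximal_nm, 2 * 40)

  expect_error(find_edges(intensity_profile(c(0, 0, 0, 0), 40)), "no signal")

  # truncation: signal still above threshold at the profile end
  tr <- intensity_profile(c(5, 9, 7, 2, 0), 40)
  et <- find_edges(tr, rule = 1 / 3)
  expect_true(et$truncated[1])
  expect_equal(et$proximal_nm, 0)
})

test_that("edge calls agree with an independent dense scan on random profiles", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_unimodal_profile()
    for (rule in list(c("frac_033", 0.33), c("FWHM", 0.5),
                      c("inv_e", exp(-1)))) {
      e <- find_edges(p, rule[[1]])
      o <- edges_dense_scan(p$values, p$spacing_nm, as.numeric(rule[[2]]))
      expect_lt(abs(e$proximal_nm - o["proximal"]), 0.5)
      expect_lt(abs(e$distal_nm - o["distal"]), 0.5)
    }
  }
})

test_that("length measurement starts at the origin channel's distal edge", {
  sp <- 40
  pos <- seq(0, 2000, by = sp)
  target <- intensity_profile(erf_profile(pos, 1000, 60, center = 600), sp)
  rec <- measure_length(target, NULL, rule = "FWHM")
  expect_equal(rec$value_nm, 1000, tolerance = 1)
  expect_identical(rec$kind, "length")

  # origin channel pushes the proximal bound distally
  origin <- intensity_profile(erf_profile(pos, 300, 60, center = 150), sp)
  rec2 <- measure_length(target, origin, rule = "FWHM")
  oe <- find_edges(origin, "FWHM")$distal_nm
  te <- find_edges(target, "FWHM")
  expect_equal(rec2$value_nm, te$distal_nm - max(te$proximal_nm, oe))

  # window overrun clamps and flags
  long <- intensity_profile(erf_profile(pos, 1900, 40, center = 1000), sp)
  rec3 <- measure_length(long, NULL, rule = "FWHM", window_nm = 1100)
  expect_equal(rec3$value_nm, 1100)
  expect_match(rec3$flags, "overrun")
})

test_that("radius is the larger lateral distance from the reference maximum", {
  sp <- 10
  pos <- seq(-400, 400, by = sp)
  ref <- intensity_profile(exp(-pos^2 / (2 * 50^2)), sp, origin_nm = -400,
                           axis = "transverse")
  # symmetric target with 33% edges at +/- 137 nm about the center:
  # top-hat of half-width a blurred by sigma has its f-edge where the
  # erf profile crosses f; build it directly from the closed form
  tgt_vals <- erf_profile(pos, 2 * 115, 30)
  tgt <- intensity_profile(tgt_vals, sp, origin_nm = -400,
                           axis = "transverse")
  e <- find_edges(tgt, rule = 0.33)
  half_width <- (e$distal_nm - e$proximal_nm) / 2
  rec <- measure_radius(tgt, ref, rule = 0.33)
  expect_equal(rec$value_nm, half_width, tolerance = 1e-6)
  expect_equal(rec$side_a_nm, rec$side_b_nm, tolerance = 1e-6)

  # tie rule: two equal maxima at +/- 90 -> center 0
  two <- rep(0, length(pos))
  two[match(c(-90, 90), pos)] <- 5
  ref2 <- intensity_profile(two, sp, origin_nm = -400, axis = "transverse")
  rec2 <- measure_radius(tgt, ref2, rule = 0.33)
  expect_equal(find_edges(ref2, 0.33)$max_position_nm, 0)
  expect_equal(rec2$value_nm, half_width, tolerance = 1e-6)
})

test_that("edge offsets are signed shifts between homologous edges", {
  sp <- 40
  pos <- seq(0, 2000, by = sp)
  a <- intensity_profile(erf_profile(pos, 600, 50, center = 800), sp)
  expect_equal(edge_offset(a, a, "distal_vs_distal")$value_nm, 0)
  # channel a = channel b shifted distally by 3 samples
  b_vals <- erf_profile(pos, 600, 50, center = 800)
  a_vals <- c(rep(0, 3), b_vals[seq_len(length(pos) - 3)])
  a2 <- intensity_profile(a_vals, sp)
  b2 <- intensity_profile(b_vals, sp)
  expect_equal(edge_offset(a2, b2, "distal_vs_distal")$value_nm, 120,
               tolerance = 1e-6)
  # shifted distally means *less* proximal extent
  expect_equal(edge_offset(a2, b2, "proximal_vs_proximal")$value_nm, -120,
               tolerance = 1e-6)
})

test_that("asymmetry index is the centroid shift from the reference axis", {
  sp <- 10
  pos <- seq(-300, 300, by = sp)
  ref <- intensity_profile(exp(-pos^2 / (2 * 40^2)), sp, origin_nm = -300,
                           axis = "transverse")
  sym <- intensity_profile(exp(-pos^2 / (2 * 80^2)), sp, origin_nm = -300,
                           axis = "transverse")
  expect_equal(asymmetry_index(sym, ref)$value_nm, 0, tolerance = 1e-9)
  # two point masses 2 and 1 at +100 / -100: centroid +33.33
  two <- rep(0, length(pos))
  two[match(100, pos)] <- 2
  two[match(-100, pos)] <- 1
  tp <- intensity_profile(two, sp, origin_nm = -300, axis = "transverse")
  expect_equal(asymmetry_index(tp, ref)$value_nm, 100 / 3, tolerance = 1e-9)
  zero <- intensity_profile(rep(0, length(pos)), sp, origin_nm = -300)
  expect_error(asymmetry_index(zero, ref), "zero total")
})

test_that("TEM rule returns the shortest principal-axis diameter", {
  px <- 2
  mask_ellipse <- function(a, b, theta, px, pad = 20) {
    half <- max(a, b) + pad
    ctr <- seq(-half, half, by = px)
    X <- outer(ctr, ctr, function(y, x) x)
    Y <- outer(ctr, ctr, function(y, x) y)
    xr <- X * cos(theta) + Y * sin(theta)
    yr <- -X * sin(theta) + Y * cos(theta)
    image2d(1 * ((xr / a)^2 + (yr / b)^2 <= 1), pixel_size_nm = px,
            origin_nm = c(-half, -half))
  }
  circ <- tem_shortest_diameter(mask_ellipse(50, 50, 0, px))
  expect_equal(circ$value_nm, 100, tolerance = px)
  ell <- tem_shortest_diameter(mask_ellipse(110, 93, 0, px))
  expect_equal(ell$value_nm, 186, tolerance = px)
  rot <- tem_shortest_diameter(mask_ellipse(110, 93, 37 * pi / 180, px))
  expect_equal(rot$value_nm, 186, tolerance = px)
  expect_equal(rot$side_b_nm, 220, tolerance = 2 * px)

  # point annotation input and degenerate error
  th <- seq(0, 2 * pi, length.out = 100)
  pts <- data.frame(x = 110 * cos(th), y = 93 * sin(th))
  expect_equal(tem_shortest_diameter(pts)$value_nm, 186, tolerance = 0.5)
  line <- data.frame(x = 1:10, y = 2 * (1:10))
  expect_error(tem_shortest_diameter(line), "collinear")
})

test_that("layer fractions integrate to one and split as constructed", {
  m <- matrix(0, 40, 10)
  m[1:10, ] <- 5
  img <- image2d(m, pixel_size_nm = 100)
  fr <- layer_intensity_fractions(img, c(1000, 2000, 3000), n_layers = 4)
  expect_equal(fr$value_nm, c(1, 0, 0, 0))

  uni <- image2d(matrix(2, 40, 10), pixel_size_nm = 100)
  fu <- layer_intensity_fractions(uni, c(1000, 2000, 3000), n_layers = 4)
  expect_equal(fu$value_nm, rep(0.25, 4))
  expect_equal(sum(fu$value_nm), 1, tolerance = 1e-9)

  m3 <- matrix(0, 40, 10)
  m3[1:20, ] <- 3; m3[21:40, ] <- 1
  f3 <- layer_intensity_fractions(image2d(m3, 100), 2000, n_layers = 2)
  expect_equal(f3$value_nm, c(0.75, 0.25))
  expect_error(layer_intensity_fractions(image2d(matrix(0, 8, 4), 100),
                                         400, n_layers = 2), "zero total")
})

test_that("measurements are invariant to uniform intensity rescaling", {
  set.seed(55)
  p <- random_unimodal_profile()
  p10 <- intensity_profile(10 * p$values, p$spacing_nm, p$origin_nm, p$axis)
  for (rule in c("frac_033", "FWHM", "inv_e")) {
    e1 <- find_edges(p, rule); e2 <- find_edges(p10, rule)
    expect_equal(e1$proximal_nm, e2$proximal_nm, tolerance = 1e-9)
    expect_equal(e1$distal_nm, e2$distal_nm, tolerance = 1e-9)
  }
})

test_that("threshold fractions order measured lengths monotonically", {
  set.seed(77)
  for (i in 1:30) {
    p <- random_unimodal_profile()
    w <- vapply(c(0.33, exp(-1), 0.5), function(f) {
      e <- find_edges(p, f)
      e$distal_nm - e$proximal_nm
    }, numeric(1))
    expect_true(w[1] >= w[2] && w[2] >= w[3])
  }
})

test_that("bent-cilium straightening recovers the straight profile", {
  # noiseless bent render straightened along the known arc centerline
  geom <- genotype_preset("WT_adult")$geometry
  ch <- channel_model("centrin", c(0, 1000), "lumen_fill",
                      list(outer = geom$lumen_radius), emitter_density = 1500)
  em <- sample_emitters(geom, ch, seed = 60, n = 2000)
  im <- imaging_model(psf_fwhm = 120, pixel_size = 40, poisson_on = FALSE,
                      read_sigma = 0, background = 0)
  straight <- render_image(em, im, seed = 1,
                           fov = list(row_nm = c(-400, 1400),
                                      col_nm = c(-500, 500)))
  p_straight <- row_average_profile(
    straighten(straight, data.frame(x = 0, z = c(-380, 1380)),
               half_width = 300))
  kappa <- 1 / 1800
  bem <- bend_axis(em, kappa, cc_length = 1000)
  bent <- render_image(bem, im, seed = 1,
                       fov = list(row_nm = c(-400, 1400),
                                  col_nm = c(-500, 700)))
  cl <- bent_centerline(1380, kappa, step_nm = 20, z_min = -380)
  p_bent <- row_average_profile(straighten(bent, cl, half_width = 300))
  n <- min(length(p_straight$values), length(p_bent$values))
  a <- p_straight$values[1:n]; b <- p_bent$values[1:n]
  rms_rel <- sqrt(mean((a - b)^2)) / sqrt(mean(a^2))
  expect_lt(rms_rel, 0.05)
})
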