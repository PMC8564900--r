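#' Simulate one cilium: emitters plus rendered channel images
#'
#' Draws ground-truth emitter sets for every channel of a preset (or a
#' custom geometry/channel list), optionally bends the cilium, and
#' renders all channels onto a common field of view so the per-channel
#' profiles are aligned.
#'
#' @param preset preset name (see [genotype_preset()]) or a list with
#'   `geometry` and `channels`.
#' @param seed integer seed for this cilium (emitter draws and noise).
#' @param imaging an [imaging_model]; its `view` selects the projection.
#' @param curvature axial curvature passed to [bend_axis()] (0 = straight).
#' @param cilium_id identifier recorded in downstream measurements.
#' @return list of class `cilium_sim` with `geometry`, `channels`,
#'   `emitters` (named list of emitter sets), `images` (named list of
#'   [image2d]), `cilium_id`, `seed`.
#' @export
simulate_cilium <- function(preset = "WT_adult", seed = 1L,
                            imaging = imaging_model(), curvature = 0,
                            cilium_id = sprintf("cilium_%04d", seed)) {
  p <- if (is.character(preset)) genotype_preset(preset) else preset
  geom <- p$geometry
  chans <- p$channels
  names(chans) <- vapply(chans, `[[`, "", "marker_name")
  pad <- 3 * imaging$psf_fwhm + 60
  zmin <- min(vapply(chans, function(ch) ch$z_range[1], numeric(1)))
  zmax <- max(vapply(chans, function(ch) ch$z_range[2], numeric(1)))
  xmax <- geom$membrane_radius + 100
  emitters <- list()
  images <- list()
  for (i in seq_along(chans)) {
    ch_seed <- (as.integer(seed) * 131L + i) %% .Machine$integer.max
    em <- sample_emitters(geom, chans[[i]], seed = ch_seed)
    if (curvature != 0)
      em <- bend_axis(em, curvature, cc_length = zmax)
    emitters[[names(chans)[i]]] <- em
  }
  if (curvature == 0) {
    fov <- list(row_nm = c(zmin - pad, zmax + pad),
                col_nm = c(-xmax - pad, xmax + pad))
  } else {
    allr <- unlist(lapply(emitters, function(e)
      if (imaging$view == "longitudinal") e$z else e$y))
    allc <- unlist(lapply(emitters, `[[`, "x"))
    fov <- list(row_nm = range(allr, 0) + c(-pad, pad),
                col_nm = range(allc, 0) + c(-pad, pad))
  }
  for (i in seq_along(emitters)) {
    ch_seed <- (as.integer(seed) * 131L + 1000L + i) %% .Machine$integer.max
    images[[names(emitters)[i]]] <-
      render_image(emitters[[i]], imaging, seed = ch_seed, fov = fov)
  }
  structure(list(geometry = geom, channels = chans, emitters = emitters,
                 images = images, cilium_id = cilium_id, seed = seed),
            class = "cilium_sim")
}

#' Crop an image to a row-axis window
#'
#' @param image an [image2d].
#' @param from_nm,to_nm physical row-axis range to keep.
#' @return cropped [image2d].
#' @export
crop_rows <- function(image, from_nm, to_nm) {
  rows <- pixel_centers(image, "row")
  keep <- which(rows >= from_nm & rows <= to_nm)
  if (length(keep) < 3) stop("crop window contains fewer than 3 rows")
  image2d(unclass(image)[keep, , drop = FALSE], pixel_size(image),
          origin_nm = c(rows[keep[1]], image_origin(image)[2]),
          view = attr(image, "view"))
}

#' Quantify one simulated or straightened cilium
#'
#' Runs the full measurement pipeline on aligned per-channel
#' longitudinal images: row-average profiles, lengths from the origin
#' channel's distal edge, maximum radii from the reference channel's
#' transverse maximum (computed on column averages inside the
#' longitudinal analysis window), and the transverse asymmetry index.
#'
#' @param images named list of aligned longitudinal [image2d], one per
#'   channel (as produced by [simulate_cilium()]).
#' @param rule,background see [find_edges()].
#' @param origin_channel channel marking the IS/CC interface (default
#'   `"CEP164"`; `NULL` uses each target's own proximal edge).
#' @param reference_channel channel whose transverse maximum defines the
#'   cilium center for radii (default `"centrin"`).
#' @param window_nm longitudinal analysis window (1100 nm for the
#'   connecting cilium; `Inf` disables it, hRPE-1 mode).
#' @param genotype,cilium_id metadata recorded per measurement.
#' @return measurement record data.frame, one row per channel per kind.
#' @export
quantify_cilium <- function(images, rule = "frac_033", background = 0,
                            origin_channel = "CEP164",
                            reference_channel = "centrin",
                            window_nm = 1100,
                            genotype = NA_character_,
                            cilium_id = NA_character_) {
  stopifnot(length(images) >= 1, !is.null(names(images)))
  profiles <- lapply(images, row_average_profile)
  origin_profile <- if (!is.null(origin_channel) &&
                        origin_channel %in% names(images))
    profiles[[origin_channel]] else NULL
  records <- list()
  targets <- setdiff(names(images), origin_channel)
  for (tg in targets) {
    rec <- try(measure_length(profiles[[tg]], origin_profile, rule,
                              background, window_nm,
                              target_channel = tg,
                              reference_channel = origin_channel %||% "self",
                              genotype = genotype, cilium_id = cilium_id),
               silent = TRUE)
    if (!inherits(rec, "try-error")) records[[length(records) + 1L]] <- rec
  }
  # transverse profiles inside the analysis window
  origin_nm <- if (!is.null(origin_profile))
    find_edges(origin_profile, rule, background)$distal_nm else 0
  win_hi <- if (is.finite(window_nm)) origin_nm + window_nm
            else max(pixel_centers(images[[1]], "row"))
  trans <- lapply(images, function(img) {
    cropped <- try(crop_rows(img, origin_nm, win_hi), silent = TRUE)
    if (inherits(cropped, "try-error")) return(NULL)
    column_average_profile(cropped)
  })
  ref_t <- trans[[reference_channel]]
  if (!is.null(ref_t)) {
    for (tg in setdiff(names(images), origin_channel)) {
      if (is.null(trans[[tg]])) next
      rec <- try(measure_radius(trans[[tg]], ref_t, rule, background,
                                target_channel = tg,
                                reference_channel = reference_channel,
                                genotype = genotype, cilium_id = cilium_id),
                 silent = TRUE)
      if (!inherits(rec, "try-error")) records[[length(records) + 1L]] <- rec
      rec <- try(asymmetry_index(trans[[tg]], ref_t, background,
                                 target_channel = tg,
                                 reference_channel = reference_channel,
                                 genotype = genotype, cilium_id = cilium_id),
                 silent = TRUE)
      if (!inherits(rec, "try-error")) records[[length(records) + 1L]] <- rec
    }
  }
  if (length(records) == 0)
    stop("no channel produced a measurable profile")
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline stage: simulate a batch of cilia to disk
#'
#' Writes, per cilium and channel, a plain-text image and a ground-truth
#' emitter CSV, plus a geometry YAML (TEM-derived diameters echoed in
#' nm) and a provenance YAML. Deterministic for a given seed.
#'
#' @param out_dir output directory (created if needed).
#' @param preset preset name, see [genotype_preset()].
#' @param n number of cilia.
#' @param seed run seed; per-cilium seeds derive from it.
#' @param psf_fwhm,pixel_size imaging parameters, nm.
#' @param noise apply camera noise.
#' @param curvature cilium curvature in 1/nm.
#' @return (invisibly) the list of `cilium_sim` objects.
#' @export
run_simulate <- function(out_dir, preset = "WT_adult", n = 10, seed = 1L,
                         psf_fwhm = 120, pixel_size = 40, noise = TRUE,
                         curvature = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- genotype_preset(preset)
  img_model <- imaging_model(psf_fwhm = psf_fwhm, pixel_size = pixel_size,
                             poisson_on = noise,
                             read_sigma = if (noise) 2 else 0,
                             background = if (noise) 10 else 0)
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    ci_seed <- (as.integer(seed) * 1009L + i) %% .Machine$integer.max
    id <- sprintf("%s_%03d", preset, i)
    sim <- simulate_cilium(p, seed = ci_seed, imaging = img_model,
                           curvature = curvature, cilium_id = id)
    for (ch in names(sim$images)) {
      write_image_txt(sim$images[[ch]],
                      file.path(out_dir, sprintf("%s_%s.img.txt", id, ch)))
      write_table_csv(as.data.frame(sim$emitters[[ch]]),
                      file.path(out_dir, sprintf("%s_%s.emitters.csv", id, ch)))
    }
    sims[[i]] <- sim
  }
  g <- p$geometry
  write_config_yaml(list(
    preset = preset, genotype_label = g$genotype_label,
    cc_length_nm = g$cc_length,
    axoneme_diameter_nm = 2 * g$axoneme_ring_radius,
    membrane_diameter_nm = 2 * g$membrane_radius,
    lumen_diameter_nm = 2 * g$lumen_radius,
    doublet_count = g$doublet_count,
    channels = lapply(p$channels, function(ch)
      list(marker = ch$marker_name, radial_kind = ch$radial_kind,
           z_range_nm = ch$z_range))),
    file.path(out_dir, "geometry.yaml"))
  write_config_yaml(.provenance("simulate",
                                list(preset = preset, n = n,
                                     psf_fwhm = psf_fwhm,
                                     pixel_size = pixel_size, noise = noise,
                                     curvature = curvature), seed),
                    file.path(out_dir, "provenance.yaml"))
  invisible(sims)
}

#' Pipeline stage: localize a frame stack to disk
#'
#' @param stack a `frame_stack` or path to a stack written by
#'   [write_stack_txt()].
#' @param out_dir output directory.
#' @param settings a [storm_settings].
#' @param detect_threshold see [detect_candidates()].
#' @param render_sigma rendering Gaussian sd, nm.
#' @return (invisibly) the [localize_stack()] result.
#' @export
run_localize <- function(stack, out_dir, settings = storm_settings(),
                         detect_threshold = 50, render_sigma = 15) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(stack)) stack <- read_stack_txt(stack)
  res <- localize_stack(stack, settings, detect_threshold)
  if (nrow(res$chains) == 0)
    warning("no accepted localizations in this stack")
  write_table_csv(res$fits, file.path(out_dir, "localizations.csv"))
  write_table_csv(res$chains, file.path(out_dir, "chains.csv"))
  write_image_txt(render_storm(res$chains, render_sigma),
                  file.path(out_dir, "storm_render.img.txt"))
  write_config_yaml(.provenance("localize", c(
    unclass(settings), list(detect_threshold = detect_threshold,
                            render_sigma = render_sigma,
                            counts = as.list(res$counts))), NA),
    file.path(out_dir, "provenance.yaml"))
  invisible(res)
}

#' Pipeline stage: quantify simulated (or straightened) cilia to disk
#'
#' Reads every cilium written by [run_simulate()] from `in_dir` (or
#' takes the in-memory simulation list), measures it, and writes one
#' measurement record CSV.
#'
#' @param in_dir directory written by [run_simulate()], or a list of
#'   `cilium_sim` objects.
#' @param out_dir output directory.
#' @param rule,background see [find_edges()].
#' @param window_nm longitudinal analysis window (`Inf` = hRPE-1 mode).
#' @param origin_channel,reference_channel see [quantify_cilium()].
#' @param genotype genotype label for the records (defaults to the
#'   prefix of each cilium id).
#' @return (invisibly) the measurement record data.frame.
#' @export
run_quantify <- function(in_dir, out_dir, rule = "frac_033", background = 0,
                         window_nm = 1100, origin_channel = "CEP164",
                         reference_channel = "centrin", genotype = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(in_dir)) {
    files <- list.files(in_dir, pattern = "\\.img\\.txt$")
    ids <- unique(sub("_[^_]+\\.img\\.txt$", "", files))
    sims <- lapply(ids, function(id) {
      chf <- files[startsWith(files, paste0(id, "_"))]
      chn <- sub("\\.img\\.txt$", "", sub(paste0("^", id, "_"), "", chf))
      imgs <- lapply(file.path(in_dir, chf), read_image_txt)
      names(imgs) <- chn
      list(images = imgs, cilium_id = id)
    })
  } else {
    sims <- in_dir
  }
  recs <- lapply(sims, function(sim) {
    gt <- genotype %||% sub("_[0-9]+$", "", sim$cilium_id)
    quantify_cilium(sim$images, rule = rule, background = background,
                    origin_channel = origin_channel,
                    reference_channel = reference_channel,
                    window_nm = window_nm, genotype = gt,
                    cilium_id = sim$cilium_id)
  })
  out <- do.call(rbind, recs)
  write_table_csv(out, file.path(out_dir, "measurements.csv"))
  write_config_yaml(.provenance("quantify", list(
    rule = if (is.numeric(rule)) sprintf("frac_%g", rule) else rule,
    background = background, window_nm = window_nm,
    origin_channel = origin_channel,
    reference_channel = reference_channel,
    n_cilia = length(sims), n_records = nrow(out)), NA),
    file.path(out_dir, "provenance.yaml"))
  invisible(out)
}

#' Pipeline stage: group summaries and hypothesis tests
#'
#' For every (target channel, measurement kind) the measurements are
#' grouped by genotype and summarized as "mean +/- SD (n)"; with two
#' groups a Student two-tailed t test is run, with more a one-way ANOVA
#' with Dunnett's post hoc comparisons against the control genotype
#' (default) or Tukey's all-pairs correction.
#'
#' @param measurements measurement record data.frame or path to the CSV
#'   from [run_quantify()].
#' @param out_dir optional output directory for `stats.csv` and
#'   `report.txt`.
#' @param method `"dunnett"` (default, comparisons against control) or
#'   `"tukey"`.
#' @param control control genotype label for Dunnett; defaults to the
#'   group whose label contains `"WT"`, else the first group.
#' @return list with `summaries`, `tests` (data.frames) and `report`
#'   (character lines).
#' @export
run_compare <- function(measurements, out_dir = NULL,
                        method = c("dunnett", "tukey"), control = NULL) {
  method <- match.arg(method)
  if (is.character(measurements))
    measurements <- read_table_csv(measurements)
  keys <- unique(measurements[, c("target", "kind")])
  summaries <- list(); tests <- list(); report <- character(0)
  for (r in seq_len(nrow(keys))) {
    sub <- measurements[measurements$target == keys$target[r] &
                          measurements$kind == keys$kind[r], , drop = FALSE]
    groups <- split(sub$value_nm, sub$genotype)
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    sm <- do.call(rbind, lapply(names(groups), function(g)
      cbind(target = keys$target[r], kind = keys$kind[r],
            summarize_group(groups[[g]], g))))
    summaries[[length(summaries) + 1L]] <- sm
    for (i in seq_len(nrow(sm)))
      report <- c(report, sprintf("%s %s [%s]: %s", keys$target[r],
                                  keys$kind[r], sm$group[i],
                                  format_summary(sm[i, ])))
    if (length(groups) < 2 || any(vapply(groups, length, integer(1)) < 2)) {
      if (length(groups) < 2)
        warning("only one group for ", keys$target[r], " ", keys$kind[r],
                "; summaries only, no test")
      next
    }
    if (length(groups) == 2) {
      tt <- t_test_two_tailed(groups[[1]], groups[[2]])
      tests[[length(tests) + 1L]] <-
        data.frame(target = keys$target[r], kind = keys$kind[r],
                   comparison = paste(names(groups)[2], "-", names(groups)[1]),
                   test = tt$test, statistic = tt$statistic, p = tt$p,
                   p_adj = tt$p)
    } else {
      ctrl <- control %||% {
        wt <- grep("WT", names(groups), value = TRUE)
        if (length(wt) > 0) wt[1] else names(groups)[1]
      }
      ap <- anova_posthoc(groups, method = method,
                          control = if (method == "dunnett") ctrl else NULL)
      tests[[length(tests) + 1L]] <-
        data.frame(target = keys$target[r], kind = keys$kind[r],
                   comparison = ap$comparisons$comparison, test = ap$test,
                   statistic = ap$comparisons$statistic,
                   p = ap$comparisons$p_raw, p_adj = ap$comparisons$p_adj)
    }
  }
  summaries <- do.call(rbind, summaries)
  tests <- if (length(tests) > 0) do.call(rbind, tests) else
    data.frame(target = character(0), kind = character(0),
               comparison = character(0), test = character(0),
               statistic = numeric(0), p = numeric(0), p_adj = numeric(0))
  rownames(summaries) <- rownames(tests) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(summaries, file.path(out_dir, "summaries.csv"))
    write_table_csv(tests, file.path(out_dir, "stats.csv"))
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  list(summaries = summaries, tests = tests, report = report)
}
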