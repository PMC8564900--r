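#' Cilium geometry
#'
#' Ground-truth geometry of one cilium: a cylinder of axial length
#' `cc_length` starting at z = 0 (the inner-segment/connecting-cilium
#' interface, i.e. the distal edge of the transition fibers marked by
#' CEP164) and extending distally. Radii describe the structural
#' positions: the lumen, the 9-doublet axoneme ring (doublet centers),
#' and the ciliary membrane. Structural radii derive from TEM diameters
#' (halved), the least-blurred measurement available, not from
#' fluorescence widths which include PSF inflation.
#'
#' @param cc_length axial extent in nm, interface to outer-segment base.
#' @param membrane_radius,axoneme_ring_radius,lumen_radius radii in nm;
#'   must satisfy `0 < lumen < ring < membrane`.
#' @param doublet_count number of microtubule doublets (default 9).
#' @param curvature axial curvature in 1/nm (0 = straight).
#' @param axis_origin 2D position of the axis in the lab frame, nm.
#' @param genotype_label free-text genotype tag.
#' @return object of class `cilium_geometry`.
#' @export
cilium_geometry <- function(cc_length, membrane_radius, axoneme_ring_radius,
                            lumen_radius, doublet_count = 9L, curvature = 0,
                            axis_origin = c(0, 0), genotype_label = "custom") {
  stopifnot(cc_length > 0, doublet_count >= 1)
  if (!(0 < lumen_radius && lumen_radius < axoneme_ring_radius &&
        axoneme_ring_radius < membrane_radius))
    stop("radii must satisfy 0 < lumen_radius < axoneme_ring_radius < membrane_radius")
  structure(list(cc_length = cc_length,
                 membrane_radius = membrane_radius,
                 axoneme_ring_radius = axoneme_ring_radius,
                 lumen_radius = lumen_radius,
                 doublet_count = as.integer(doublet_count),
                 curvature = curvature,
                 axis_origin = axis_origin,
                 genotype_label = genotype_label),
            class = "cilium_geometry")
}

#' @export
print.cilium_geometry <- function(x, ...) {
  cat(sprintf("<cilium_geometry> %s: length %g nm; radii lumen/ring/membrane = %g/%g/%g nm; %d doublets; curvature %g /nm\n",
              x$genotype_label, x$cc_length, x$lumen_radius,
              x$axoneme_ring_radius, x$membrane_radius, x$doublet_count,
              x$curvature))
  invisible(x)
}

#' Labeling model for one fluorescence channel
#'
#' Describes where a marker sits in the cilium frame: an axial window
#' `z_range` relative to the IS/CC interface (negative = proximal,
#' inner-segment side) and a radial law.
#'
#' Radial kinds:
#' \describe{
#'   \item{lumen_fill}{uniform over the disk of radius `outer` (defaults
#'     to the geometry's lumen radius): soluble/lumenal markers such as
#'     centrin in the rod connecting cilium.}
#'   \item{doublet_ring}{emitters clustered (2D Gaussian, sd
#'     `cluster_sigma`) around the `doublet_count` doublet positions on
#'     the axoneme ring: acetylated tubulin.}
#'   \item{annulus}{uniform over the annulus `inner`..`outer`: material
#'     between axoneme and membrane such as CEP290 / Y-link region.}
#'   \item{membrane_shell}{radius uniform in `outer` +/- `thickness`/2:
#'     membrane glycocalyx labels such as WGA.}
#'   \item{basal_patch}{uniform over the disk of radius `outer`; used with
#'     a short axial window for basal-body/transition-fiber markers
#'     (CEP164, basal-body centrin or CEP290 in epithelial primary
#'     cilia).}
#' }
#'
#' @param marker_name text, e.g. "centrin", "AcTub", "CEP290".
#' @param z_range length-2 numeric, axial window nm (`z_range[1] < z_range[2]`).
#' @param radial_kind one of the kinds above.
#' @param radial_params list with the fields the kind uses: `inner`,
#'   `outer`, `thickness`, `cluster_sigma` (all nm).
#' @param azimuthal_asymmetry von Mises concentration kappa (>= 0; 0 =
#'   azimuthally uniform).
#' @param emitter_density expected emitters per micrometer of axial extent.
#' @param labeling_efficiency fraction in `[0, 1]`.
#' @param photon_budget expected photons per emitter.
#' @return object of class `channel_model`.
#' @export
channel_model <- function(marker_name, z_range, radial_kind,
                          radial_params = list(),
                          azimuthal_asymmetry = 0,
                          emitter_density = 500,
                          labeling_efficiency = 1,
                          photon_budget = 1000) {
  radial_kind <- match.arg(radial_kind,
                           c("lumen_fill", "doublet_ring", "annulus",
                             "membrane_shell", "basal_patch"))
  stopifnot(length(z_range) == 2, z_range[1] < z_range[2],
            azimuthal_asymmetry >= 0, emitter_density >= 0,
            labeling_efficiency >= 0, labeling_efficiency <= 1,
            photon_budget > 0)
  if (radial_kind == "annulus") {
    stopifnot(!is.null(radial_params$inner), !is.null(radial_params$outer))
    if (radial_params$inner >= radial_params$outer)
      stop("annulus requires inner < outer radius")
  }
  structure(list(marker_name = marker_name, z_range = as.numeric(z_range),
                 radial_kind = radial_kind, radial_params = radial_params,
                 azimuthal_asymmetry = azimuthal_asymmetry,
                 emitter_density = emitter_density,
                 labeling_efficiency = labeling_efficiency,
                 photon_budget = photon_budget),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("<channel_model> %s: %s, z in [%g, %g] nm, density %g /um, kappa %g\n",
              x$marker_name, x$radial_kind, x$z_range[1], x$z_range[2],
              x$emitter_density, x$azimuthal_asymmetry))
  invisible(x)
}

# TEM cross-section diameters (nm) by genotype: axoneme ring and ciliary
# membrane, measured as the shortest of two perpendicular diameters.
.tem_diameters <- list(
  WT    = c(axoneme = 186.0, membrane = 261.1),
  rd16  = c(axoneme = 171.5, membrane = 245.8),
  NN    = c(axoneme = 171.6, membrane = 239.7),
  KO    = c(axoneme = 161.3, membrane = 217.3)
)

.preset_names <- c("WT_adult", "WT_P10", "rd16_P10", "NN_P10", "KO_P10", "hRPE1")

# Default connecting-cilium channel set for a given geometry. Structural
# radii anchor the radial laws; fluorescence-derived extents (CEP290
# annulus spanning ring..membrane) are label-position estimates.
.cc_channels <- function(geom, cep290 = TRUE) {
  ring <- geom$axoneme_ring_radius
  ch <- list(
    channel_model("centrin", c(0, min(1000, geom$cc_length)), "lumen_fill",
                  list(outer = geom$lumen_radius),
                  emitter_density = 800),
    channel_model("AcTub", c(0, geom$cc_length), "doublet_ring",
                  list(cluster_sigma = 12),
                  emitter_density = 800),
    channel_model("WGA", c(0, geom$cc_length), "membrane_shell",
                  list(outer = geom$membrane_radius, thickness = 20),
                  emitter_density = 600),
    channel_model("CEP164", c(-200, 0), "basal_patch",
                  list(outer = geom$membrane_radius + 40),
                  emitter_density = 2500),
    channel_model("NPHP8", c(0, 200), "annulus",
                  list(inner = ring, outer = geom$membrane_radius),
                  emitter_density = 1500)
  )
  if (cep290)
    ch <- append(ch, list(
      channel_model("CEP290", c(0, geom$cc_length), "annulus",
                    list(inner = ring, outer = geom$membrane_radius),
                    azimuthal_asymmetry = 2,
                    emitter_density = 600)), after = 2)
  ch
}

#' Genotype presets
#'
#' Returns a documented geometry plus default channel list for one of the
#' supported genotypes. Radii are half the TEM cross-section diameters of
#' the corresponding genotype; the adult wild type reuses the wild-type
#' TEM radii with the ~1100 nm adult connecting-cilium length. P10 mutant
#' lengths follow the measured shortening (rd16 and KO significantly
#' shorter than wild type, NN not). The `hRPE1` preset models an
#' epithelial primary cilium: centrin restricted to the basal body, a
#' ~200 nm CEP290 basal patch at the cilium base, NPHP8/MKS3 in the
#' distal transition zone, and an axoneme extending microns distally.
#'
#' @param name one of `"WT_adult"`, `"WT_P10"`, `"rd16_P10"`, `"NN_P10"`,
#'   `"KO_P10"`, `"hRPE1"`.
#' @return list with elements `geometry` (a [cilium_geometry]) and
#'   `channels` (list of [channel_model]).
#' @examples
#' p <- genotype_preset("WT_adult")
#' p$geometry$axoneme_ring_radius  # 93 nm, half the 186 nm TEM diameter
#' @export
genotype_preset <- function(name) {
  if (length(name) != 1 || !name %in% .preset_names)
    stop("unknown preset '", paste(name, collapse = ","),
         "'; supported presets: ", paste(.preset_names, collapse = ", "))
  geno <- switch(name, WT_adult = "WT", WT_P10 = "WT", rd16_P10 = "rd16",
                 NN_P10 = "NN", KO_P10 = "KO", hRPE1 = "WT")
  d <- .tem_diameters[[geno]]
  ring <- d[["axoneme"]] / 2
  memb <- d[["membrane"]] / 2
  lumen <- ring - 30  # doublet footprint: lumen boundary ~30 nm inside ring
  if (name == "hRPE1") {
    geom <- cilium_geometry(cc_length = 2500, membrane_radius = memb,
                            axoneme_ring_radius = ring, lumen_radius = lumen,
                            genotype_label = "hRPE1")
    channels <- list(
      # basal body marker: centrin is not axonemal in hRPE-1 cells
      channel_model("centrin", c(-450, -80), "basal_patch",
                    list(outer = memb), emitter_density = 1500),
      channel_model("AcTub", c(0, geom$cc_length), "doublet_ring",
                    list(cluster_sigma = 12), emitter_density = 800),
      # CEP290 basal patch ~200 nm long, ending ~64 nm distal to centrin
      channel_model("CEP290", c(-216, -16), "basal_patch",
                    list(outer = memb), emitter_density = 1500),
      channel_model("CEP164", c(-300, -100), "basal_patch",
                    list(outer = memb + 60), emitter_density = 2000),
      channel_model("NPHP8", c(0, 300), "annulus",
                    list(inner = ring, outer = memb), emitter_density = 1200),
      channel_model("MKS3", c(0, 300), "membrane_shell",
                    list(outer = memb, thickness = 20), emitter_density = 1200)
    )
    return(list(geometry = geom, channels = channels))
  }
  len <- switch(name,
                WT_adult = 1100,
                WT_P10 = 1000,
                rd16_P10 = 820,   # scaled by the measured rd16/WT shortening
                NN_P10 = 1000,    # no significant length difference vs WT
                KO_P10 = 820)
  geom <- cilium_geometry(cc_length = len, membrane_radius = memb,
                          axoneme_ring_radius = ring, lumen_radius = lumen,
                          genotype_label = name)
  channels <- .cc_channels(geom, cep290 = !name %in% c("NN_P10", "KO_P10"))
  if (name == "WT_adult")
    channels[[1]]$z_range <- c(0, 1000)  # centrin calibrates axoneme length
  list(geometry = geom, channels = channels)
}
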