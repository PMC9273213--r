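#' Parameters of the synthetic scene generator
#'
#' Returns a validated parameter list describing the simulated assay: fields
#' of HeLa-like cells carrying a nucleus, a mitochondrial filament network, a
#' compact perinuclear Golgi-like compartment, a transfection marker with
#' lognormal expression and an untransfected subpopulation, and a reporter
#' whose photon mass is split between the mitochondrial and the Golgi
#' compartments by the mislocalized fraction `theta`.
#'
#' Defaults emulate the real acquisition the generator stands in for: 512x512
#' EMCCD fields, 15 fields per condition with 3-4 cells each (around 50 cells
#' per condition in total), smooth additive background, Poisson shot noise and
#' Gaussian read noise.
#'
#' @param image_height,image_width Field size in pixels (>= 64).
#' @param n_cells_per_field Cells placed per field.
#' @param n_fields Fields generated per condition.
#' @param nucleus_radius_range,cell_radius_range Min/max radius in pixels.
#' @param mito_filament_count Filaments per cell.
#' @param mito_filament_length Random-walk steps per filament.
#' @param mito_filament_width Filament thickness in pixels (rendered by
#'   dilating the walk trace).
#' @param golgi_arc_params List with `thickness` (radial extent, px) and
#'   `angle_deg` (angular width of the perinuclear arc).
#' @param misloc_fraction Mislocalized fraction theta in \[0, 1\]: the fraction
#'   of per-cell reporter photon mass placed on the mitochondrial mask; the
#'   remainder goes to the Golgi mask.
#' @param transfected_prob Probability that a cell expresses the marker.
#' @param marker_lognormal_mu,marker_lognormal_sigma Meanlog/sdlog of the
#'   per-pixel marker expression level of transfected cells.
#' @param theta_expression_slope When nonzero, couples a transfected cell's
#'   mislocalized fraction to its expression level on the logit scale:
#'   `theta_i = plogis(qlogis(theta) + slope * z_i)` with `z_i` the z-score of
#'   log expression. 0 (default) keeps theta identical for every cell.
#' @param reporter_total Total reporter photon mass per cell (counts).
#' @param nuclei_amplitude,mito_amplitude Per-pixel signal amplitude of the
#'   nuclear stain and the mitochondrial stain (counts).
#' @param background_plane_coeffs Numeric `c(b0, bx, by)`: additive background
#'   `b0 + bx * (col-1)/(ncol-1) + by * (row-1)/(nrow-1)`, same for every
#'   channel.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param shot_noise Apply Poisson shot noise?
#' @param n_z Number of z-planes; planes repeat the scene with independent
#'   noise.
#' @param seed Integer master seed; field i uses a derived sub-seed.
#' @param ... Override any default by name.
#'
#' @return A list of class `"synth_params"`.
#' @export
#' @examples
#' p <- synth_params(n_fields = 2, n_cells_per_field = 3, seed = 7)
#' p$misloc_fraction
synth_params <- function(image_height = 512L,
                         image_width = 512L,
                         n_cells_per_field = 3L,
                         n_fields = 15L,
                         nucleus_radius_range = c(12, 18),
                         cell_radius_range = c(38, 55),
                         mito_filament_count = 12L,
                         mito_filament_length = 70L,
                         mito_filament_width = 3,
                         golgi_arc_params = list(thickness = 8, angle_deg = 120),
                         misloc_fraction = 0.3,
                         transfected_prob = 0.7,
                         marker_lognormal_mu = log(300),
                         marker_lognormal_sigma = 0.8,
                         theta_expression_slope = 0,
                         reporter_total = 6e5,
                         nuclei_amplitude = 600,
                         mito_amplitude = 500,
                         background_plane_coeffs = c(100, 20, 10),
                         read_noise_sd = 5,
                         shot_noise = TRUE,
                         n_z = 1L,
                         seed = 1L,
                         ...) {
  p <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_cells_per_field = as.integer(n_cells_per_field),
    n_fields = as.integer(n_fields),
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    cell_radius_range = as.numeric(cell_radius_range),
    mito_filament_count = as.integer(mito_filament_count),
    mito_filament_length = as.integer(mito_filament_length),
    mito_filament_width = as.numeric(mito_filament_width),
    golgi_arc_params = golgi_arc_params,
    misloc_fraction = as.numeric(misloc_fraction),
    transfected_prob = as.numeric(transfected_prob),
    marker_lognormal_mu = as.numeric(marker_lognormal_mu),
    marker_lognormal_sigma = as.numeric(marker_lognormal_sigma),
    theta_expression_slope = as.numeric(theta_expression_slope),
    reporter_total = as.numeric(reporter_total),
    nuclei_amplitude = as.numeric(nuclei_amplitude),
    mito_amplitude = as.numeric(mito_amplitude),
    background_plane_coeffs = as.numeric(background_plane_coeffs),
    read_noise_sd = as.numeric(read_noise_sd),
    shot_noise = isTRUE(shot_noise),
    n_z = as.integer(n_z),
    seed = as.integer(seed)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      abort(paste0("unknown synth_params field(s): ",
                   paste(unknown, collapse = ", ")),
            class = "mitoloc_param_error")
    p[names(dots)] <- dots
  }
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "mitoloc_param_error")
  chk(p$image_height >= 64 && p$image_width >= 64,
      "image dimensions must be >= 64 pixels")
  chk(p$misloc_fraction >= 0 && p$misloc_fraction <= 1,
      "misloc_fraction (theta) must lie in [0, 1]")
  chk(p$transfected_prob >= 0 && p$transfected_prob <= 1,
      "transfected_prob must lie in [0, 1]")
  chk(length(p$nucleus_radius_range) == 2 && all(p$nucleus_radius_range > 0) &&
        diff(p$nucleus_radius_range) >= 0,
      "nucleus_radius_range must be two positive increasing values")
  chk(length(p$cell_radius_range) == 2 && all(p$cell_radius_range > 0) &&
        diff(p$cell_radius_range) >= 0,
      "cell_radius_range must be two positive increasing values")
  chk(min(p$cell_radius_range) > max(p$nucleus_radius_range),
      "cell radii must exceed nucleus radii")
  chk(p$mito_filament_count > 0 && p$mito_filament_length > 0 &&
        p$mito_filament_width > 0,
      "mitochondrial filament parameters must be positive")
  chk(is.list(p$golgi_arc_params) &&
        all(c("thickness", "angle_deg") %in% names(p$golgi_arc_params)) &&
        p$golgi_arc_params$thickness > 0 && p$golgi_arc_params$angle_deg > 0,
      "golgi_arc_params needs positive thickness and angle_deg")
  chk(p$n_cells_per_field >= 0 && p$n_fields >= 0,
      "cell and field counts must be nonnegative")
  chk(p$read_noise_sd >= 0, "read_noise_sd must be >= 0")
  chk(p$reporter_total > 0 && p$nuclei_amplitude > 0 && p$mito_amplitude > 0,
      "signal amplitudes must be positive")
  chk(length(p$background_plane_coeffs) == 3,
      "background_plane_coeffs must be c(b0, bx, by)")
  chk(p$n_z >= 1, "n_z must be >= 1")
  invisible(p)
}

#' Parameters of the segmentation and gating stages
#'
#' @param nucleus_threshold `"otsu"` or a fixed numeric threshold for the
#'   nuclei channel.
#' @param nucleus_min_area,nucleus_max_area Area gate (px) for nucleus labels.
#' @param declump Split touching nuclei by distance-transform watershed?
#' @param lambda Propagation regularization (>= 0): weight of the Euclidean
#'   step length against the normalized image gradient in the propagation
#'   cost.
#' @param guidance Channel role guiding cell-body propagation.
#' @param guidance_threshold `"otsu"` or fixed threshold defining the
#'   propagation foreground on the guidance channel.
#' @param guidance_close_radius Radius (px) of the closing applied to the
#'   thresholded guidance foreground before propagation, bridging the gaps of
#'   the filamentous mitochondrial stain into a solid cytoplasm proxy.
#' @param guidance_grow_px Dilation (px) applied to the closed guidance
#'   foreground: the mitochondrial network stops short of the plasma
#'   membrane, so the cytoplasm proxy is padded outward by a few pixels.
#' @param mito_threshold `"otsu"` or fixed threshold for the mitochondria
#'   channel when building the pseudo-cell mask.
#' @param closing_radius Radius (px) of the closing that bridges gaps in the
#'   thresholded mitochondrial network ("closing all gaps").
#' @param marker_gate Integrated-intensity threshold above which a cell counts
#'   as transfected. No numeric default: either a number chosen by inspecting
#'   [suggest_marker_gate()]/the intensity histogram, or the string
#'   `"suggest"` to derive one automatically from the pooled per-cell
#'   integrated intensities.
#' @param min_pixels Minimum measurement pixels for a defined per-cell PCC.
#'
#' @return A list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(nucleus_threshold = "otsu",
                                nucleus_min_area = 80,
                                nucleus_max_area = 4000,
                                declump = FALSE,
                                lambda = 0.05,
                                guidance = "mito",
                                guidance_threshold = "otsu",
                                guidance_close_radius = 10,
                                guidance_grow_px = 5,
                                mito_threshold = "otsu",
                                closing_radius = 10,
                                marker_gate = "suggest",
                                min_pixels = 50) {
  p <- list(nucleus_threshold = nucleus_threshold,
            nucleus_min_area = nucleus_min_area,
            nucleus_max_area = nucleus_max_area,
            declump = isTRUE(declump),
            lambda = lambda,
            guidance = guidance,
            guidance_threshold = guidance_threshold,
            guidance_close_radius = guidance_close_radius,
            guidance_grow_px = guidance_grow_px,
            mito_threshold = mito_threshold,
            closing_radius = closing_radius,
            marker_gate = marker_gate,
            min_pixels = min_pixels)
  chk <- function(ok, msg) if (!ok) abort(msg, class = "mitoloc_param_error")
  chk(p$lambda >= 0, "lambda must be >= 0")
  chk(p$nucleus_min_area > 0 && p$nucleus_max_area >= p$nucleus_min_area,
      "nucleus area gate must be positive and increasing")
  chk(is.numeric(p$marker_gate) || identical(p$marker_gate, "suggest"),
      "marker_gate must be a numeric threshold or \"suggest\"")
  if (is.numeric(p$marker_gate))
    chk(p$marker_gate >= 0, "marker_gate must be >= 0")
  chk(p$min_pixels >= 2, "min_pixels must be >= 2")
  chk(p$guidance %in% c("nuclei", "reporter", "marker", "mito"),
      "guidance must name a channel role")
  structure(p, class = "segmentation_params")
}

#' Derive the deterministic sub-seed of field `i`
#'
#' Mixes the master seed and the field index so fields are reproducible
#' individually (and in parallel) while remaining inside 32-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param i Field index (1-based).
#' @return An integer seed.
#' @export
derive_subseed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 69069 + as.numeric(i) * 40503 + 12345) %%
               2147483647)
}
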