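## Synthetic 4-channel fluorescence scenes with per-cell ground truth.
##
## A scene emulates the live-cell mislocalization assay: Hoechst-stained
## nuclei, an EGFP reporter split between a perinuclear Golgi-like arc and the
## mitochondrial network according to the mislocalized fraction theta, a
## transiently expressed marker filling transfected cells, and a MitoTracker
## channel. Pixel indices in truths are 1-based linear indices into the
## [row, col] field matrix.

disk_px <- function(center, radius, dim) {
  r0 <- center[1]; c0 <- center[2]
  rows <- max(1L, floor(r0 - radius)):min(dim[1], ceiling(r0 + radius))
  cols <- max(1L, floor(c0 - radius)):min(dim[2], ceiling(c0 + radius))
  rr <- outer(rows - r0, rep(1, length(cols)))
  cc <- outer(rep(1, length(rows)), cols - c0)
  sel <- which(rr^2 + cc^2 <= radius^2)
  ri <- rows[((sel - 1) %% length(rows)) + 1]
  ci <- cols[((sel - 1) %/% length(rows)) + 1]
  (ci - 1L) * dim[1] + ri
}

mask_from_px <- function(px, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[px] <- TRUE
  m
}

#' Sample the geometry and ground truth of one synthetic cell
#'
#' Places a circular cell (rejection sampling against `occupied`), an interior
#' nucleus, a compact perinuclear Golgi-like arc, and a mitochondrial network
#' rendered as dilated correlated random-walk filaments confined to the
#' cytoplasm and kept disjoint from the Golgi arc. Draws from the current RNG
#' state; callers control reproducibility with a seed.
#'
#' @param params A [synth_params()] object.
#' @param occupied Optional logical matrix of pixels already taken by other
#'   cells (plus a safety margin); the new cell avoids them.
#' @param cell_id Integer id recorded in the truth.
#' @param max_attempts Placement attempts before a structured error
#'   (`mitoloc_placement_error`) is raised for a crowded field.
#'
#' @return A `scene_truth` list: `cell_id`, centers/radii, pixel-index sets
#'   `nucleus_px`, `cell_px`, `mito_px`, `golgi_px` (linear indices), `theta`,
#'   `expression_level`, `transfected`.
#' @export
sample_cell_geometry <- function(params, occupied = NULL, cell_id = 1L,
                                 max_attempts = 200L) {
  validate_synth_params(params)
  dim <- c(params$image_height, params$image_width)
  if (is.null(occupied)) occupied <- matrix(FALSE, dim[1], dim[2])

  placed <- FALSE
  for (attempt in seq_len(max_attempts)) {
    rc <- runif(1, params$cell_radius_range[1], params$cell_radius_range[2])
    if (2 * rc + 4 > min(dim))
      abort("cell radius does not fit the field", class = "mitoloc_param_error")
    r0 <- runif(1, rc + 2, dim[1] - rc - 2)
    c0 <- runif(1, rc + 2, dim[2] - rc - 2)
    cell_px <- disk_px(c(r0, c0), rc, dim)
    if (!any(occupied[cell_px])) { placed <- TRUE; break }
  }
  if (!placed)
    abort(sprintf(
      "could not place cell %d after %d attempts: field too crowded",
      cell_id, max_attempts), class = "mitoloc_placement_error")

  rn <- runif(1, params$nucleus_radius_range[1], params$nucleus_radius_range[2])
  max_off <- max(0, 0.2 * rc - 1)
  off_ang <- runif(1, 0, 2 * pi)
  off <- min(max_off, rc - rn - 3) * c(cos(off_ang), sin(off_ang))
  ncen <- c(r0, c0) + off
  nucleus_px <- disk_px(ncen, rn, dim)

  ## Golgi: radial band just outside the nucleus, limited angular width
  g <- params$golgi_arc_params
  ang0 <- runif(1, 0, 2 * pi)
  half <- (g$angle_deg / 2) * pi / 180
  band <- c(rn + 1, rn + 1 + g$thickness)
  gpx <- disk_px(ncen, band[2], dim)
  ri <- ((gpx - 1L) %% dim[1]) + 1L
  ci <- ((gpx - 1L) %/% dim[1]) + 1L
  d <- sqrt((ri - ncen[1])^2 + (ci - ncen[2])^2)
  a <- atan2(ci - ncen[2], ri - ncen[1])
  dang <- abs(((a - ang0 + pi) %% (2 * pi)) - pi)
  golgi_px <- gpx[d >= band[1] & d <= band[2] & dang <= half]
  golgi_px <- intersect(golgi_px, setdiff(cell_px, nucleus_px))

  ## Mitochondrial network: correlated random walks from the nucleus rim,
  ## confined to the cytoplasm, then dilated to filament width
  trace <- matrix(FALSE, dim[1], dim[2])
  for (f in seq_len(params$mito_filament_count)) {
    ang <- runif(1, 0, 2 * pi)
    pos <- ncen + (rn + 2) * c(cos(ang), sin(ang))
    phi <- ang  # initial heading: outward
    for (s in seq_len(params$mito_filament_length)) {
      phi <- phi + rnorm(1, 0, 0.45)
      cand <- pos + c(cos(phi), sin(phi))
      dcell <- sqrt(sum((cand - c(r0, c0))^2))
      dnuc <- sqrt(sum((cand - ncen)^2))
      if (dcell > rc - 1.5 || dnuc < rn + 1) {
        phi <- phi + pi / 2 + runif(1, 0, pi)  # bounce off the boundary
        next
      }
      pos <- cand
      rr <- round(pos[1]); cc <- round(pos[2])
      if (rr >= 1 && rr <= dim[1] && cc >= 1 && cc <= dim[2])
        trace[rr, cc] <- TRUE
    }
  }
  dil_r <- max(1L, floor(params$mito_filament_width / 2))
  brush <- EBImage::makeBrush(2L * dil_r + 1L, shape = "disc")
  ## dilate on the cell bounding box only
  rows <- max(1L, floor(r0 - rc)):min(dim[1], ceiling(r0 + rc))
  cols <- max(1L, floor(c0 - rc)):min(dim[2], ceiling(c0 + rc))
  sub <- EBImage::dilate(trace[rows, cols, drop = FALSE] * 1, brush) > 0
  mito <- matrix(FALSE, dim[1], dim[2])
  mito[rows, cols] <- sub
  mito_px <- which(mito)
  mito_px <- intersect(mito_px, setdiff(cell_px, nucleus_px))
  mito_px <- setdiff(mito_px, golgi_px)

  expr_raw <- rlnorm(1, params$marker_lognormal_mu, params$marker_lognormal_sigma)
  transfected <- runif(1) < params$transfected_prob
  theta <- params$misloc_fraction
  if (params$theta_expression_slope != 0) {
    z <- (log(expr_raw) - params$marker_lognormal_mu) /
      params$marker_lognormal_sigma
    base <- min(max(theta, 1e-3), 1 - 1e-3)
    theta <- stats::plogis(stats::qlogis(base) +
                             params$theta_expression_slope * z)
  }

  structure(list(
    cell_id = as.integer(cell_id),
    center = c(r0, c0), cell_radius = rc,
    nucleus_center = ncen, nucleus_radius = rn,
    cell_px = cell_px, nucleus_px = nucleus_px,
    mito_px = mito_px, golgi_px = golgi_px,
    theta = theta,
    expression_level = if (transfected) expr_raw else 0,
    transfected = transfected
  ), class = "scene_truth")
}

place_field_cells <- function(params) {
  dim <- c(params$image_height, params$image_width)
  occupied <- matrix(FALSE, dim[1], dim[2])
  truths <- vector("list", params$n_cells_per_field)
  for (k in seq_len(params$n_cells_per_field)) {
    tr <- sample_cell_geometry(params, occupied, cell_id = k)
    ## margin keeps neighboring cells from touching
    occupied[disk_px(tr$center, tr$cell_radius + 3, dim)] <- TRUE
    truths[[k]] <- tr
  }
  truths
}

background_plane <- function(params) {
  h <- params$image_height; w <- params$image_width
  b <- params$background_plane_coeffs
  xs <- if (w > 1) (seq_len(w) - 1) / (w - 1) else 0
  ys <- if (h > 1) (seq_len(h) - 1) / (h - 1) else 0
  b[1] + outer(rep(1, h), xs) * b[2] + outer(ys, rep(1, w)) * b[3]
}

#' Render a field's four channels from per-cell ground truth
#'
#' Noise-free signal: nuclei = nuclear stain amplitude on nucleus masks;
#' mito = mitochondrial stain amplitude on mito masks; marker = expression
#' level filling the cell mask of transfected cells; reporter = per-cell
#' photon mass `reporter_total` split as `theta` on the mito mask and
#' `1 - theta` on the Golgi mask (uniform within each compartment). A smooth
#' background plane is added, then Poisson shot noise (if enabled) and
#' Gaussian read noise; noisy images are digitized to integer counts and
#' clipped at 0. With all noise off the returned values are exact.
#'
#' @param truths List of `scene_truth` objects with mutually disjoint cells.
#' @param params A [synth_params()] object.
#' @param field_id,condition Labels stored in the result.
#' @return A `field_stack`: `channels` (named list nuclei/reporter/marker/mito
#'   of matrices, or `height x width x n_z` arrays when `params$n_z > 1`),
#'   `field_id`, `condition`.
#' @export
render_field <- function(truths, params, field_id = "f01", condition = "cond") {
  validate_synth_params(params)
  dim <- c(params$image_height, params$image_width)
  zero <- matrix(0, dim[1], dim[2])
  sig <- list(nuclei = zero, reporter = zero, marker = zero, mito = zero)

  all_cell <- unlist(lapply(truths, `[[`, "cell_px"))
  if (anyDuplicated(all_cell))
    abort("cell masks of distinct cells must be disjoint",
          class = "mitoloc_param_error")

  for (tr in truths) {
    sig$nuclei[tr$nucleus_px] <- sig$nuclei[tr$nucleus_px] + params$nuclei_amplitude
    sig$mito[tr$mito_px] <- sig$mito[tr$mito_px] + params$mito_amplitude
    if (tr$transfected)
      sig$marker[tr$cell_px] <- sig$marker[tr$cell_px] + tr$expression_level
    M <- params$reporter_total
    if (tr$theta > 0 && length(tr$mito_px))
      sig$reporter[tr$mito_px] <- sig$reporter[tr$mito_px] +
        tr$theta * M / length(tr$mito_px)
    if (tr$theta < 1 && length(tr$golgi_px))
      sig$reporter[tr$golgi_px] <- sig$reporter[tr$golgi_px] +
        (1 - tr$theta) * M / length(tr$golgi_px)
  }

  bg <- background_plane(params)
  noisy <- params$shot_noise || params$read_noise_sd > 0
  channels <- lapply(sig, function(s) {
    planes <- lapply(seq_len(params$n_z), function(z) {
      img <- s + bg
      if (params$shot_noise)
        img <- matrix(rpois(length(img), lambda = img), dim[1], dim[2])
      if (params$read_noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, params$read_noise_sd),
                            dim[1], dim[2])
      if (noisy) img <- round(img)  # EMCCD-style integer digitization
      pmax(img, 0)
    })
    if (params$n_z == 1L) planes[[1]]
    else array(unlist(planes), dim = c(dim, params$n_z))
  })

  structure(list(channels = channels, field_id = field_id,
                 condition = condition),
            class = "field_stack")
}

#' Generate all fields of one synthetic condition
#'
#' Produces `params$n_fields` fields; field `i` is generated under the
#' deterministic sub-seed [derive_subseed()]`(params$seed, i)`, so identical
#' parameters yield byte-identical output and fields are independently
#' reproducible.
#'
#' @param params A [synth_params()] object.
#' @param condition_name Condition label recorded in fields and manifest.
#' @return A list with `fields` (list of `field_stack`), `truths` (list of
#'   per-field `scene_truth` lists) and `manifest` (parameters, sub-seeds,
#'   total cell count).
#' @export
#' @examples
#' cond <- generate_condition(synth_params(
#'   image_height = 128, image_width = 128, n_fields = 1,
#'   n_cells_per_field = 2, cell_radius_range = c(25, 30),
#'   nucleus_radius_range = c(8, 10), seed = 3), "demo")
#' length(cond$truths[[1]])
generate_condition <- function(params, condition_name = "condition") {
  validate_synth_params(params)
  n <- params$n_fields
  fields <- vector("list", n)
  truths <- vector("list", n)
  subseeds <- integer(n)
  for (i in seq_len(n)) {
    subseeds[i] <- derive_subseed(params$seed, i)
    fid <- sprintf("%s_f%02d", condition_name, i)
    res <- withr::with_seed(subseeds[i], {
      tr <- tryCatch(place_field_cells(params),
                     mitoloc_placement_error = function(e)
                       abort(paste0(conditionMessage(e), " (field ", fid, ")"),
                             class = "mitoloc_placement_error"))
      list(truths = tr,
           field = render_field(tr, params, field_id = fid,
                                condition = condition_name))
    })
    fields[[i]] <- res$field
    truths[[i]] <- res$truths
  }
  manifest <- list(
    condition = condition_name,
    generated = "mitoloc synthetic scene generator",
    package_version = as.character(utils::packageVersion("mitoloc")),
    params = unclass(params),
    subseeds = subseeds,
    n_cells_total = sum(vapply(truths, length, 1L))
  )
  list(fields = fields, truths = truths, manifest = manifest)
}

#' Ground-truth label masks of one field
#'
#' @param truths List of `scene_truth` for one field.
#' @param dim `c(height, width)` of the field.
#' @return Named list of integer label matrices (`nuclei`, `cell`, `mito`,
#'   `golgi`), labels = `cell_id`.
#' @export
truth_label_masks <- function(truths, dim) {
  out <- list(nuclei = matrix(0L, dim[1], dim[2]),
              cell = matrix(0L, dim[1], dim[2]),
              mito = matrix(0L, dim[1], dim[2]),
              golgi = matrix(0L, dim[1], dim[2]))
  for (tr in truths) {
    out$nuclei[tr$nucleus_px] <- tr$cell_id
    out$cell[tr$cell_px] <- tr$cell_id
    out$mito[tr$mito_px] <- tr$cell_id
    out$golgi[tr$golgi_px] <- tr$cell_id
  }
  out
}
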