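## Segmentation: nuclei -> propagated cell bodies -> transfection gate ->
## mitochondria-derived pseudo-cell measurement mask.

auto_threshold <- function(image, spec) {
  if (is.numeric(spec)) return(spec)
  if (!identical(spec, "otsu"))
    abort("threshold must be numeric or \"otsu\"", class = "mitoloc_param_error")
  rng <- range(image)
  if (diff(rng) == 0) return(rng[2])  # blank image: nothing passes '>'
  EBImage::otsu(image, range = rng)
}

#' Summary table of a label mask
#'
#' @param labels Integer label matrix (0 = background).
#' @return A tibble with `label`, `area` (px) and centroid (`centroid_r`,
#'   `centroid_c`).
#' @export
label_table <- function(labels) {
  idx <- which(labels > 0)
  if (!length(idx))
    return(tibble(label = integer(), area = integer(),
                  centroid_r = numeric(), centroid_c = numeric()))
  lab <- labels[idx]
  ri <- ((idx - 1L) %% nrow(labels)) + 1L
  ci <- ((idx - 1L) %/% nrow(labels)) + 1L
  tibble(
    label = sort(unique(lab)),
    area = as.integer(tapply(lab, lab, length)),
    centroid_r = as.numeric(tapply(ri, lab, mean)),
    centroid_c = as.numeric(tapply(ci, lab, mean))
  )
}

#' Segment nuclei
#'
#' Thresholds the (background-corrected) nuclear stain, fills holes, labels
#' connected components, optionally declumps touching nuclei by
#' distance-transform watershed, and removes labels outside the area gate.
#' Labels are relabeled 1..K in scan order. A blank image yields zero labels.
#'
#' @param nuclei_image Background-corrected nuclei channel.
#' @param params A [segmentation_params()] object.
#' @return Integer label matrix.
#' @export
segment_nuclei <- function(nuclei_image, params = segmentation_params()) {
  th <- auto_threshold(nuclei_image, params$nucleus_threshold)
  mask <- nuclei_image > th
  if (!any(mask)) return(matrix(0L, nrow(nuclei_image), ncol(nuclei_image)))
  mask <- EBImage::fillHull(mask * 1) > 0
  if (params$declump) {
    dm <- EBImage::distmap(mask * 1)
    labels <- EBImage::watershed(dm, tolerance = 1)
  } else {
    labels <- EBImage::bwlabel(mask * 1)
  }
  labels <- matrix(as.integer(labels), nrow(nuclei_image))
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= params$nucleus_min_area & tab <= params$nucleus_max_area)
  relabel <- integer(length(tab))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- relabel[labels[pos]]
  out
}

#' Propagate cell-body masks from nucleus seeds
#'
#' Defines the propagation foreground by thresholding the guidance channel
#' (closing and hole-filling it with `guidance_close_radius` so a filamentous
#' stain such as MitoTracker becomes a solid cytoplasm proxy), then assigns
#' every foreground pixel to the seed with the smallest accumulated cost
#' `|dI| + lambda * step` along an 8-connected path, where `dI` is the
#' intensity difference on the guidance image normalized to \[0, 1\]. Every
#' cell mask contains its seed nucleus; masks are disjoint; equal-cost ties go
#' to the lower seed label.
#'
#' @param nuclei_labels Integer seed label matrix (from [segment_nuclei()]).
#' @param guidance_image Background-corrected guidance channel, same shape.
#' @param params A [segmentation_params()] object (`lambda`,
#'   `guidance_threshold`, `guidance_close_radius`).
#' @return Integer cell label matrix (labels match the seeds).
#' @export
propagate_cell_masks <- function(nuclei_labels, guidance_image,
                                 params = segmentation_params()) {
  if (!all(dim(nuclei_labels) == dim(guidance_image)))
    abort(sprintf("shape mismatch: seeds %s vs guidance %s",
                  paste(dim(nuclei_labels), collapse = "x"),
                  paste(dim(guidance_image), collapse = "x")),
          class = "mitoloc_input_error")
  if (!any(nuclei_labels > 0))
    return(matrix(0L, nrow(nuclei_labels), ncol(nuclei_labels)))

  th <- auto_threshold(guidance_image, params$guidance_threshold)
  fg <- guidance_image > th
  r <- params$guidance_close_radius
  if (r > 0 && any(fg)) {
    fg <- EBImage::closing(fg * 1, EBImage::makeBrush(2L * as.integer(r) + 1L,
                                                      "disc")) > 0
    fg <- EBImage::fillHull(fg * 1) > 0
  }
  g <- as.integer(params$guidance_grow_px %||% 0)
  if (g > 0 && any(fg))
    fg <- EBImage::dilate(fg * 1, EBImage::makeBrush(2L * g + 1L, "disc")) > 0
  fg <- fg | nuclei_labels > 0

  rng <- range(guidance_image)
  norm <- if (diff(rng) > 0) (guidance_image - rng[1]) / diff(rng)
          else guidance_image * 0
  .propagate_labels(matrix(as.integer(nuclei_labels), nrow(nuclei_labels)),
                    matrix(as.integer(fg), nrow(fg)),
                    norm, params$lambda)
}

#' Gate transfected cells on integrated marker intensity
#'
#' Integrated intensity is the sum of marker pixels within each cell label
#' (the expression-level proxy); cells whose sum exceeds the threshold are
#' selected.
#'
#' @param cell_labels Integer cell label matrix.
#' @param marker_image Background-corrected marker channel, same shape.
#' @param threshold Integrated-intensity threshold (>= 0), normally the
#'   "manually chosen" gate; see [suggest_marker_gate()].
#' @return List with `selected` (integer labels passing the gate) and
#'   `integrated` (named numeric, every label's integrated intensity).
#' @export
gate_transfected <- function(cell_labels, marker_image, threshold) {
  if (!all(dim(cell_labels) == dim(marker_image)))
    abort("cell_labels and marker_image must share one shape",
          class = "mitoloc_input_error")
  if (!is.numeric(threshold) || threshold < 0)
    abort("marker gate threshold must be >= 0", class = "mitoloc_param_error")
  idx <- which(cell_labels > 0)
  labs <- sort(unique(cell_labels[idx]))
  if (!length(labs))
    return(list(selected = integer(), integrated = stats::setNames(numeric(0),
                                                                   character(0))))
  sums <- vapply(labs, function(l) sum(marker_image[cell_labels == l]), 0)
  names(sums) <- labs
  list(selected = labs[sums > threshold], integrated = sums)
}

#' Suggest a transfection gate from pooled integrated intensities
#'
#' The assay's gate is chosen manually from the intensity histogram; this
#' helper automates that choice for unattended runs by applying Otsu's
#' threshold to `log1p` of the pooled per-cell integrated marker intensities
#' (which are strongly bimodal when an untransfected subpopulation exists).
#'
#' @param integrated Numeric vector of per-cell integrated intensities,
#'   pooled across fields/conditions.
#' @return A threshold in integrated-intensity units.
#' @export
suggest_marker_gate <- function(integrated) {
  x <- log1p(integrated[is.finite(integrated)])
  if (length(x) < 2 || diff(range(x)) == 0)
    abort("need a spread of integrated intensities to suggest a gate",
          class = "mitoloc_input_error")
  ## Otsu on the 1-d histogram of log intensities
  br <- seq(min(x), max(x), length.out = 257)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; cut <- mids[1]
  csum <- cumsum(w); cmean <- cumsum(w * mids); mu <- sum(w * mids)
  for (k in seq_len(length(mids) - 1)) {
    w0 <- csum[k]; w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- cmean[k] / w0; m1 <- (mu - cmean[k]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; cut <- (mids[k] + mids[k + 1]) / 2 }
  }
  expm1(cut)
}

#' Mitochondria-derived pseudo-cell measurement mask
#'
#' Within each selected cell label the mitochondria channel is thresholded,
#' morphologically closed (bridging inter-filament gaps) and hole-filled,
#' yielding one solid measurement region per cell, restricted to its parent
#' cell mask. Cells with no mitochondrial signal are flagged, not fatal.
#'
#' @param mito_image Background-corrected mitochondria channel.
#' @param cell_labels Integer cell label matrix, same shape.
#' @param selected Labels to process (default: all).
#' @param params A [segmentation_params()] object (`mito_threshold`,
#'   `closing_radius`).
#' @return List with `mask` (integer label matrix) and `no_mito_mask`
#'   (integer vector of labels lacking mitochondrial signal).
#' @export
make_pseudo_cell_mask <- function(mito_image, cell_labels,
                                  selected = NULL,
                                  params = segmentation_params()) {
  if (!all(dim(mito_image) == dim(cell_labels)))
    abort("mito_image and cell_labels must share one shape",
          class = "mitoloc_input_error")
  if (is.null(selected)) selected <- setdiff(sort(unique(as.vector(cell_labels))), 0L)
  th <- auto_threshold(mito_image, params$mito_threshold)
  fg <- mito_image > th
  out <- matrix(0L, nrow(mito_image), ncol(mito_image))
  missing <- integer(0)
  r <- as.integer(params$closing_radius)
  brush <- EBImage::makeBrush(2L * r + 1L, "disc")
  nr <- nrow(mito_image); nc <- ncol(mito_image)
  for (l in selected) {
    idx <- which(cell_labels == l)
    if (!length(idx)) { missing <- c(missing, l); next }
    cellfg <- idx[fg[idx]]
    if (!length(cellfg)) { missing <- c(missing, l); next }
    ri <- ((idx - 1L) %% nr) + 1L
    ci <- ((idx - 1L) %/% nr) + 1L
    rows <- min(ri):max(ri)
    cols <- min(ci):max(ci)
    ## zero-pad by the brush radius so closing sees empty space, not the
    ## image border, around the cell
    pad <- r + 1L
    sub <- matrix(FALSE, length(rows) + 2L * pad, length(cols) + 2L * pad)
    fri <- ((cellfg - 1L) %% nr) + 1L
    fci <- ((cellfg - 1L) %/% nr) + 1L
    sub[cbind(match(fri, rows) + pad, match(fci, cols) + pad)] <- TRUE
    closed <- EBImage::closing(sub * 1, brush)
    solid <- EBImage::fillHull(closed) > 0
    solid <- solid[pad + seq_along(rows), pad + seq_along(cols), drop = FALSE]
    solid_idx <- (rep(cols, each = length(rows)) - 1L) * nr +
      rep(rows, times = length(cols))
    take <- solid_idx[as.vector(solid)]
    take <- take[cell_labels[take] == l]  # restrict to the parent cell
    out[take] <- l
  }
  list(mask = out, no_mito_mask = missing)
}
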