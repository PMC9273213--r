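#' Pearson correlation coefficient of two intensity vectors
#'
#' The mislocalization metric: `r = sum((x - mx) * (y - my)) /
#' sqrt(sum((x - mx)^2) * sum((y - my)^2))`, evaluated over the measurement
#' pixels of one cell. Either vector being constant makes the correlation
#' undefined; this raises a condition of class `mitoloc_zero_variance`, which
#' the per-cell driver converts into an exclusion flag.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Correlation in \[-1, 1\] (up to rounding).
#' @export
#' @examples
#' pearson_cc(c(1, 2, 3), c(3, 5, 7))  # positive affine image: 1
pearson_cc <- function(x, y) {
  if (length(x) != length(y))
    abort(sprintf("length mismatch: %d vs %d", length(x), length(y)),
          class = "mitoloc_input_error")
  if (length(x) < 2)
    abort("need at least 2 pixels", class = "mitoloc_input_error")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0)
    abort("undefined correlation: zero variance",
          class = "mitoloc_zero_variance")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Per-cell colocalization records
#'
#' For each cell in the pseudo-cell mask, computes the Pearson correlation of
#' the reporter and mitochondria channels over the measurement pixel set
#' (pseudo-cell mask minus nuclei). Cells with too few pixels or a constant
#' channel are flagged excluded, never dropped silently.
#'
#' @param reporter_image,mito_image Background-corrected channels.
#' @param pseudo_cell_mask Integer label matrix from [make_pseudo_cell_mask()].
#' @param nucleus_mask Integer label matrix (or logical) of nuclei to exclude.
#' @param min_pixels Minimum measurement pixels for a defined PCC.
#' @param field_id,condition Labels copied into the records.
#' @param integrated_marker Optional named vector (by label) of integrated
#'   marker intensities to carry along.
#' @return A tibble of cell records: `cell_id`, `field_id`, `condition`,
#'   `pcc`, `n_pixels`, `integrated_marker`, `mean_reporter`, `mean_mito`,
#'   `excluded`, `exclude_reason`.
#' @export
per_cell_colocalization <- function(reporter_image, mito_image,
                                    pseudo_cell_mask, nucleus_mask,
                                    min_pixels = 50,
                                    field_id = NA_character_,
                                    condition = NA_character_,
                                    integrated_marker = NULL) {
  dims <- list(dim(reporter_image), dim(mito_image), dim(pseudo_cell_mask),
               dim(nucleus_mask))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    abort("all images and masks must share one shape",
          class = "mitoloc_input_error")
  labs <- setdiff(sort(unique(as.vector(pseudo_cell_mask))), 0L)
  rows <- lapply(labs, function(l) {
    px <- which(pseudo_cell_mask == l & !(nucleus_mask > 0))
    im <- if (!is.null(integrated_marker))
      unname(integrated_marker[as.character(l)]) else NA_real_
    rec <- list(cell_id = as.integer(l), field_id = field_id,
                condition = condition, pcc = NA_real_,
                n_pixels = length(px), integrated_marker = im,
                mean_reporter = NA_real_, mean_mito = NA_real_,
                excluded = TRUE, exclude_reason = "none")
    if (length(px) < min_pixels) {
      rec$exclude_reason <- "too_few_pixels"
      return(rec)
    }
    x <- reporter_image[px]; y <- mito_image[px]
    rec$mean_reporter <- mean(x)
    rec$mean_mito <- mean(y)
    r <- tryCatch(pearson_cc(x, y),
                  mitoloc_zero_variance = function(e) NULL)
    if (is.null(r)) {
      rec$exclude_reason <- "zero_variance"
    } else {
      rec$pcc <- r
      rec$excluded <- FALSE
    }
    rec
  })
  if (!length(rows))
    return(tibble(cell_id = integer(), field_id = character(),
                  condition = character(), pcc = numeric(),
                  n_pixels = integer(), integrated_marker = numeric(),
                  mean_reporter = numeric(), mean_mito = numeric(),
                  excluded = logical(), exclude_reason = character()))
  do.call(rbind, lapply(rows, function(r) as_tibble(r)))
}

#' Measure per-cell colocalization on ground-truth masks
#'
#' Oracle route for synthetic data: uses the generator's own cell and nucleus
#' masks as the measurement regions (cell mask minus nucleus), bypassing
#' segmentation. Useful for validating the measurement itself and for
#' statistical calibration studies.
#'
#' @param field A `field_stack` (noise-free or noisy).
#' @param truths The field's list of `scene_truth`.
#' @param min_pixels Minimum pixels for a defined PCC.
#' @param project Apply [average_projection()] to each channel first.
#' @return A tibble as in [per_cell_colocalization()], plus `theta`,
#'   `expression_level` and `transfected` from the truth.
#' @export
measure_with_truth <- function(field, truths, min_pixels = 50,
                               project = TRUE) {
  rep_img <- field$channels$reporter
  mito_img <- field$channels$mito
  if (project) {
    rep_img <- average_projection(rep_img)
    mito_img <- average_projection(mito_img)
  }
  rows <- lapply(truths, function(tr) {
    px <- setdiff(tr$cell_px, tr$nucleus_px)
    rec <- list(cell_id = tr$cell_id, field_id = field$field_id,
                condition = field$condition, pcc = NA_real_,
                n_pixels = length(px),
                integrated_marker = tr$expression_level * length(tr$cell_px),
                mean_reporter = NA_real_, mean_mito = NA_real_,
                excluded = TRUE, exclude_reason = "none",
                theta = tr$theta, expression_level = tr$expression_level,
                transfected = tr$transfected)
    if (length(px) < min_pixels) {
      rec$exclude_reason <- "too_few_pixels"
      return(rec)
    }
    x <- rep_img[px]; y <- mito_img[px]
    rec$mean_reporter <- mean(x); rec$mean_mito <- mean(y)
    r <- tryCatch(pearson_cc(x, y), mitoloc_zero_variance = function(e) NULL)
    if (is.null(r)) rec$exclude_reason <- "zero_variance"
    else { rec$pcc <- r; rec$excluded <- FALSE }
    rec
  })
  do.call(rbind, lapply(rows, as_tibble))
}
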