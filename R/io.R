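## TIFF / CSV / config I/O. Channel order in field TIFFs is fixed and
## recorded in the sidecar manifest: nuclei, reporter, marker, mito; z-planes
## follow channel-major order (all z of channel 1, then channel 2, ...).

CHANNEL_ORDER <- c("nuclei", "reporter", "marker", "mito")

#' Write one field as a multi-directory TIFF (plus JSON sidecar)
#'
#' Images are stored as 32-bit float TIFF directories; integer count data
#' round-trips exactly. The sidecar `<path>.json` records channel order,
#' z-depth, field id and condition.
#'
#' @param field A `field_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  planes <- list()
  nz <- 1L
  for (ch in CHANNEL_ORDER) {
    img <- field$channels[[ch]]
    if (is.null(img))
      abort(sprintf("field is missing channel role '%s'", ch),
            class = "mitoloc_input_error")
    if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
    nz <- dim(img)[3]
    for (z in seq_len(nz)) planes[[length(planes) + 1L]] <- img[, , z]
  }
  ## 16-bit samples with an integer scale: digitized counts <= 65535
  ## round-trip exactly; brighter data loses only the scale's quantization
  scale <- max(1, ceiling(max(vapply(planes, max, 0)) / 65535))
  tiff::writeTIFF(lapply(planes, function(p) p / (scale * 65535)), path,
                  bits.per.sample = 16L, compression = "none")
  meta <- list(channel_order = CHANNEL_ORDER, n_z = nz,
               intensity_scale = scale * 65535,
               field_id = field$field_id, condition = field$condition)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a field from TIFF(s)
#'
#' Either a single multi-directory TIFF written by [write_field()] (with its
#' JSON sidecar), or four per-channel TIFF paths given as a named list/vector
#' with roles `nuclei`, `reporter`, `marker`, `mito`.
#'
#' @param path A TIFF path, or a named list/character vector of per-role
#'   paths.
#' @param field_id,condition Labels for the result (overridden by sidecar
#'   metadata when present).
#' @return A `field_stack`.
#' @export
read_field <- function(path, field_id = NA_character_,
                       condition = NA_character_) {
  read_one <- function(p) {
    if (!file.exists(p))
      abort(sprintf("cannot read image file '%s'", p),
            class = "mitoloc_io_error")
    pl <- tiff::readTIFF(p, all = TRUE)
    lapply(pl, function(m) matrix(as.numeric(m), nrow(m)))
  }
  if (length(path) == 1L && is.character(path) && is.null(names(path))) {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path))
      abort(sprintf("missing sidecar metadata '%s'", meta_path),
            class = "mitoloc_io_error")
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    planes <- read_one(path)
    nz <- as.integer(meta$n_z)
    scale <- as.numeric(meta$intensity_scale)
    if (length(planes) != 4L * nz)
      abort(sprintf("'%s' has %d directories, expected %d", path,
                    length(planes), 4L * nz), class = "mitoloc_io_error")
    channels <- list()
    k <- 1L
    for (ch in meta$channel_order) {
      zs <- planes[k:(k + nz - 1L)]
      k <- k + nz
      arr <- array(unlist(zs), dim = c(dim(zs[[1]]), nz)) * scale
      channels[[ch]] <- if (nz == 1L) arr[, , 1] else arr
    }
    return(structure(list(channels = channels,
                          field_id = meta$field_id %||% field_id,
                          condition = meta$condition %||% condition),
                     class = "field_stack"))
  }
  roles <- names(path)
  missing_roles <- setdiff(CHANNEL_ORDER, roles)
  if (length(missing_roles))
    abort(sprintf("missing channel role(s): %s",
                  paste(missing_roles, collapse = ", ")),
          class = "mitoloc_io_error")
  channels <- lapply(path[CHANNEL_ORDER], function(p) {
    pl <- read_one(p)
    if (length(pl) == 1L) pl[[1]]
    else array(unlist(pl), dim = c(dim(pl[[1]]), length(pl)))
  })
  names(channels) <- CHANNEL_ORDER
  shapes <- lapply(channels, function(ch) dim(ch)[1:2])
  same <- vapply(shapes, identical, TRUE, shapes[[1]])
  if (!all(same))
    abort(sprintf("channel shape mismatch: %s is %s but %s is %s",
                  CHANNEL_ORDER[1], paste(shapes[[1]], collapse = "x"),
                  CHANNEL_ORDER[which(!same)[1]],
                  paste(shapes[[which(!same)[1]]], collapse = "x")),
          class = "mitoloc_io_error")
  structure(list(channels = channels, field_id = field_id,
                 condition = condition), class = "field_stack")
}

#' Write a label mask as 16-bit TIFF
#'
#' @param labels Integer label matrix (values <= 65535).
#' @param path Output path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535)
    abort("label values exceed 16-bit range", class = "mitoloc_io_error")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label mask TIFF
#' @param path TIFF path written by [write_label_mask()].
#' @return Integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Write per-cell truth records as CSV
#' @param truths List of per-field `scene_truth` lists.
#' @param path Output CSV path.
#' @param field_ids Optional field id per element of `truths`.
#' @export
write_truth_csv <- function(truths, path, field_ids = NULL) {
  if (is.null(field_ids)) field_ids <- sprintf("f%02d", seq_along(truths))
  rows <- list()
  for (i in seq_along(truths)) for (tr in truths[[i]])
    rows[[length(rows) + 1L]] <- tibble(
      field_id = field_ids[i], cell_id = tr$cell_id,
      center_r = tr$center[1], center_c = tr$center[2],
      cell_radius = tr$cell_radius,
      cell_area = length(tr$cell_px), nucleus_area = length(tr$nucleus_px),
      mito_area = length(tr$mito_px), golgi_area = length(tr$golgi_px),
      theta = tr$theta, expression_level = tr$expression_level,
      transfected = tr$transfected)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' @param conditions Named list: for simulated runs, each element is a list of
#'   [synth_params()] overrides (at least `misloc_fraction`); for runs on
#'   disk, each element has a `fields` entry listing field TIFF paths.
#' @param synth Baseline [synth_params()] shared by all simulated conditions.
#' @param segmentation A [segmentation_params()] object.
#' @param background List with `method`, `radius_px`, `poly_order` for
#'   [correct_background()].
#' @param out_dir Output directory for tables and masks.
#' @param seed Master seed; condition k runs under `seed + 1000 * (k - 1)`.
#' @param write_images Write label masks / field TIFFs alongside tables?
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(conditions,
                            synth = synth_params(),
                            segmentation = segmentation_params(),
                            background = list(method = "opening",
                                              radius_px = 50, poly_order = 2),
                            out_dir = tempfile("mitoloc_run_"),
                            seed = 1L,
                            write_images = FALSE) {
  if (!is.list(conditions) || is.null(names(conditions)) ||
      any(!nzchar(names(conditions))))
    abort("conditions must be a named list", class = "mitoloc_param_error")
  cfg <- list(conditions = conditions, synth = unclass(synth),
              segmentation = unclass(segmentation), background = background,
              out_dir = out_dir, seed = as.integer(seed),
              write_images = isTRUE(write_images))
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' Round-trips losslessly: `config_hash()` of the restored object equals the
#' original's.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' @rdname write_config
#' @export
config_hash <- function(config) {
  rlang::hash(normalize_for_hash(unclass(config)))
}

## canonical form: drop attribute/typing noise that YAML does not preserve
normalize_for_hash <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, normalize_for_hash)
    attributes(x) <- list(names = names(x))
    return(x)
  }
  if (is.numeric(x)) return(as.numeric(x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
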