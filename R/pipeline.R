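## End-to-end workflow: preprocess -> segment -> gate -> pseudo-cell mask ->
## per-cell PCC -> condition summaries -> pairwise comparisons.

#' Quantify one preprocessed field
#'
#' Runs segmentation, cell-body propagation, transfection gating, the
#' pseudo-cell mask and per-cell colocalization on a single field whose
#' channels are already projected and background-corrected.
#'
#' All segmented cells appear in the result: non-gated cells are flagged
#' `not_transfected`, gated cells missing a mitochondrial mask
#' `no_mito_mask`, and the remaining exclusion reasons come from the
#' colocalization stage.
#'
#' @param field A preprocessed `field_stack` (see [preprocess_field()]).
#' @param seg A [segmentation_params()] object; `marker_gate` must be numeric
#'   here (the experiment-level gate is resolved by [run_pipeline()]).
#' @param keep_masks Also return the label masks.
#' @return A tibble of cell records (plus `masks` attribute when requested).
#' @export
quantify_field <- function(field, seg = segmentation_params(marker_gate = 0),
                           keep_masks = FALSE) {
  if (!is.numeric(seg$marker_gate))
    abort("quantify_field needs a numeric marker_gate",
          class = "mitoloc_param_error")
  ch <- field$channels
  nuclei <- segment_nuclei(ch$nuclei, seg)
  cells <- propagate_cell_masks(nuclei, ch[[seg$guidance]], seg)
  gate <- gate_transfected(cells, ch$marker, seg$marker_gate)
  pseudo <- make_pseudo_cell_mask(ch$mito, cells, selected = gate$selected,
                                  params = seg)
  recs <- per_cell_colocalization(ch$reporter, ch$mito, pseudo$mask, nuclei,
                                  min_pixels = seg$min_pixels,
                                  field_id = field$field_id,
                                  condition = field$condition,
                                  integrated_marker = gate$integrated)
  all_labels <- as.integer(names(gate$integrated))
  extra <- setdiff(all_labels, recs$cell_id)
  if (length(extra)) {
    reason <- ifelse(extra %in% gate$selected, "no_mito_mask",
                     "not_transfected")
    recs <- rbind(recs, tibble(
      cell_id = extra, field_id = field$field_id,
      condition = field$condition, pcc = NA_real_, n_pixels = 0L,
      integrated_marker = unname(gate$integrated[as.character(extra)]),
      mean_reporter = NA_real_, mean_mito = NA_real_,
      excluded = TRUE, exclude_reason = reason))
  }
  recs <- recs[order(recs$cell_id), ]
  if (keep_masks)
    attr(recs, "masks") <- list(nuclei = nuclei, cells = cells,
                                pseudo = pseudo$mask)
  recs
}

#' Run the full mislocalization pipeline
#'
#' Executes, per condition: synthetic generation (or field loading),
#' average-intensity projection, background correction, nucleus segmentation,
#' cell-body propagation, transfection gating (a single experiment-wide gate,
#' either the configured number or one derived from the pooled integrated
#' intensities), pseudo-cell masking, per-cell PCC, condition summaries and
#' all pairwise Mann-Whitney comparisons. Writes `per_cell.csv`,
#' `condition_summary.csv`, `comparisons.csv` and `manifest.json` under
#' `config$out_dir` and returns the tables invisibly.
#'
#' @param config A [pipeline_config()].
#' @return (invisibly) list with `records`, `summaries`, `comparisons`,
#'   `gate`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort("config must be a pipeline_config", class = "mitoloc_param_error")
  conds <- names(config$conditions)
  if (!length(conds))
    abort("no conditions configured", class = "mitoloc_param_error")
  seg <- do.call(segmentation_params, config$segmentation)
  bg <- config$background

  ## stage 1: obtain + preprocess fields
  fields <- list()
  for (k in seq_along(conds)) {
    spec_k <- config$conditions[[k]]
    if (!is.null(spec_k$fields)) {           # fields on disk
      fl <- lapply(spec_k$fields, read_field, condition = conds[k])
      for (i in seq_along(fl)) {
        fl[[i]]$condition <- conds[k]
        if (is.na(fl[[i]]$field_id))
          fl[[i]]$field_id <- sprintf("%s_f%02d", conds[k], i)
      }
    } else {                                  # simulate
      overrides <- spec_k
      sp_args <- utils::modifyList(config$synth, overrides)
      sp_args$seed <- as.integer(config$seed + 1000 * (k - 1))
      sp <- do.call(synth_params, sp_args)
      fl <- generate_condition(sp, conds[k])$fields
    }
    if (!length(fl))
      abort(sprintf("condition '%s' has no fields", conds[k]),
            class = "mitoloc_input_error")
    fields[[conds[k]]] <- lapply(fl, preprocess_field, method = bg$method,
                                 radius_px = bg$radius_px,
                                 poly_order = bg$poly_order)
  }

  ## stage 2: segment all fields, pool integrated intensities for the gate
  seg_state <- list()
  pooled <- numeric(0)
  for (cn in conds) for (f in fields[[cn]]) {
    nuclei <- segment_nuclei(f$channels$nuclei, seg)
    cells <- propagate_cell_masks(nuclei, f$channels[[seg$guidance]], seg)
    gate0 <- gate_transfected(cells, f$channels$marker, 0)
    seg_state[[f$field_id]] <- list(field = f, nuclei = nuclei, cells = cells,
                                    integrated = gate0$integrated)
    pooled <- c(pooled, gate0$integrated)
  }
  gate_value <- if (identical(seg$marker_gate, "suggest"))
    suggest_marker_gate(pooled) else seg$marker_gate

  ## stage 3: gate, pseudo-cell mask, per-cell PCC
  records <- list()
  for (st in seg_state) {
    f <- st$field
    selected <- as.integer(names(st$integrated)[st$integrated > gate_value])
    pseudo <- make_pseudo_cell_mask(f$channels$mito, st$cells,
                                    selected = selected, params = seg)
    recs <- per_cell_colocalization(f$channels$reporter, f$channels$mito,
                                    pseudo$mask, st$nuclei,
                                    min_pixels = seg$min_pixels,
                                    field_id = f$field_id,
                                    condition = f$condition,
                                    integrated_marker = st$integrated)
    extra <- setdiff(as.integer(names(st$integrated)), recs$cell_id)
    if (length(extra)) {
      reason <- ifelse(extra %in% selected, "no_mito_mask", "not_transfected")
      recs <- rbind(recs, tibble(
        cell_id = extra, field_id = f$field_id, condition = f$condition,
        pcc = NA_real_, n_pixels = 0L,
        integrated_marker = unname(st$integrated[as.character(extra)]),
        mean_reporter = NA_real_, mean_mito = NA_real_,
        excluded = TRUE, exclude_reason = reason))
    }
    records[[length(records) + 1L]] <- recs[order(recs$cell_id), ]
  }
  records <- do.call(rbind, records)

  ## stage 4: statistics
  summaries <- do.call(rbind, lapply(conds, function(cn) {
    sub <- records[records$condition == cn, ]
    if (!any(!sub$excluded))
      abort(sprintf("condition '%s' has zero analyzable cells", cn),
            class = "mitoloc_stats_error")
    summarize_condition(sub, cn)
  }))
  comparisons <- NULL
  if (length(conds) >= 2) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(pr) {
      a <- records$pcc[records$condition == pr[1] & !records$excluded]
      b <- records$pcc[records$condition == pr[2] & !records$excluded]
      mann_whitney_u(a, b, pr[1], pr[2])
    }))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mitoloc")),
    config_hash = config_hash(config),
    seed = config$seed,
    marker_gate = gate_value,
    n_fields = sum(vapply(fields, length, 1L)),
    n_cells = nrow(records),
    n_analyzed = sum(!records$excluded)
  )

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(config$out_dir, "per_cell.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(config$out_dir,
                                        "condition_summary.csv"),
                   row.names = FALSE)
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (config$write_images)
    for (st in seg_state)
      write_label_mask(st$cells, file.path(
        config$out_dir, paste0(st$field$field_id, "_cells.tif")))

  invisible(list(records = records, summaries = summaries,
                 comparisons = comparisons, gate = gate_value,
                 manifest = manifest))
}

#' Match segmented cells to ground truth by mask overlap
#'
#' Greedy one-to-one matching of predicted cell labels to true cells by
#' intersection-over-union.
#'
#' @param pred_labels Integer label matrix from the pipeline.
#' @param truths List of `scene_truth` for the same field.
#' @param iou_threshold Minimum IoU for a match.
#' @return A tibble with one row per true cell: `cell_id`, `matched_label`
#'   (NA if unmatched), `iou`.
#' @export
match_cells_to_truth <- function(pred_labels, truths, iou_threshold = 0.5) {
  labs <- setdiff(sort(unique(as.vector(pred_labels))), 0L)
  pred_px <- lapply(labs, function(l) which(pred_labels == l))
  names(pred_px) <- labs
  rows <- list()
  used <- character(0)
  for (tr in truths) {
    best_iou <- 0; best_lab <- NA_integer_
    for (l in setdiff(as.character(labs), used)) {
      inter <- length(intersect(tr$cell_px, pred_px[[l]]))
      if (!inter) next
      iou <- inter / (length(tr$cell_px) + length(pred_px[[l]]) - inter)
      if (iou > best_iou) { best_iou <- iou; best_lab <- as.integer(l) }
    }
    if (!is.na(best_lab) && best_iou >= iou_threshold)
      used <- c(used, as.character(best_lab))
    else best_lab <- NA_integer_
    rows[[length(rows) + 1L]] <- tibble(cell_id = tr$cell_id,
                                        matched_label = best_lab,
                                        iou = best_iou)
  }
  do.call(rbind, rows)
}
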