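#' Dot plot of per-cell PCC values by condition
#'
#' One dot per analyzed cell, a bar at the condition mean and a whisker of
#' +/- 1 SEM — the standard presentation of per-cell colocalization data.
#' Requires ggplot2.
#'
#' @param records Per-cell record tibble (non-excluded rows are plotted).
#' @return A ggplot object.
#' @export
plot_pcc_dots <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort("plot_pcc_dots requires ggplot2", class = "mitoloc_input_error")
  ok <- records[!records$excluded, ]
  summ <- do.call(rbind, lapply(split(ok, ok$condition), summarize_condition))
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$condition, y = .data$pcc)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_errorbar(
      data = summ,
      ggplot2::aes(x = .data$condition,
                   ymin = .data$mean_pcc - .data$sem_pcc,
                   ymax = .data$mean_pcc + .data$sem_pcc),
      inherit.aes = FALSE, width = 0.25) +
    ggplot2::geom_point(data = summ,
                        ggplot2::aes(x = .data$condition, y = .data$mean_pcc),
                        inherit.aes = FALSE, shape = 95, size = 10) +
    ggplot2::labs(x = NULL, y = "Per-cell PCC (reporter vs mitochondria)") +
    ggplot2::theme_classic()
}
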