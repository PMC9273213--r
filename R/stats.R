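## Condition-level statistics: mean +/- SEM of per-cell PCCs, Mann-Whitney
## two-group comparisons, and the expression-vs-mislocalization correlation.

#' Summarize a condition's per-cell PCC values
#'
#' Mean and standard error of the mean (sample sd / sqrt(n)) over the
#' non-excluded records of one condition.
#'
#' @param records Tibble of cell records (from [per_cell_colocalization()]).
#' @param condition Condition name used in messages (defaults to the records'
#'   own label).
#' @return A tibble with `condition`, `n_cells`, `mean_pcc`, `sem_pcc`
#'   (`NA` for n = 1).
#' @export
#' @examples
#' recs <- tibble::tibble(condition = "wt", pcc = c(0.1, 0.2, 0.3),
#'                        excluded = FALSE)
#' summarize_condition(recs)
summarize_condition <- function(records, condition = NULL) {
  if (is.null(condition))
    condition <- if (nrow(records)) records$condition[1] else NA_character_
  if (!nrow(records))
    abort(sprintf("no records for condition '%s'", condition),
          class = "mitoloc_stats_error")
  v <- records$pcc[!records$excluded]
  if (!length(v))
    abort(sprintf("all records excluded for condition '%s'", condition),
          class = "mitoloc_stats_error")
  tibble(condition = condition, n_cells = length(v), mean_pcc = mean(v),
         sem_pcc = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                   else NA_real_)
}

#' Mann-Whitney U test for two groups of per-cell values
#'
#' `U = #\{(i,j): a_i > b_j\} + ties/2`. Tie-free small samples
#' (`n_a + n_b <= 16`) get the exact two-sided p-value from the null rank
#' distribution (`method = "exact"`); otherwise the normal approximation with
#' tie correction and continuity correction is used
#' (`method = "normal_tie_corrected"`). Two-sided p = `min(1, 2 * one-sided)`.
#'
#' @param a,b Nonempty numeric vectors.
#' @param condition_a,condition_b Optional group labels for the result.
#' @return A tibble with `condition_a`, `condition_b`, `u`, `p_two_sided`,
#'   `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_two_sided  # exact: 1/3
mann_whitney_u <- function(a, b, condition_a = "a", condition_b = "b") {
  if (!length(a) || !length(b))
    abort("both groups must be nonempty", class = "mitoloc_stats_error")
  na <- length(a); nb <- length(b)
  comb <- c(a, b)
  r <- rank(comb)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(comb))
  if (!ties && na + nb <= 16) {
    ## exact null distribution of U
    p_le <- pwilcox(u, na, nb)
    p_ge <- 1 - if (u >= 1) pwilcox(u - 1, na, nb) else 0
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    n <- na + nb
    mu <- na * nb / 2
    tie_tab <- table(comb)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)  # continuity corrected
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_tie_corrected"
  }
  tibble(condition_a = condition_a, condition_b = condition_b,
         u = u, p_two_sided = p, method = method, n_a = na, n_b = nb)
}

#' Correlation between expression level and mislocalization
#'
#' Spearman rank correlation between each cell's integrated marker intensity
#' (the expression proxy) and its PCC, over non-excluded records. Ties get
#' average ranks; the p-value uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` and is flagged approximate for
#' n < 10.
#'
#' @param records Tibble with `integrated_marker`, `pcc`, `excluded`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list: `rho`, `p`, `n`, `undefined` (constant input), and
#'   `approximate` (small-n flag).
#' @export
expression_correlation <- function(records, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- !records$excluded & is.finite(records$integrated_marker) &
    is.finite(records$pcc)
  x <- records$integrated_marker[ok]
  y <- records$pcc[ok]
  n <- length(x)
  if (n < 3)
    abort("need >= 3 non-excluded records with defined expression",
          class = "mitoloc_stats_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE,
                approximate = FALSE))
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  rho <- cor(x, y)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n, undefined = FALSE, approximate = n < 10)
}
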