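recs_of <- function(pcc, condition = "c", excluded = FALSE,
                    marker = seq_along(pcc)) {
  tibble::tibble(condition = condition, pcc = pcc,
                 excluded = rep_len(excluded, length(pcc)),
                 integrated_marker = marker)
}

test_that("condition summaries report mean and sample-sd SEM over non-excluded cells", {
  s <- summarize_condition(recs_of(c(0.1, 0.2, 0.3)))
  expect_equal(s$mean_pcc, 0.2)
  expect_equal(s$sem_pcc, 0.1 / sqrt(3), tolerance = 1e-12)  # sd([.1,.2,.3]) = .1
  one <- summarize_condition(recs_of(0.4))
  expect_equal(one$mean_pcc, 0.4)
  expect_true(is.na(one$sem_pcc))
  # excluded records do not contribute
  mix <- rbind(recs_of(c(0.1, 0.3)), recs_of(9, excluded = TRUE))
  expect_equal(summarize_condition(mix)$mean_pcc, 0.2)
  expect_error(summarize_condition(recs_of(numeric(0))),
               class = "mitoloc_stats_error")
  expect_error(summarize_condition(recs_of(0.5, excluded = TRUE)),
               class = "mitoloc_stats_error")
})

test_that("Mann-Whitney exact p-values match the enumeration of rank assignments", {
  r1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r1$u, 0)
  expect_equal(r1$p_two_sided, 1 / 3, tolerance = 1e-12)
  expect_equal(r1$method, "exact")
  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$u, 1)
  expect_equal(r2$p_two_sided, 2 / 3, tolerance = 1e-12)
  withr::with_seed(6, {
    for (i in 1:15) {
      na <- sample(2:6, 1); nb <- sample(2:6, 1)
      a <- sample(100, na); b <- setdiff(sample(100, na + nb), a)[seq_len(nb)]
      oracle <- enum_mw(a, b)
      got <- mann_whitney_u(a, b)
      expect_equal(got$u, oracle$u)
      expect_equal(got$p_two_sided, oracle$p, tolerance = 1e-12)
    }
  })
})

test_that("tied and large samples use the tie-corrected normal approximation", {
  same <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(same$p_two_sided, 1)
  expect_equal(same$method, "normal_tie_corrected")
  withr::with_seed(11, {
    a <- rnorm(30); b <- rnorm(35)
    got <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
    expect_gt(got$p_two_sided, 0)
    expect_lte(got$p_two_sided, 1)
  })
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "mitoloc_stats_error")
})

test_that("U statistics of the two orientations sum to n_a * n_b", {
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
      u_ab <- mann_whitney_u(a, b)$u
      u_ba <- mann_whitney_u(b, a)$u
      expect_equal(u_ab + u_ba, length(a) * length(b))
      expect_gte(u_ab, 0)
      expect_lte(u_ab, length(a) * length(b))
    }
  })
})

test_that("expression correlation recovers monotone association and flags degenerate input", {
  mono <- recs_of(pcc = c(0.1, 0.2, 0.4, 0.5, 0.7), marker = c(1, 3, 8, 20, 90))
  r <- expression_correlation(mono)
  expect_equal(r$rho, 1.0)
  expect_equal(r$p, 0)
  # hand-derived: pairs (1,3),(2,1),(3,2) -> rho = 1 - 6*6/(3*8) = -0.5
  r2 <- expression_correlation(recs_of(pcc = c(3, 1, 2), marker = c(1, 2, 3)))
  expect_equal(r2$rho, -0.5, tolerance = 1e-12)
  expect_true(r2$approximate)
  const <- expression_correlation(recs_of(pcc = c(1, 2, 3), marker = rep(4, 3)))
  expect_true(const$undefined)
  expect_error(expression_correlation(recs_of(pcc = c(1, 2), marker = 1:2)),
               class = "mitoloc_stats_error")
})

test_that("Spearman rho is invariant under strictly increasing transforms", {
  withr::with_seed(21, {
    x <- rlnorm(30); y <- rnorm(30)
    base <- expression_correlation(recs_of(pcc = y, marker = x))
    tr1 <- expression_correlation(recs_of(pcc = y, marker = log(x)))
    tr2 <- expression_correlation(recs_of(pcc = exp(y / 3), marker = x^3))
    expect_equal(tr1$rho, base$rho, tolerance = 1e-12)
    expect_equal(tr2$rho, base$rho, tolerance = 1e-12)
  })
})

test_that("t-approximation p-value agrees with cor.test on untied data", {
  withr::with_seed(25, {
    x <- rlnorm(40); y <- 0.3 * rank(x) + rnorm(40, sd = 6)
    r <- expression_correlation(recs_of(pcc = y, marker = x))
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
  })
})
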