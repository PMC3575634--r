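test_that("incidence percentages follow half-up rounding of count/n", {
  expect_equal(incidence_percent(29, 120), 24.2)
  expect_equal(incidence_percent(63, 120), 52.5)
  expect_equal(incidence_percent(0, 120), 0)
  set.seed(5)
  for (i in 1:50) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    expect_equal(incidence_percent(k, n),
                 round_half_up(100 * k / n, 1))
  }
})

test_that("incidence counts impinged specimens per region and nail", {
  reports <- list(
    stub_report("f1", "A", impinged_vec(prox = TRUE)),
    stub_report("f1", "B", impinged_vec()),
    stub_report("f2", "A", impinged_vec(prox = TRUE, dist = TRUE)),
    stub_report("f2", "B", impinged_vec(mid = TRUE)),
    stub_report("f3", "A", impinged_vec()),
    stub_report("f3", "B", impinged_vec(mid = TRUE)),
    stub_report("f4", "A", impinged_vec(dist = TRUE)),
    stub_report("f4", "B", impinged_vec()))
  tab <- build_cohort(reports)
  expect_equal(tab$n, 4)
  expect_equal(incidence(tab, "proximal", "A")$count, 2)
  expect_equal(incidence(tab, "proximal", "A")$percent, 50)
  expect_equal(incidence(tab, "proximal", "B")$count, 0)
  expect_equal(incidence(tab, "middle", "B")$count, 2)
  expect_equal(incidence(tab, "distal", "A")$count, 2)
  expect_error(incidence(tab, "shaft", "A"), class = "femfit_config_error")
  expect_error(incidence(tab, "distal", "C"), class = "femfit_config_error")
})

test_that("unpaired report sets are rejected", {
  expect_error(build_cohort(list(stub_report("f1", "A", impinged_vec()))),
               class = "femfit_config_error")
  expect_error(build_cohort(list(
    stub_report("f1", "A", impinged_vec()),
    stub_report("f1", "B", impinged_vec()),
    stub_report("f2", "A", impinged_vec()))),
    class = "femfit_config_error")
})

test_that("incidence comparison picks the documented test variants", {
  # frozen from the independent sum((O-E)^2/E) computation on
  # [[29, 91], [7, 113]]
  cmp <- compare_incidence(29, 7, 120)
  expect_equal(cmp$test, "chi-square")
  expect_equal(round(cmp$statistic, 2), 15.82)

  eq <- compare_incidence(17, 17, 99)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  fis <- compare_incidence(2, 0, 5)  # expected counts < 5
  expect_equal(fis$test, "fisher")

  expect_error(compare_incidence(3, 1, 0), class = "femfit_config_error")
  expect_error(compare_incidence(7, 1, 5), class = "femfit_config_error")
})

test_that("chi-square matches the from-scratch oracle on random tables", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(30:400, 1)
    a <- sample(6:(n - 6), 1)
    b <- sample(6:(n - 6), 1)
    tab <- matrix(c(a, n - a, b, n - b), nrow = 2, byrow = TRUE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(E < 5)) next
    oracle <- sum((tab - E)^2 / E)
    cmp <- compare_incidence(a, b, n)
    expect_equal(cmp$statistic, oracle, tolerance = 1e-10)
  }
})

test_that("incidence comparison is symmetric in the two designs", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    a <- sample(0:n, 1)
    b <- sample(0:n, 1)
    x <- compare_incidence(a, b, n)
    y <- compare_incidence(b, a, n)
    expect_equal(x$p_value, y$p_value, tolerance = 1e-12)
    if (x$test == "chi-square")
      expect_equal(x$statistic, y$statistic, tolerance = 1e-12)
  }
})

test_that("metric summaries use mean and n-1 SD", {
  s <- summarize_metric(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(round(s$sd, 2), 1.41)
  expect_equal(s$n, 2)
  one <- summarize_metric(c(NA, 7, NA))
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sd))
  none <- summarize_metric(c(NA_real_, NA_real_))
  expect_equal(none$n, 0)
  expect_true(is.na(none$mean))
  set.seed(12)
  draws <- rnorm(1000, 10, 2)
  expect_lt(abs(summarize_metric(draws)$mean - 10), 3 * 2 / sqrt(1000))
})

test_that("paired comparison handles identical and degenerate inputs", {
  same <- compare_paired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shift <- compare_paired(c(1, 2, 3), c(0, 1, 2))
  expect_true(is.infinite(shift$statistic))
  expect_equal(shift$p_value, 0)
  expect_error(compare_paired(c(1, NA), c(2, 3)),
               class = "femfit_insufficient_data_error")
  w <- compare_paired(c(1, 5, 3, 8), c(2, 1, 1, 4), method = "wilcoxon")
  expect_equal(w$test, "wilcoxon-signed-rank")
  expect_equal(w$n_pairs, 4)
})

test_that("paired t against base R on ordinary data", {
  set.seed(9)
  a <- rnorm(30, 5)
  b <- rnorm(30, 4.5)
  cmp <- compare_paired(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(cmp$statistic, unname(ref$statistic))
  expect_equal(cmp$p_value, ref$p.value)
})

test_that("cohort summary matches a hand tally on a constructed table", {
  reports <- list(
    stub_report("f1", "A", impinged_vec(prox = TRUE),
                list(A_max_thickness_proximal = 2, D_protrusion = 1.1,
                     G_max_gap_middle = 4)),
    stub_report("f1", "B", impinged_vec(), list(G_max_gap_middle = 6)),
    stub_report("f2", "A", impinged_vec(prox = TRUE),
                list(A_max_thickness_proximal = 3, G_max_gap_middle = 5)),
    stub_report("f2", "B", impinged_vec(mid = TRUE),
                list(E_thickness_middle = 1.5, G_max_gap_middle = 7)),
    stub_report("f3", "A", impinged_vec(), list(G_max_gap_middle = 4.5)),
    stub_report("f3", "B", impinged_vec(mid = TRUE),
                list(E_thickness_middle = 2.5, G_max_gap_middle = 6.5)),
    stub_report("f4", "A", impinged_vec(), list(G_max_gap_middle = 4)),
    stub_report("f4", "B", impinged_vec(), list(G_max_gap_middle = 7)))
  summ <- build_summary(build_cohort(reports))
  inc <- summ$incidence
  expect_equal(inc$count_a[inc$region == "proximal"], 2)
  expect_equal(inc$percent_a[inc$region == "proximal"], 50)
  expect_equal(inc$count_b[inc$region == "middle"], 2)
  expect_equal(inc$count_b[inc$region == "proximal"], 0)
  expect_equal(inc$count_a[inc$region == "protrusion"], 1)
  met <- summ$metrics
  g <- met[met$metric == "G_max_gap_middle", ]
  expect_equal(g$mean_a, mean(c(4, 5, 4.5, 4)))
  expect_equal(g$mean_b, mean(c(6, 7, 6.5, 7)))
  expect_equal(g$n_pairs, 4)
  a_row <- met[met$metric == "A_max_thickness_proximal", ]
  expect_equal(a_row$mean_a, 2.5)
  expect_equal(a_row$n_b, 0)
  expect_match(a_row$test, "insufficient")
})

test_that("an impingement-free cohort summarizes to zeros and skips", {
  reports <- unlist(lapply(1:3, function(i) list(
    stub_report(paste0("f", i), "A", impinged_vec()),
    stub_report(paste0("f", i), "B", impinged_vec()))),
    recursive = FALSE)
  summ <- build_summary(build_cohort(reports))
  expect_true(all(summ$incidence$percent_a[summ$incidence$region %in%
                                             c("proximal", "middle",
                                               "distal")] == 0))
  a_row <- summ$metrics[summ$metrics$metric == "A_max_thickness_proximal", ]
  expect_match(a_row$test, "insufficient")
})

test_that("summaries round-trip through JSON and render to CSV", {
  reports <- list(
    stub_report("f1", "A", impinged_vec(prox = TRUE),
                list(A_max_thickness_proximal = 2.345)),
    stub_report("f1", "B", impinged_vec()),
    stub_report("f2", "A", impinged_vec(prox = TRUE),
                list(A_max_thickness_proximal = 3.123)),
    stub_report("f2", "B", impinged_vec(prox = TRUE),
                list(A_max_thickness_proximal = 1.2)))
  summ <- build_summary(build_cohort(reports))
  tmp <- withr::local_tempdir()
  jp <- file.path(tmp, "s.json")
  write_cohort_summary(summ, jp)
  back <- read_cohort_summary(jp)
  expect_equal(back$incidence$count_a, summ$incidence$count_a)
  expect_equal(back$metrics$mean_a, summ$metrics$mean_a,
               tolerance = 1e-12)
  expect_equal(unname(back$nails), unname(summ$nails))
  cp <- file.path(tmp, "s.csv")
  write_cohort_summary(summ, cp)
  csv <- read.csv(cp)
  expect_true(all(c("incidence", "metric") %in% csv$kind))
  expect_equal(csv$percent_a[csv$region == "proximal" &
                               csv$kind == "incidence"], 100)
})
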