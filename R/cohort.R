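# Paired-cohort aggregation: both nail designs are virtually fitted to
# every femur, so incidences are compared between designs on 2x2 counts
# (Pearson chi-square without continuity correction when all expected
# counts allow, Fisher's exact test otherwise) and millimetre metrics by
# a paired test on per-specimen differences (paired t by default, a
# Wilcoxon signed-rank alternative behind a flag).

#' Assemble a paired cohort table
#'
#' @param reports list of `fitness_report` objects covering exactly two
#'   nail models, one report per femur per nail.
#' @return an object of class `cohort_table` with `ids`, `nails`,
#'   `reports` (reports indexed `[[femur_id]][[nail_id]]`) and `n`.
#' @export
build_cohort <- function(reports) {
  if (length(reports) == 0)
    stop_femfit("config", "no fitness reports supplied")
  ids <- vapply(reports, function(r) r$femur_id, "")
  nails <- vapply(reports, function(r) r$nail_id, "")
  un <- sort(unique(nails))
  if (length(un) != 2)
    stop_femfit("config",
                "paired cohort needs exactly 2 nail models (got: %s)",
                paste(un, collapse = ", "))
  tab <- list()
  for (i in seq_along(reports)) tab[[ids[i]]][[nails[i]]] <- reports[[i]]
  complete <- vapply(tab, function(x) length(x) == 2, TRUE)
  if (!all(complete))
    stop_femfit("config",
                "specimens missing a report for one nail: %s",
                paste(names(tab)[!complete], collapse = ", "))
  structure(list(ids = names(tab), nails = un, reports = tab,
                 n = length(tab)),
            class = "cohort_table")
}

#' Impingement incidence for one region and nail
#'
#' @param table a [build_cohort()] table.
#' @param region `"proximal"`, `"middle"` or `"distal"`.
#' @param nail one of `table$nails`.
#' @return list with `count` and `percent` (half-up, 1 decimal).
#' @export
incidence <- function(table, region, nail) {
  stopifnot(inherits(table, "cohort_table"))
  if (!region %in% region_levels)
    stop_femfit("config", "unknown region '%s'", region)
  if (!nail %in% table$nails)
    stop_femfit("config", "unknown nail '%s'", nail)
  count <- sum(vapply(table$reports, function(x)
    isTRUE(x[[nail]]$impinged[[region]]), TRUE))
  list(count = count, percent = incidence_percent(count, table$n))
}

#' @rdname incidence
#' @param count,n incidence count and denominator.
#' @export
incidence_percent <- function(count, n) {
  if (n <= 0) stop_femfit("config", "denominator must be positive")
  round_half_up(100 * count / n, 1)
}

#' Compare two incidences on a paired cohort of size n
#'
#' Builds the 2x2 table `[[a, n-a], [b, n-b]]`. Pearson chi-square
#' without continuity correction when all expected counts are >= 5,
#' otherwise the two-sided Fisher exact test (statistic = odds ratio).
#'
#' @param count_a,count_b impingement counts for the two nails.
#' @param n cohort size.
#' @return list with `test`, `statistic`, `p_value`, `table`.
#' @export
compare_incidence <- function(count_a, count_b, n) {
  if (n <= 0) stop_femfit("config", "n must be positive")
  if (count_a < 0 || count_a > n || count_b < 0 || count_b > n)
    stop_femfit("config", "counts must lie in [0, n]")
  tab <- matrix(c(count_a, n - count_a, count_b, n - count_b),
                nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (count_a == count_b)
    return(list(test = "chi-square", statistic = 0, p_value = 1,
                table = tab))
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(test = "chi-square", statistic = unname(ct$statistic),
         p_value = ct$p.value, table = tab)
  } else {
    ft <- fisher.test(tab)
    list(test = "fisher", statistic = unname(ft$estimate),
         p_value = ft$p.value, table = tab)
  }
}

#' Mean and sample SD of a metric
#'
#' @param values numeric vector; `NA`s (regions without impingement) are
#'   dropped.
#' @return list with `mean`, `sd` (n-1 denominator; `NA` for a single
#'   value) and `n`. All-`NA` input yields a null summary with `n = 0`.
#' @export
summarize_metric <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(v),
       sd = if (length(v) > 1) sd(v) else NA_real_,
       n = length(v))
}

#' Paired comparison of a metric between the two nails
#'
#' Pairs with any missing value are dropped. The default is a paired t
#' test on per-specimen differences; `method = "wilcoxon"` switches to
#' the signed-rank test. All-zero differences give statistic 0, p = 1;
#' a constant non-zero shift with zero difference variance is reported
#' as a degenerate infinite-t case with p = 0.
#'
#' @param values_a,values_b equal-length paired numeric vectors.
#' @param method `"t"` or `"wilcoxon"`.
#' @return list with `test`, `statistic`, `p_value`, `n_pairs`.
#' @export
compare_paired <- function(values_a, values_b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b))
    stop_femfit("config", "paired vectors must have equal length")
  ok <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[ok]
  b <- values_b[ok]
  if (length(a) < 2)
    stop_femfit("insufficient_data",
                "need >= 2 complete pairs (got %d)", length(a))
  d <- a - b
  if (all(d == 0))
    return(list(test = paste0("paired-", method), statistic = 0,
                p_value = 1, n_pairs = length(d)))
  if (method == "t") {
    if (sd(d) == 0)
      return(list(test = "paired-t", statistic = sign(mean(d)) * Inf,
                  p_value = 0, n_pairs = length(d)))
    tt <- t.test(a, b, paired = TRUE)
    list(test = "paired-t", statistic = unname(tt$statistic),
         p_value = tt$p.value, n_pairs = length(d))
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    list(test = "wilcoxon-signed-rank", statistic = unname(wt$statistic),
         p_value = wt$p.value, n_pairs = length(d))
  }
}

metric_fields <- function() {
  data.frame(
    region = c("proximal", "proximal", "proximal", "proximal",
               "middle", "middle", "middle", "middle", "distal", "distal"),
    metric = c("A_max_thickness_proximal", "B_length_proximal",
               "C_dist_proximal", "D_protrusion", "E_thickness_middle",
               "E_length_middle", "F_dist_middle", "G_max_gap_middle",
               "H_length_distal", "H_thickness_distal"),
    stringsAsFactors = FALSE)
}

#' Cohort summary: incidences, metric means, comparisons
#'
#' Aggregates a paired cohort into per-region incidence counts and
#' percentages with between-design tests, and per-metric mean +/- SD per
#' design with paired comparisons (plus the protrusion incidence, i.e.
#' specimens whose nail tip sits proud of the GT apex). Specimens whose
#' placement did not converge for either nail are excluded from metric
#' summaries and reported in `n_unconverged`.
#'
#' @param table a [build_cohort()] table.
#' @param paired_method `"t"` or `"wilcoxon"` for metric comparisons.
#' @return an object of class `cohort_summary` with data.frames
#'   `incidence` and `metrics`.
#' @export
build_summary <- function(table, paired_method = "t") {
  stopifnot(inherits(table, "cohort_table"))
  na <- table$nails[1]
  nb <- table$nails[2]
  conv <- vapply(table$reports, function(x)
    isTRUE(x[[na]]$converged) && isTRUE(x[[nb]]$converged), TRUE)
  use <- table$reports[conv]

  inc_rows <- lapply(region_levels, function(rg) {
    ca <- incidence(table, rg, na)
    cb <- incidence(table, rg, nb)
    cmp <- compare_incidence(ca$count, cb$count, table$n)
    data.frame(region = rg, count_a = ca$count, percent_a = ca$percent,
               count_b = cb$count, percent_b = cb$percent,
               test = cmp$test, statistic = cmp$statistic,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  # protrusion incidence (tip proud of the GT apex)
  prot <- function(nail) sum(vapply(table$reports, function(x)
    x[[nail]]$D_protrusion > 0, TRUE))
  pa <- prot(na)
  pb <- prot(nb)
  pcmp <- compare_incidence(pa, pb, table$n)
  inc_rows <- c(inc_rows, list(data.frame(
    region = "protrusion", count_a = pa,
    percent_a = incidence_percent(pa, table$n), count_b = pb,
    percent_b = incidence_percent(pb, table$n), test = pcmp$test,
    statistic = pcmp$statistic, p_value = pcmp$p_value,
    stringsAsFactors = FALSE)))
  inc_df <- do.call(rbind, inc_rows)

  mf <- metric_fields()
  met_rows <- lapply(seq_len(nrow(mf)), function(i) {
    f <- mf$metric[i]
    va <- vapply(use, function(x) x[[na]][[f]] %||% NA_real_, 0)
    vb <- vapply(use, function(x) x[[nb]][[f]] %||% NA_real_, 0)
    sa <- summarize_metric(va)
    sb <- summarize_metric(vb)
    cmp <- tryCatch(compare_paired(va, vb, method = paired_method),
                    femfit_insufficient_data_error = function(e)
                      list(test = "skipped: insufficient pairs",
                           statistic = NA_real_, p_value = NA_real_,
                           n_pairs = sum(!is.na(va) & !is.na(vb))))
    data.frame(region = mf$region[i], metric = f,
               mean_a = sa$mean, sd_a = sa$sd, n_a = sa$n,
               mean_b = sb$mean, sd_b = sb$sd, n_b = sb$n,
               test = cmp$test, statistic = cmp$statistic,
               p_value = cmp$p_value, n_pairs = cmp$n_pairs,
               stringsAsFactors = FALSE)
  })
  met_df <- do.call(rbind, met_rows)

  structure(list(nails = c(a = na, b = nb), n = table$n,
                 n_unconverged = sum(!conv), incidence = inc_df,
                 metrics = met_df),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d (a = %s, b = %s, %d unconverged)\n",
              x$n, x$nails["a"], x$nails["b"], x$n_unconverged))
  inc <- x$incidence
  for (i in seq_len(nrow(inc)))
    cat(sprintf("  %-10s a: %d (%.1f%%)  b: %d (%.1f%%)  %s p=%.3g\n",
                inc$region[i], inc$count_a[i], inc$percent_a[i],
                inc$count_b[i], inc$percent_b[i], inc$test[i],
                inc$p_value[i]))
  invisible(x)
}

#' Write / read a cohort summary
#'
#' JSON keeps full precision; the CSV renders the two display tables
#' (percentages to 1 decimal, millimetre summaries to 2).
#'
#' @param summary a `cohort_summary`.
#' @param path output path (`.json` or `.csv`).
#' @return `read_cohort_summary()` restores a `cohort_summary` from
#'   JSON.
#' @export
write_cohort_summary <- function(summary, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(summary), path, digits = NA,
                         auto_unbox = TRUE, na = "null", dataframe = "rows")
  } else {
    inc <- summary$incidence
    met <- summary$metrics
    met[c("mean_a", "sd_a", "mean_b", "sd_b")] <-
      lapply(met[c("mean_a", "sd_a", "mean_b", "sd_b")], round_half_up, 2)
    inc$kind <- "incidence"
    met$kind <- "metric"
    all_cols <- union(names(inc), names(met))
    for (cn in setdiff(all_cols, names(inc))) inc[[cn]] <- NA
    for (cn in setdiff(all_cols, names(met))) met[[cn]] <- NA
    write.csv(rbind(inc[all_cols], met[all_cols]), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort_summary
#' @export
read_cohort_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$nails <- stats::setNames(unlist(x$nails), c("a", "b"))
  structure(x, class = "cohort_summary")
}
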