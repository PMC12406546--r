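# Longitudinal two-group statistics.
#
# The study design is two groups (control / T2D) measured at weeks
# 0, 4, 8, 12. Texture-style endpoints are compared at each follow-up
# week by ANCOVA with the week-0 value as a quantitative covariate;
# thickness-style endpoints (percent of baseline) by Student's t-test,
# falling back to Mann-Whitney when either group fails a Shapiro-Wilk
# normality check. Significance level 5% throughout, uncorrected by
# default (Benjamini-Hochberg available behind a flag).

cohort_groups <- c("control", "T2D")

check_cohort_table <- function(table) {
  need <- c("animal_id", "group", "week", "layer", "measure", "value")
  if (!all(need %in% names(table)))
    stopf("cohort table needs columns %s", paste(need, collapse = ", "))
  invisible(table)
}

#' Baseline-adjusted group comparison (ANCOVA)
#'
#' Fits `value_t = b0 + b1 * group + b2 * value_0 + e` by least squares,
#' with group coded control = 0, T2D = 1, and tests `b1 = 0`. Animals
#' missing either the baseline or the follow-up value are dropped
#' (complete-case); the drop count is reported.
#'
#' @param table Long-format cohort table with columns `animal_id`,
#'   `group`, `week`, `layer`, `measure`, `value`.
#' @param measure,layer Endpoint to test.
#' @param week Follow-up week (4, 8 or 12).
#' @param baseline_week Covariate week (default 0); `NULL` drops the
#'   covariate, reducing the model to a two-group comparison of means.
#' @param alpha Significance level.
#' @return One-row data frame (a `StatResult`): `measure`, `layer`,
#'   `week`, `test_name`, `estimate` (adjusted T2D - control
#'   difference), `statistic` (F = t^2), `p_value`, `n_control`,
#'   `n_t2d`, `n_dropped`, `normality_p` (`NA`), `significant`.
#' @export
ancova_group_effect <- function(table, measure, layer, week,
                                baseline_week = 0, alpha = 0.05) {
  check_cohort_table(table)
  sub <- table[table$measure == measure & table$layer == layer, ]
  at <- sub[sub$week == week, c("animal_id", "group", "value")]
  if (!is.null(baseline_week)) {
    b <- sub[sub$week == baseline_week, c("animal_id", "value")]
    names(b)[2] <- "value_0"
    n_before <- nrow(at)
    at <- merge(at, b, by = "animal_id")
    at <- at[stats::complete.cases(at), ]
    n_dropped <- n_before - nrow(at)
  } else {
    at <- at[stats::complete.cases(at), ]
    n_dropped <- 0L
  }
  n_c <- sum(at$group == "control"); n_t <- sum(at$group == "T2D")
  if (n_c < 3L || n_t < 3L)
    stopf("insufficient data for ANCOVA on %s/%s week %s: %d control, %d T2D",
          measure, layer, week, n_c, n_t)
  if (stats::var(at$value) == 0)
    stopf("degenerate model: zero variance in %s/%s at week %s",
          measure, layer, week)
  at$grp <- as.integer(at$group == "T2D")
  fit <- if (is.null(baseline_week)) stats::lm(value ~ grp, data = at)
         else stats::lm(value ~ grp + value_0, data = at)
  co <- stats::summary.lm(fit)$coefficients
  est <- co["grp", "Estimate"]
  tval <- co["grp", "t value"]
  pval <- co["grp", "Pr(>|t|)"]
  data.frame(measure = measure, layer = layer, week = week,
             test_name = "ancova", estimate = est, statistic = tval^2,
             p_value = pval, n_control = n_c, n_t2d = n_t,
             n_dropped = n_dropped, normality_p = NA_real_,
             significant = pval <= alpha,
             stringsAsFactors = FALSE)
}

#' Normality-gated two-sample test
#'
#' Applies a Shapiro-Wilk test to each group; when both pass
#' (`p > normality_alpha`), groups are compared by the two-sided
#' Student's t-test (pooled variance), otherwise by the two-sided
#' Mann-Whitney test. Constant samples cannot be assessed by
#' Shapiro-Wilk and are routed to Mann-Whitney with a warning. The
#' Mann-Whitney p-value is exact when both groups have at most 20
#' observations and no ties straddle the samples, and otherwise uses the
#' normal approximation with continuity and tie correction.
#'
#' @param x Control-group values.
#' @param y T2D-group values.
#' @param alpha Significance level.
#' @param normality_alpha Shapiro-Wilk gate level.
#' @return One-row data frame (a `StatResult`) as in
#'   [ancova_group_effect()]; `estimate` is the T2D - control mean
#'   difference, `normality_p` the smaller of the two Shapiro-Wilk
#'   p-values.
#' @export
gated_two_sample_test <- function(x, y, alpha = 0.05,
                                  normality_alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stopf("gated test needs at least 3 values per group (got %d, %d)",
          length(x), length(y))
  sw_p <- function(v) {
    if (length(unique(v)) < 3L) {
      warning("constant or near-constant sample: Shapiro-Wilk undefined, routing to Mann-Whitney",
              call. = FALSE)
      return(NA_real_)
    }
    stats::shapiro.test(v)$p.value
  }
  px <- sw_p(x); py <- sw_p(y)
  normal <- !is.na(px) && !is.na(py) &&
    px > normality_alpha && py > normality_alpha
  if (length(unique(c(x, y))) == 1L) {
    # both samples constant and identical: no evidence of any difference
    return(data.frame(measure = NA_character_, layer = NA_character_,
                      week = NA_integer_, test_name = "mann_whitney",
                      estimate = 0, statistic = NA_real_, p_value = 1,
                      n_control = length(x), n_t2d = length(y),
                      n_dropped = 0L, normality_p = NA_real_,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  if (normal) {
    ht <- stats::t.test(y, x, var.equal = TRUE)
    test_name <- "t_test"
  } else {
    exact <- length(x) <= 20L && length(y) <= 20L &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(y, x, exact = exact, correct = TRUE))
    test_name <- "mann_whitney"
  }
  pval <- ht$p.value
  data.frame(measure = NA_character_, layer = NA_character_,
             week = NA_integer_, test_name = test_name,
             estimate = mean(y) - mean(x),
             statistic = unname(ht$statistic), p_value = pval,
             n_control = length(x), n_t2d = length(y),
             n_dropped = 0L,
             normality_p = suppressWarnings(min(px, py, na.rm = TRUE)),
             significant = pval <= alpha,
             stringsAsFactors = FALSE)
}

#' Descriptive summary of one cohort cell
#'
#' Mean, standard error of the mean, and the five-number box-plot
#' summary (median, quartiles by linear interpolation, extremes).
#'
#' @param values Numeric vector (n >= 1).
#' @return One-row data frame with `mean`, `sem`, `median`, `q25`,
#'   `q75`, `min`, `max`, `n`; `sem` is `NA` for a single value.
#' @export
five_number_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) stopf("empty cell: no finite values to summarise")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(mean = mean(values),
             sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
             median = q[2], q25 = q[1], q75 = q[3],
             min = min(values), max = max(values), n = n)
}

#' Descriptive summaries per (group, week, layer, measure) cell
#'
#' @param table Long-format cohort table.
#' @param measures Optional subset of measures.
#' @return Data frame with one row per occupied cell, columns `group`,
#'   `week`, `layer`, `measure` plus the [five_number_summary()] fields.
#' @export
summarize_cohort <- function(table, measures = NULL) {
  check_cohort_table(table)
  if (!is.null(measures)) table <- table[table$measure %in% measures, ]
  table <- table[is.finite(table$value), ]
  key <- interaction(table$group, table$week, table$layer, table$measure,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(table, key), function(d) {
    cbind(data.frame(group = d$group[1], week = d$week[1],
                     layer = d$layer[1], measure = d$measure[1],
                     stringsAsFactors = FALSE),
          five_number_summary(d$value))
  }))
  rownames(out) <- NULL
  out[order(out$measure, out$layer, out$week, out$group), ]
}

#' Run the full (measure, layer, week) comparison grid
#'
#' Applies [ancova_group_effect()] or the gated two-sample test to every
#' combination of endpoint, layer (as present in the table) and
#' follow-up week. No multiplicity correction is applied by default;
#' `fdr = TRUE` adds Benjamini-Hochberg adjusted p-values and flags
#' significance on those instead.
#'
#' @param table Long-format cohort table.
#' @param endpoints Data frame with columns `measure` and `test`
#'   (`"ancova"` or `"gated"`). Defaults to ANCOVA on every measure in
#'   the table except `thickness_pct`, which is gated.
#' @param weeks Follow-up weeks to test.
#' @param baseline_week Covariate week for ANCOVA endpoints.
#' @param alpha Significance level.
#' @param fdr Apply Benjamini-Hochberg across all cells.
#' @return Data frame of `StatResult` rows; zero rows for an empty
#'   endpoint list. Cells with insufficient data are skipped with a
#'   warning.
#' @export
run_full_comparison <- function(table, endpoints = NULL,
                                weeks = c(4, 8, 12), baseline_week = 0,
                                alpha = 0.05, fdr = FALSE) {
  check_cohort_table(table)
  if (is.null(endpoints)) {
    ms <- unique(table$measure)
    endpoints <- data.frame(
      measure = ms,
      test = ifelse(ms == "thickness_pct", "gated", "ancova"),
      stringsAsFactors = FALSE)
  }
  if (!nrow(endpoints))
    return(data.frame(measure = character(), layer = character(),
                      week = integer(), test_name = character(),
                      estimate = double(), statistic = double(),
                      p_value = double(), n_control = integer(),
                      n_t2d = integer(), n_dropped = integer(),
                      normality_p = double(), significant = logical()))
  res <- list()
  for (e in seq_len(nrow(endpoints))) {
    ms <- endpoints$measure[e]
    lys <- unique(table$layer[table$measure == ms])
    for (ly in lys) for (wk in weeks) {
      r <- tryCatch({
        if (endpoints$test[e] == "ancova") {
          ancova_group_effect(table, ms, ly, wk,
                              baseline_week = baseline_week, alpha = alpha)
        } else {
          sub <- table[table$measure == ms & table$layer == ly &
                         table$week == wk, ]
          r <- suppressWarnings(gated_two_sample_test(
            sub$value[sub$group == "control"],
            sub$value[sub$group == "T2D"], alpha = alpha))
          r$measure <- ms; r$layer <- ly; r$week <- wk
          r
        }
      }, error = function(err) {
        warning(sprintf("skipping %s/%s week %s: %s",
                        ms, ly, wk, conditionMessage(err)), call. = FALSE)
        NULL
      })
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(run_full_comparison(table, endpoints[0, ]))
  if (fdr) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted <= alpha
  }
  rownames(out) <- NULL
  out
}
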