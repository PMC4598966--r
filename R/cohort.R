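#' Eligibility filter on a functional score
#'
#' Keeps records whose score is at or above the threshold. The default
#' threshold 39.93 is the population-mean self-care domain score of the
#' disability instrument used to define need for home nursing care (domain
#' scores run 0--100, higher meaning worse functioning).
#'
#' @param records data frame containing `score_col`.
#' @param threshold eligibility cutoff; records with `score >= threshold`
#'   are kept.
#' @param score_col name of the score column.
#' @return the eligible subset of `records`.
#' @export
filter_eligible <- function(records, threshold = 39.93, score_col = "score") {
  s <- records[[score_col]]
  if (is.null(s))
    stop_spaccess("no column '%s' in records", score_col,
                  class = "spaccess_validation_error")
  if (length(s) && (anyNA(s) || any(s < 0 | s > 100)))
    stop_spaccess("scores must lie in [0, 100]",
                  class = "spaccess_validation_error")
  records[s >= threshold, , drop = FALSE]
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p), method = method),
            class = "spaccess_test")
}

#' @export
print.spaccess_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %s, p %.4g%s\n", x$method, x$statistic,
              format(x$df), x$p_value, p_stars(x$p_value)))
  invisible(x)
}

p_stars <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 0.001) " ***" else if (p < 0.01) " **" else if (p < 0.05) " *" else ""
}

as_count_matrix <- function(tab) {
  m <- as.matrix(tab)
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m)))
    stop_spaccess("contingency table must hold nonnegative integer counts",
                  class = "spaccess_validation_error")
  m
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic (no continuity correction), df =
#' (rows-1)(cols-1), p from the chi-square distribution.
#'
#' @param tab matrix or data frame of nonnegative integer counts, at least
#'   2 x 2.
#' @return a test result: `statistic`, `df`, `p_value`, `method`.
#' @export
pearson_chi2 <- function(tab) {
  m <- as_count_matrix(tab)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_spaccess("contingency table must be at least 2x2",
                  class = "spaccess_validation_error")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_spaccess("zero row or column marginal: expected counts undefined",
                  class = "spaccess_validation_error")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  test_result(ht$statistic, ht$parameter, ht$p.value, "pearson-chi2")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-ordering rule: the sum of
#' hypergeometric probabilities of all tables with the same margins that are
#' no more probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return a test result (`df` is `NA`: the test is exact).
#' @export
fisher_exact_2x2 <- function(tab) {
  m <- as_count_matrix(tab)
  if (!all(dim(m) == c(2, 2)))
    stop_spaccess("fisher_exact_2x2 requires a 2x2 table",
                  class = "spaccess_validation_error")
  ht <- stats::fisher.test(m)
  test_result(NA_real_, NA_real_, ht$p.value, "fisher-exact")
}

#' Two-sample t test from summary statistics
#'
#' Computes the t statistic from group means, standard deviations and sizes,
#' as needed when only a printed summary table is available. `pooled` uses
#' the df-weighted pooled variance with `n_a + n_b - 2` degrees of freedom;
#' `welch` uses the Welch--Satterthwaite statistic and df.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`sd >= 0`,
#'   `n >= 2`).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return a test result with two-sided p.
#' @examples
#' two_sample_t(75.61, 12.0, 5627, 72.88, 11.7, 956)  # t = 6.53
#' @export
two_sample_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (sd_a < 0 || sd_b < 0 || n_a < 2 || n_b < 2)
    stop_spaccess("need sd >= 0 and n >= 2 in both groups",
                  class = "spaccess_validation_error")
  diff <- mean_a - mean_b
  if (sd_a == 0 && sd_b == 0) {
    if (diff == 0)
      return(test_result(0, n_a + n_b - 2, 1, paste0("t-", variant)))
    stop_spaccess("zero variance in both groups with unequal means",
                  class = "spaccess_degenerate_variance_error")
  }
  if (variant == "pooled") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- diff / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), paste0("t-", variant))
}

#' Cohort comparison report from printed tables
#'
#' Reproduces a demographics-table comparison between two regions from
#' contingency rows (per categorical variable) and summary-statistic rows
#' (per continuous variable). Categorical variables use the uncorrected
#' Pearson chi-square, switching automatically to Fisher's exact test for
#' 2x2 tables with any expected cell below 5 (the conventional rule).
#' Continuous variables use the two-sample t from summaries.
#'
#' @param contingency data frame with columns
#'   `variable, level, count_a, count_b`, one row per level; or `NULL`.
#' @param summaries data frame with columns
#'   `variable, mean_a, sd_a, n_a, mean_b, sd_b, n_b`; or `NULL`.
#' @param t_variant t-test variant, see [two_sample_t()].
#' @return a `cohort_comparison` data frame: `variable`, `method`,
#'   `statistic`, `df`, `p_value`, `stars`.
#' @export
cohort_compare <- function(contingency = NULL, summaries = NULL,
                           t_variant = "pooled") {
  rows <- list()
  if (!is.null(contingency)) {
    need <- c("variable", "level", "count_a", "count_b")
    if (!all(need %in% names(contingency)))
      stop_spaccess("contingency input needs columns %s",
                    paste(need, collapse = ","),
                    class = "spaccess_validation_error")
    if (nrow(contingency) == 0)
      stop_spaccess("contingency input has no rows",
                    class = "spaccess_validation_error")
    for (v in unique(contingency$variable)) {
      sub <- contingency[contingency$variable == v, ]
      m <- as_count_matrix(sub[, c("count_a", "count_b")])
      exp_min <- min(outer(rowSums(m), colSums(m)) / sum(m))
      res <- if (all(dim(m) == 2) && exp_min < 5) fisher_exact_2x2(m)
             else pearson_chi2(m)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, method = res$method, statistic = res$statistic,
        df = res$df, p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(summaries)) {
    need <- c("variable", "mean_a", "sd_a", "n_a", "mean_b", "sd_b", "n_b")
    if (!all(need %in% names(summaries)))
      stop_spaccess("summary input needs columns %s",
                    paste(need, collapse = ","),
                    class = "spaccess_validation_error")
    for (i in seq_len(nrow(summaries))) {
      s <- summaries[i, ]
      res <- two_sample_t(s$mean_a, s$sd_a, s$n_a, s$mean_b, s$sd_b, s$n_b,
                          variant = t_variant)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = s$variable, method = res$method, statistic = res$statistic,
        df = res$df, p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop_spaccess("nothing to compare: both inputs empty",
                  class = "spaccess_validation_error")
  out <- do.call(rbind, rows)
  out$stars <- trimws(vapply(out$p_value, p_stars, character(1)))
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  d <- as.data.frame(x)
  d$statistic <- signif(d$statistic, 4)
  d$p_value <- signif(d$p_value, 4)
  print.data.frame(d, row.names = FALSE)
  cat("stars: * p<0.05, ** p<0.01, *** p<0.001\n")
  invisible(x)
}
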