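#' Standard deviation from an interquartile range width
#'
#' Under a normal distribution the interquartile range spans about 1.35
#' standard deviations (2 * qnorm(0.75) = 1.349), so sigma is approximated
#' by the IQR width divided by 1.35. This is the convention used to put
#' median/IQR summaries on a common footing with mean/SD summaries when
#' computing effect sizes across studies.
#'
#' @param iqr_width nonnegative IQR width (Q3 - Q1).
#' @return approximate standard deviation.
#' @export
sigma_from_iqr <- function(iqr_width) {
  if (any(iqr_width < 0)) stop("IQR width must be nonnegative")
  iqr_width / 1.35
}

#' Cohen's d from two group summaries
#'
#' Standardized difference `d = (center1 - center2) / s_pooled` with the
#' pooled SD taken as the simple two-group root mean of variances,
#' `sqrt((sd1^2 + sd2^2) / 2)`. Medians may substitute for means when a
#' study reports only medians; pass SDs derived via [sigma_from_iqr()] in
#' that case and record it with `sd_source`.
#'
#' @param center1,center2 group centers (means, or medians standing in).
#' @param sd1,sd2 group standard deviations (>= 0, not both 0).
#' @param sd_source "reported_sd" or "iqr_approx" provenance tag.
#' @return an `effect_size` list: `d`, `classification`, `group1`,
#'   `group2`, `sd_source`.
#' @export
cohens_d <- function(center1, sd1, center2, sd2,
                     sd_source = c("reported_sd", "iqr_approx")) {
  sd_source <- match.arg(sd_source)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) {
    if (center1 == center2) {
      d <- 0
    } else {
      stop("zero pooled SD with unequal centers: infinite effect size")
    }
  } else {
    d <- (center1 - center2) / pooled
  }
  structure(list(d = d, classification = classify_effect(d),
                 group1 = c(center = center1, sd = sd1),
                 group2 = c(center = center2, sd = sd2),
                 sd_source = sd_source),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.2f (%s)\n", x$d, x$classification))
  invisible(x)
}

#' Classify the magnitude of an effect size
#'
#' Conventional |d| thresholds: below 0.2 negligible, 0.2 small, 0.5
#' moderate, 0.8 or greater large.
#' @param d finite Cohen's d (vectorized).
#' @return character vector.
#' @export
classify_effect <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite")
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "moderate", "large")) |>
    as.character()
}

#' Compare two samples with a Wilcoxon test and Bonferroni correction
#'
#' Runs a Shapiro-Wilk normality check on each sample (reported, not
#' enforced), then a Wilcoxon signed-rank test (paired) or rank-sum test
#' (unpaired), and Bonferroni-adjusts the p-value for `n_comparisons`
#' simultaneous tests. The default of three matches the three main
#' comparisons of the manual-segmentation analysis (inter-individual,
#' intra-individual, and meshing-method impact).
#'
#' @param x,y numeric samples (length >= 3; equal lengths when paired).
#' @param paired logical.
#' @param n_comparisons family size for the Bonferroni correction.
#' @return list: `statistic`, `p_value`, `p_adjusted`, `paired`,
#'   `normality_p` (length-2), `n`.
#' @export
compare_groups <- function(x, y, paired = FALSE, n_comparisons = 3) {
  if (length(x) < 3 || length(y) < 3) stop("need at least 3 values per group")
  if (paired && length(x) != length(y))
    stop("paired comparison requires equal lengths")
  shap <- function(v) {
    v <- v[is.finite(v)]
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000)
      return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            exact = FALSE))
  p_adj <- min(1, wt$p.value * n_comparisons)
  if (paired && all(x == y)) p_adj <- 1  # degenerate no-difference case
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = p_adj, paired = paired,
       normality_p = c(x = shap(x), y = shap(y)),
       n = c(length(x), length(y)))
}

#' Median / IQR summary of a metric sample
#'
#' Quartiles use linear interpolation (quantile type 7, the R default).
#' @param values non-empty numeric vector.
#' @param label summary label.
#' @return a `metric_summary`: `median`, `iqr_low`, `iqr_high`, `n`,
#'   `label`.
#' @export
summarize_metric <- function(values, label = "") {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no values to summarize")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(median = q[2], iqr_low = q[1], iqr_high = q[3],
                 n = length(values), label = label),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("%s: %.2f (IQR %.2f-%.2f), n = %d\n",
              if (nzchar(x$label)) x$label else "summary",
              x$median, x$iqr_low, x$iqr_high, x$n))
  invisible(x)
}

#' Cross-study effect sizes from printed summary statistics
#'
#' Computes Cohen's d between a reference study summarized as
#' median (IQR) and comparison studies summarized as mean (SD), using
#' sigma = IQR width / 1.35 for the median/IQR side and the two-group
#' pooled SD. This is how segmentation-variability results reported in
#' different formats across the prostate TRUS literature are put on a
#' common scale.
#'
#' @param summaries data frame with columns `comparison`, `study`,
#'   `ref_center`, `ref_iqr_low`, `ref_iqr_high`, `ref_n`, `study_center`,
#'   `study_sd`, `study_n`, and logical `report_magnitude` (report |d|).
#' @return the input with columns `d` (rounded to 2 decimals, magnitude
#'   where flagged), `d_raw` and `classification` appended.
#' @export
effect_size_table <- function(summaries) {
  need <- c("comparison", "study", "ref_center", "ref_iqr_low",
            "ref_iqr_high", "study_center", "study_sd")
  if (!all(need %in% names(summaries)))
    stop("summary table missing columns: ",
         paste(setdiff(need, names(summaries)), collapse = ", "))
  d_raw <- vapply(seq_len(nrow(summaries)), function(i) {
    r <- summaries[i, ]
    s_ref <- sigma_from_iqr(r$ref_iqr_high - r$ref_iqr_low)
    cohens_d(r$ref_center, s_ref, r$study_center, r$study_sd,
             sd_source = "iqr_approx")$d
  }, numeric(1))
  mag <- if ("report_magnitude" %in% names(summaries))
    as.logical(summaries$report_magnitude) else rep(FALSE, nrow(summaries))
  summaries$d_raw <- d_raw
  summaries$d <- round(ifelse(mag, abs(d_raw), d_raw), 2)
  summaries$classification <- classify_effect(d_raw)
  summaries
}
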