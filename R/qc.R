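#' 3'/5' ratio of a control transcript
#'
#' Classic Affymetrix RNA-quality indicator: the ratio of the summarized
#' probe intensity at the 3' end of a housekeeping transcript (GAPDH, ACTB)
#' over the 5' end.  Degraded RNA loses 5' signal, inflating the ratio;
#' values above ~3 are conventionally suspect.
#'
#' @param intensity_3p,intensity_5p Positive summarized probe intensities.
#' @return The 3'/5' quotient.
#' @export
three_prime_ratio <- function(intensity_3p, intensity_5p) {
  stopifnot(is.numeric(intensity_3p), is.numeric(intensity_5p))
  if (any(intensity_3p <= 0) || any(intensity_5p <= 0))
    stop("probe intensities must be positive", call. = FALSE)
  intensity_3p / intensity_5p
}

#' RNA degradation slope
#'
#' Ordinary least-squares slope of mean probe intensity against probe
#' position index 0..k-1 (5' to 3'), the summary statistic of the classic
#' per-sample RNA degradation plot.  Strongly positive slopes indicate 3'
#' bias from degraded input RNA.
#'
#' @param mean_intensity_by_position Numeric vector of mean intensities
#'   ordered by probe position, length >= 3.
#' @return OLS slope (intensity units per position index).
#' @export
rna_degradation_slope <- function(mean_intensity_by_position) {
  y <- as.numeric(mean_intensity_by_position)
  if (length(y) < 3L)
    stop("need at least 3 probe positions", call. = FALSE)
  x <- seq_along(y) - 1
  unname(stats::coef(stats::lm(y ~ x))[["x"]])
}

#' Default per-sample QC rule set
#'
#' A configurable rule table implementing the Affymetrix-style per-sample
#' quality panel: average probe intensity, counts of negative and >16-bit
#' (65535) intensity values, poly-A and labelled-cRNA spike-in controls,
#' GAPDH and ACTB 3'/5' ratios, center of intensity, positive/negative
#' border control means, and the RNA degradation slope.  Ratio bounds follow
#' standard Affymetrix guidance (3'/5' <= 3); negative and overflow values
#' are not tolerated; spike-in booleans are required `TRUE`; the remaining
#' numeric bounds are pragmatic defaults on the log2 scale and are meant to
#' be overridden per cohort (e.g. via [cohort_qc_rules()]).
#'
#' @return Data.frame with columns `metric`, `type` (`"range"` or `"flag"`),
#'   `min`, `max`, `enabled`.  `NA` bounds are unbounded.
#' @export
default_qc_rules <- function() {
  data.frame(
    metric = c("avg_intensity", "n_negative_values", "n_overflow_values",
               "polyA_spike_ok", "cRNA_spike_ok",
               "gapdh_3p5p_ratio", "actb_3p5p_ratio",
               "center_of_intensity", "pos_border_mean", "neg_border_mean",
               "rna_deg_slope"),
    type = c("range", "range", "range", "flag", "flag",
             "range", "range", "range", "range", "range", "range"),
    min = c(5,  0, 0, NA, NA, NA, NA, 4,  6, NA, NA),
    max = c(11, 0, 0, NA, NA, 3,  3,  10, NA, 4,  3),
    enabled = TRUE,
    stringsAsFactors = FALSE)
}

#' Derive cohort-adaptive intensity bounds
#'
#' Replaces the `avg_intensity`, `center_of_intensity` and border-control
#' bounds of a rule set with mean +/- 3 SD computed over the cohort's own
#' metric table, the usual way array-level outliers are flagged when no
#' absolute guidance exists.
#'
#' @param metrics Data.frame of per-sample QC metrics (one row per sample).
#' @param rules Rule set to update (default [default_qc_rules()]).
#' @param k_sd Number of SDs around the cohort mean (default 3).
#' @return Updated rule data.frame.
#' @export
cohort_qc_rules <- function(metrics, rules = default_qc_rules(), k_sd = 3) {
  for (m in c("avg_intensity", "center_of_intensity",
              "pos_border_mean", "neg_border_mean")) {
    if (!m %in% names(metrics)) next
    mu <- mean(metrics[[m]])
    s <- stats::sd(metrics[[m]])
    i <- rules$metric == m
    rules$min[i] <- mu - k_sd * s
    rules$max[i] <- mu + k_sd * s
  }
  rules
}

#' Evaluate QC rules for one sample
#'
#' Pure function of the metrics and rules: every enabled rule gets a
#' verdict, the sample passes overall iff all enabled rules pass, and the
#' order of rules never changes the outcome.
#'
#' @param metrics Named list or one-row data.frame of QC metric values for
#'   one sample; must include `sample_id` and a value for every enabled
#'   rule's metric.
#' @param rules Rule data.frame as from [default_qc_rules()].
#' @return A `qc_report`: list with `sample_id`, `verdicts` (named logical
#'   per enabled rule), `pass` (overall) and `failure_reasons`.
#' @export
evaluate_qc <- function(metrics, rules = default_qc_rules()) {
  metrics <- as.list(metrics)
  rules <- rules[rules$enabled, , drop = FALSE]
  if (any(bad <- !is.na(rules$min) & !is.na(rules$max) &
            rules$min > rules$max))
    stop("ill-ordered bounds (min > max) for rule(s): ",
         paste(rules$metric[bad], collapse = ", "), call. = FALSE)
  missing <- setdiff(rules$metric, names(metrics))
  if (length(missing))
    stop("metric(s) missing for enabled rule(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  verdicts <- vapply(seq_len(nrow(rules)), function(i) {
    v <- metrics[[rules$metric[i]]]
    if (rules$type[i] == "flag") return(isTRUE(v))
    (is.na(rules$min[i]) || v >= rules$min[i]) &&
      (is.na(rules$max[i]) || v <= rules$max[i])
  }, logical(1))
  names(verdicts) <- rules$metric
  structure(
    list(sample_id = if (!is.null(metrics$sample_id))
           as.character(metrics$sample_id) else NA_character_,
         verdicts = verdicts,
         pass = all(verdicts),
         failure_reasons = names(verdicts)[!verdicts]),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s\n", x$sample_id,
              if (x$pass) "PASS" else
                paste0("FAIL (", paste(x$failure_reasons, collapse = ", "),
                       ")")))
  invisible(x)
}

#' Evaluate QC for every sample of a metrics table
#'
#' @param metrics_table Data.frame, one row per sample, with `sample_id`
#'   and metric columns.
#' @param rules Rule data.frame.
#' @return Named list of `qc_report`s (by sample id).
#' @export
evaluate_qc_table <- function(metrics_table, rules = default_qc_rules()) {
  stopifnot(is.data.frame(metrics_table), "sample_id" %in% names(metrics_table))
  reports <- lapply(seq_len(nrow(metrics_table)), function(i)
    evaluate_qc(metrics_table[i, , drop = FALSE], rules))
  names(reports) <- as.character(metrics_table$sample_id)
  reports
}

#' Remove QC-failing samples from a cohort
#'
#' Samples that fail QC are removed before any downstream analysis.
#' Surviving samples keep their original order; removed sample ids are
#' reported via `message()`.
#'
#' @param cohort An [expression_matrix].
#' @param reports List of `qc_report`s covering every cohort sample.
#' @return The cohort restricted to passing samples (possibly with zero
#'   samples; downstream stages then error).
#' @export
filter_cohort <- function(cohort, reports) {
  stopifnot(inherits(cohort, "expression_matrix"))
  ids <- vapply(reports, `[[`, character(1), "sample_id")
  missing <- setdiff(colnames(cohort$values), ids)
  if (length(missing))
    stop("no QC report for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pass <- vapply(reports, `[[`, logical(1), "pass")
  keep <- colnames(cohort$values)[colnames(cohort$values) %in% ids[pass]]
  removed <- setdiff(colnames(cohort$values), keep)
  if (length(removed))
    message("QC removed ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  x <- cohort
  x$values <- x$values[, keep, drop = FALSE]
  x$annotations <- x$annotations[match(keep, x$annotations$sample_id), ,
                                 drop = FALSE]
  rownames(x$annotations) <- NULL
  x
}
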