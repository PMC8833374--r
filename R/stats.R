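#' Normal-range upper threshold from healthy reference scores
#'
#' The upper bound of the normal range for a pathway's activity is the mean
#' plus `k_sd` sample standard deviations (n-1 denominator) of the scores
#' measured in a healthy reference group; scores above it are called
#' abnormally high by [classify_abnormal()].
#'
#' @param ref_scores Numeric vector of log2-odds scores from healthy
#'   reference samples (>= 2 finite values).
#' @param k_sd Number of SDs above the mean (default 2).
#' @param pathway_name Optional pathway label carried in the result.
#' @return A `reference_threshold`: list with `pathway_name`, `ref_mean`,
#'   `ref_sd`, `upper` (= mean + k_sd * sd) and `n_ref`.
#' @export
normal_threshold <- function(ref_scores, k_sd = 2,
                             pathway_name = NA_character_) {
  ref_scores <- as.numeric(ref_scores)
  if (length(ref_scores) < 2L || !all(is.finite(ref_scores)))
    stop("need at least 2 finite reference scores (SD is undefined ",
         "otherwise)", call. = FALSE)
  m <- mean(ref_scores)
  s <- stats::sd(ref_scores)
  structure(
    list(pathway_name = pathway_name, ref_mean = m, ref_sd = s,
         upper = m + k_sd * s, n_ref = length(ref_scores)),
    class = "reference_threshold")
}

#' Classify pathway scores against normal-range thresholds
#'
#' A score is `abnormal_high` iff it lies strictly above the pathway's
#' upper threshold; a score exactly at the threshold is `normal`.  Note a
#' `normal` call says only that the activity is within the healthy
#' reference range; a low or negative log2-odds score never means the
#' pathway is biologically inactive.
#'
#' @param scores Named numeric vector, pathway -> log2-odds score.
#' @param thresholds Named list of `reference_threshold`s covering every
#'   scored pathway.
#' @return Named character vector, pathway -> `"abnormal_high"`/`"normal"`.
#' @export
classify_abnormal <- function(scores, thresholds) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  missing <- setdiff(names(scores), names(thresholds))
  if (length(missing))
    stop("no threshold for pathway(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- vapply(names(scores), function(p) {
    if (scores[[p]] > thresholds[[p]]$upper) "abnormal_high" else "normal"
  }, character(1))
  names(out) <- names(scores)
  out
}

new_comparison_result <- function(method, statistic, p_value, alternative,
                                  n1, n2, ties_present, estimate = NA_real_) {
  structure(
    list(method = method, statistic = unname(statistic),
         p_value = unname(p_value), alternative = alternative,
         n1 = n1, n2 = n2, ties_present = ties_present,
         estimate = unname(estimate)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %g, p = %.4g (%s)\n",
              x$method, x$statistic, x$p_value, x$alternative))
  invisible(x)
}

map_alternative <- function(alternative) {
  alternative <- match.arg(alternative, c("two_sided", "less", "greater"))
  list(spec = alternative,
       r = switch(alternative, two_sided = "two.sided", alternative))
}

#' Mann-Whitney U test between two groups of pathway scores
#'
#' Rank-sum comparison of two independent groups, the study's default test
#' for comparing pathway activity scores across groups.  The U statistic is
#' computed from mid-ranks; the p-value is exact (full permutation null of
#' the rank sum) when n1 + n2 <= 20 and the pooled data are tie-free,
#' otherwise the normal approximation with continuity correction is used.
#' `alternative = "less"` means group A is stochastically smaller than
#' group B.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @return A `comparison_result` with method `"mann_whitney_exact"` or
#'   `"mann_whitney_normal_approx"`, the U statistic of group A, the
#'   p-value, group sizes, and a ties flag.
#' @export
mann_whitney <- function(group_a, group_b, alternative = "two_sided") {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 1L || length(group_b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  alt <- map_alternative(alternative)
  n1 <- length(group_a); n2 <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- (n1 + n2) <= 20L && !ties
  # U of group A from mid-ranks (equals wilcox.test's W for tie-free data,
  # and remains well-defined under ties)
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alt$r,
                       exact = exact, correct = TRUE))
  new_comparison_result(
    method = if (exact) "mann_whitney_exact" else "mann_whitney_normal_approx",
    statistic = u, p_value = ht$p.value, alternative = alt$spec,
    n1 = n1, n2 = n2, ties_present = ties)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided by default, as used for within-patient comparisons of matched
#' blood / lymph-node / tumor-infiltrate samples.  Zero differences are
#' dropped (with a message recording the count).  The p-value is exact
#' (enumeration null over sign patterns) when the number of non-zero
#' differences is <= 15 and their absolute values are tie-free, otherwise a
#' normal approximation with continuity correction is used.  If every
#' difference is zero the result is degenerate with p = 1 and a warning.
#'
#' @param x,y Equal-length numeric vectors of paired measurements.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @return A `comparison_result` with the signed-rank statistic W
#'   (sum of ranks of positive differences).
#' @export
wilcoxon_paired <- function(x, y, alternative = "two_sided") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be equal-length, non-empty", call. = FALSE)
  alt <- map_alternative(alternative)
  d <- x - y
  n_zero <- sum(d == 0)
  if (n_zero > 0)
    message("dropping ", n_zero, " zero difference(s)")
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; degenerate result with p = 1",
            call. = FALSE)
    return(new_comparison_result("wilcoxon_signed_rank", statistic = 0,
                                 p_value = 1, alternative = alt$spec,
                                 n1 = length(x), n2 = length(x),
                                 ties_present = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- length(d) <= 15L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = alt$r, exact = exact,
                       correct = TRUE))
  new_comparison_result(
    method = "wilcoxon_signed_rank",
    statistic = ht$statistic, p_value = ht$p.value, alternative = alt$spec,
    n1 = length(x), n2 = length(x), ties_present = ties)
}

#' Pearson correlation test between two pathway score vectors
#'
#' Two-sided test of zero correlation via the t transform with n - 2
#' degrees of freedom, as used for pathway-pathway correlation across
#' samples (always within comparable quantities, never pooling raw scores
#' of different pathways into one statistic).
#'
#' @param x,y Equal-length numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return A `comparison_result` with `estimate` = r and the two-sided
#'   p-value.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must be equal-length with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  new_comparison_result(
    method = "pearson", statistic = ht$statistic, p_value = ht$p.value,
    alternative = "two_sided", n1 = length(x), n2 = length(y),
    ties_present = FALSE, estimate = ht$estimate)
}

#' Match a sample's pathway-activity profile to reference cell types
#'
#' Raw log2-odds scores are not comparable across pathways (each pathway has
#' its own dynamic range), so each pathway is first standardized (centered
#' and scaled) using the mean and SD of that pathway's scores across the
#' pooled reference set; the sample is transformed with the same per-pathway
#' parameters.  Similarity to each reference is then the Pearson correlation
#' of the standardized vectors; references are ranked by similarity with
#' deterministic ties broken by reference label order.
#'
#' @param profile Named numeric vector pathway -> log2-odds for the sample,
#'   or an `activity_profile`.
#' @param references Named list (label -> named numeric vector or
#'   `activity_profile`) of reference profiles scored by the same frozen
#'   models.
#' @return A `profile_match`: list with `sample_id`, `best_label`,
#'   `similarity` (of the best match) and `ranking` (data.frame label /
#'   similarity / rank).
#' @export
match_profile <- function(profile, references) {
  as_vec <- function(p) {
    if (inherits(p, "activity_profile"))
      vapply(p$scores, `[[`, numeric(1), "log2_odds")
    else p
  }
  sample_id <- if (inherits(profile, "activity_profile"))
    profile$sample_id else NA_character_
  v <- as_vec(profile)
  stopifnot(is.numeric(v), !is.null(names(v)), length(references) >= 1L,
            !is.null(names(references)))
  refs <- lapply(references, as_vec)
  common <- Reduce(intersect, c(list(names(v)), lapply(refs, names)))
  if (length(common) < 2L)
    stop("fewer than 2 pathways shared between profile and references",
         call. = FALSE)
  refmat <- vapply(refs, function(r) r[common], numeric(length(common)))
  mu <- rowMeans(refmat)
  s <- apply(refmat, 1L, stats::sd)
  s[s == 0] <- 1                      # constant pathway: center only
  z_ref <- (refmat - mu) / s
  z_sam <- (v[common] - mu) / s
  sim <- vapply(seq_along(refs), function(j)
    stats::cor(z_sam, z_ref[, j]), numeric(1))
  ranking <- data.frame(label = names(references), similarity = sim,
                        stringsAsFactors = FALSE)
  ord <- order(-ranking$similarity, ranking$label)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(
    list(sample_id = sample_id, best_label = ranking$label[1],
         similarity = ranking$similarity[1], ranking = ranking),
    class = "profile_match")
}

#' @export
print.profile_match <- function(x, ...) {
  cat(sprintf("<profile_match> %s -> %s (r = %.3f)\n",
              x$sample_id, x$best_label, x$similarity))
  invisible(x)
}

#' Rank-based AUC of scores against binary truth
#'
#' Probability that a randomly chosen positive sample scores higher than a
#' randomly chosen negative one (Mann-Whitney formulation, mid-ranks for
#' ties).  Used to quantify how well calibrate-then-score recovers planted
#' activation truth.
#'
#' @param scores Numeric vector.
#' @param truth Logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), any(truth), any(!truth))
  r <- rank(scores)
  n1 <- sum(truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * sum(!truth))
}
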