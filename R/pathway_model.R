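#' Calibrate a Bayesian-network pathway activity model
#'
#' Fits the two-layer Bayesian network that links a hidden binary pathway
#' state (transcription factor active / inactive) to binary evidence from
#' each target gene.  Per gene, expression is discretized at the median of
#' the gene's values over *all* training samples (active and inactive
#' pooled); the conditional probabilities of observing a value above that
#' cutoff given each hidden state are estimated by pseudocount-smoothed
#' frequencies.  The returned model is frozen: it is applied to new samples
#' without further adaptation, as in the calibrate-once-then-freeze protocol
#' this assay family uses.
#'
#' Down-regulated target genes need no special handling: their
#' `p_high_given_active` simply calibrates below `p_high_given_inactive`.
#'
#' @param train An [expression_matrix] of training samples.
#' @param labels Character vector (one per training sample, in column
#'   order), each `"active"` or `"inactive"`.
#' @param gene_set A [target_gene_set].
#' @param prior_active Prior probability that the pathway is active, in
#'   (0,1).  Default 0.5 (log2 prior odds 0).
#' @param pseudocount Positive Laplace pseudocount keeping all conditional
#'   probabilities strictly inside (0,1).  Default 1.
#' @return A `frozen_pathway_model`: pathway name, prior, per-gene
#'   parameters (direction, cutoff, conditional probabilities), and
#'   calibration metadata.
#' @export
calibrate_model <- function(train, labels, gene_set, prior_active = 0.5,
                            pseudocount = 1) {
  stopifnot(inherits(train, "expression_matrix"),
            inherits(gene_set, "target_gene_set"),
            is.numeric(prior_active), length(prior_active) == 1L,
            prior_active > 0, prior_active < 1,
            is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount > 0)
  labels <- as.character(labels)
  if (length(labels) != ncol(train$values))
    stop("need one label per training sample", call. = FALSE)
  if (!all(labels %in% c("active", "inactive")))
    stop("labels must be 'active' or 'inactive'", call. = FALSE)
  n_active <- sum(labels == "active")
  n_inactive <- sum(labels == "inactive")
  if (n_active < 2L || n_inactive < 2L)
    stop("calibration needs at least 2 samples per label class (got ",
         n_active, " active, ", n_inactive, " inactive)", call. = FALSE)

  genes <- gene_set$genes
  present <- genes$gene_id %in% rownames(train$values)
  if (any(!present)) {
    warning("dropping ", sum(!present), " gene(s) absent from training ",
            "data for pathway '", gene_set$pathway_name, "': ",
            paste(genes$gene_id[!present], collapse = ", "), call. = FALSE)
    genes <- genes[present, , drop = FALSE]
  }
  if (nrow(genes) == 0L)
    stop("no gene of pathway '", gene_set$pathway_name,
         "' is present in the training data", call. = FALSE)

  params <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    v <- train$values[g, ]
    if (diff(range(v)) == 0) return(NULL)           # degenerate cutoff
    cutoff <- stats::median(v)
    high <- v > cutoff
    list(gene_id = g,
         direction = genes$direction[i],
         cutoff = cutoff,
         p_high_given_active =
           (sum(high[labels == "active"]) + pseudocount) /
           (n_active + 2 * pseudocount),
         p_high_given_inactive =
           (sum(high[labels == "inactive"]) + pseudocount) /
           (n_inactive + 2 * pseudocount))
  })
  dropped <- genes$gene_id[vapply(params, is.null, logical(1))]
  if (length(dropped))
    warning("dropping gene(s) with constant training values (degenerate ",
            "cutoff) for pathway '", gene_set$pathway_name, "': ",
            paste(dropped, collapse = ", "), call. = FALSE)
  params <- params[!vapply(params, is.null, logical(1))]
  if (length(params) == 0L)
    stop("no usable gene left after calibration for pathway '",
         gene_set$pathway_name, "'", call. = FALSE)
  gene_params <- do.call(rbind, lapply(params, function(p)
    data.frame(p, stringsAsFactors = FALSE)))
  rownames(gene_params) <- NULL

  structure(
    list(pathway_name = gene_set$pathway_name,
         prior_active = prior_active,
         gene_params = gene_params,
         frozen = TRUE,
         calibration_meta = list(
           n_active = n_active, n_inactive = n_inactive,
           pseudocount = pseudocount,
           date = format(Sys.Date()))),
    class = "frozen_pathway_model")
}

#' @export
print.frozen_pathway_model <- function(x, ...) {
  cat(sprintf(
    "<frozen_pathway_model> %s: %d genes, prior P(active) = %g%s\n",
    x$pathway_name, nrow(x$gene_params), x$prior_active,
    if (isTRUE(x$frozen)) ", frozen" else " (NOT frozen)"))
  invisible(x)
}

log2_odds_to_prob <- function(l) 1 / (1 + 2^(-l))

#' Score one sample with a frozen pathway model
#'
#' Computes the posterior probability that the pathway is active given the
#' sample's target-gene expression, and its log2 odds.  Evidence per gene is
#' binary (`value > cutoff`); by conditional independence the posterior odds
#' are the prior odds times the product of per-gene likelihood ratios.
#' Genes absent from the sample contribute a likelihood ratio of 1 and are
#' reported in `missing_genes`.  The log2 odds are clamped to [-60, 60] so
#' the probability never underflows to exactly 0 or 1.
#'
#' @param model A `frozen_pathway_model` (must have `frozen = TRUE`).
#' @param sample Named numeric vector of log2 expression values
#'   (names = gene ids), or a single-sample [expression_matrix] column
#'   extracted as such.
#' @param sample_id Optional sample label for the result.
#' @return A `pathway_score`: list with `sample_id`, `pathway_name`,
#'   `prob_active`, `log2_odds`, `n_genes_used`, `missing_genes`.
#' @export
score_sample <- function(model, sample, sample_id = NA_character_) {
  stopifnot(inherits(model, "frozen_pathway_model"))
  if (!isTRUE(model$frozen))
    stop("model for pathway '", model$pathway_name,
         "' is not frozen; refusing to score", call. = FALSE)
  stopifnot(is.numeric(sample))
  if (is.null(names(sample)))
    stop("sample must be a named gene -> value vector", call. = FALSE)

  gp <- model$gene_params
  obs <- gp$gene_id %in% names(sample)
  if (!any(obs))
    stop("no overlap between model genes and sample genes for pathway '",
         model$pathway_name, "'", call. = FALSE)

  l <- log2(model$prior_active) - log2(1 - model$prior_active)
  for (i in which(obs)) {
    high <- sample[[gp$gene_id[i]]] > gp$cutoff[i]
    lr <- if (high) {
      gp$p_high_given_active[i] / gp$p_high_given_inactive[i]
    } else {
      (1 - gp$p_high_given_active[i]) / (1 - gp$p_high_given_inactive[i])
    }
    l <- l + log2(lr)
  }
  l <- max(-60, min(60, l))
  structure(
    list(sample_id = sample_id,
         pathway_name = model$pathway_name,
         prob_active = log2_odds_to_prob(l),
         log2_odds = l,
         n_genes_used = sum(obs),
         missing_genes = gp$gene_id[!obs]),
    class = "pathway_score")
}

#' @export
print.pathway_score <- function(x, ...) {
  cat(sprintf("<pathway_score> %s %s: log2 odds %.3f (P = %.4f, %d genes)\n",
              x$pathway_name,
              if (is.na(x$sample_id)) "" else x$sample_id,
              x$log2_odds, x$prob_active, x$n_genes_used))
  invisible(x)
}

#' Reference posterior by brute-force joint enumeration
#'
#' Independent validation route for [score_sample()]: builds the full joint
#' probability table over the hidden pathway state and every observed
#' gene's binary evidence, then obtains the posterior by direct
#' marginalization.  Exponential in the number of genes, so intended for
#' models with few genes (<= ~12) in validation only.
#'
#' @inheritParams score_sample
#' @return Posterior probability that the pathway is active (numeric scalar,
#'   unclamped).
#' @export
score_sample_enumeration <- function(model, sample) {
  stopifnot(inherits(model, "frozen_pathway_model"), is.numeric(sample))
  gp <- model$gene_params[model$gene_params$gene_id %in% names(sample), ,
                          drop = FALSE]
  k <- nrow(gp)
  if (k == 0L) stop("no overlap between model genes and sample", call. = FALSE)
  if (k > 20L) stop("enumeration oracle limited to 20 genes", call. = FALSE)
  e_obs <- vapply(seq_len(k), function(i)
    sample[[gp$gene_id[i]]] > gp$cutoff[i], logical(1))
  joint <- c(active = 0, inactive = 0)
  for (code in 0:(2^k - 1)) {
    e <- as.logical(bitwAnd(bitwShiftR(code, 0:(k - 1)), 1L))
    if (!identical(e, e_obs)) next
    p_act <- model$prior_active *
      prod(ifelse(e, gp$p_high_given_active, 1 - gp$p_high_given_active))
    p_inact <- (1 - model$prior_active) *
      prod(ifelse(e, gp$p_high_given_inactive, 1 - gp$p_high_given_inactive))
    joint["active"] <- joint["active"] + p_act
    joint["inactive"] <- joint["inactive"] + p_inact
  }
  unname(joint["active"] / sum(joint))
}

#' Score a whole cohort with a set of frozen models
#'
#' Applies [score_sample()] for every model to every sample.  Each sample's
#' scores depend only on its own column, so cohort composition and sample
#' order never affect individual results.
#'
#' @param models List of `frozen_pathway_model` objects with unique pathway
#'   names.
#' @param cohort An [expression_matrix].
#' @return Named list (by sample id) of `activity_profile` objects, each
#'   holding that sample's per-pathway `pathway_score`s plus its annotation
#'   row.
#' @export
score_cohort <- function(models, cohort) {
  stopifnot(inherits(cohort, "expression_matrix"), length(models) >= 1L)
  if (ncol(cohort$values) < 1L)
    stop("cohort contains no samples to score", call. = FALSE)
  pw <- vapply(models, `[[`, character(1), "pathway_name")
  if (anyDuplicated(pw))
    stop("duplicate pathway names across models: ",
         paste(unique(pw[duplicated(pw)]), collapse = ", "), call. = FALSE)
  names(models) <- pw
  profiles <- lapply(colnames(cohort$values), function(s) {
    vec <- cohort$values[, s]
    names(vec) <- rownames(cohort$values)
    scores <- lapply(models, score_sample, sample = vec, sample_id = s)
    structure(
      list(sample_id = s, scores = scores,
           annotations =
             cohort$annotations[cohort$annotations$sample_id == s, ,
                                drop = FALSE]),
      class = "activity_profile")
  })
  names(profiles) <- colnames(cohort$values)
  profiles
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s\n", x$sample_id))
  for (s in x$scores)
    cat(sprintf("  %-14s %8.3f log2 odds\n", s$pathway_name, s$log2_odds))
  invisible(x)
}

#' Extract a samples x pathways log2-odds matrix from activity profiles
#'
#' @param profiles List of `activity_profile` objects (as returned by
#'   [score_cohort()]).
#' @return Numeric matrix, rows = samples, columns = pathways.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  pw <- names(profiles[[1]]$scores)
  m <- vapply(profiles, function(p)
    vapply(p$scores[pw], `[[`, numeric(1), "log2_odds"), numeric(length(pw)))
  m <- matrix(m, nrow = length(pw),
              dimnames = list(pw, unname(vapply(profiles, `[[`, character(1),
                                                "sample_id"))))
  t(m)
}

#' Qualitative PI3K pathway call from FOXO activity
#'
#' PI3K pathway activity is inferred inversely from the measured FOXO
#' transcription-factor activity, which is valid only in the absence of
#' cellular oxidative stress (oxidative stress activates FOXO independently
#' of PI3K).  The call is qualitative and relative to a supplied FOXO
#' reference score (for example a comparison sample's score): a FOXO score
#' above the reference implies lower PI3K activity and vice versa.  FOXO
#' scores themselves are always reported as FOXO activity, never relabeled
#' as PI3K activity.
#'
#' @param foxo_score FOXO log2-odds score of the sample.
#' @param reference FOXO log2-odds score of the comparison sample.
#' @param oxidative_stress Logical; `TRUE` invalidates the inverse
#'   inference.
#' @return One of `"pi3k_low"`, `"pi3k_high"`, `"indeterminate"`.
#' @export
infer_pi3k_from_foxo <- function(foxo_score, reference,
                                 oxidative_stress = FALSE) {
  stopifnot(is.numeric(foxo_score), length(foxo_score) == 1L,
            is.numeric(reference), length(reference) == 1L,
            is.logical(oxidative_stress), length(oxidative_stress) == 1L)
  if (isTRUE(oxidative_stress)) return("indeterminate")
  if (foxo_score > reference) return("pi3k_low")
  if (foxo_score < reference) return("pi3k_high")
  "indeterminate"
}

#' Write a frozen pathway model to a JSON file
#'
#' Versioned flat JSON holding every model field; [read_model_json()] is its
#' lossless inverse (scores round-trip bit-exactly).
#'
#' @param model A `frozen_pathway_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "frozen_pathway_model"))
  jsonlite::write_json(
    list(format = "stpscore_model", format_version = 1L,
         pathway_name = model$pathway_name,
         prior_active = model$prior_active,
         gene_params = model$gene_params,
         frozen = model$frozen,
         calibration_meta = model$calibration_meta),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a frozen pathway model from a JSON file
#'
#' @param path Path written by [write_model_json()].
#' @return A `frozen_pathway_model`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "stpscore_model"))
    stop("'", path, "' is not a pathway model file", call. = FALSE)
  structure(
    list(pathway_name = x$pathway_name,
         prior_active = x$prior_active,
         gene_params = as.data.frame(x$gene_params,
                                     stringsAsFactors = FALSE),
         frozen = isTRUE(x$frozen),
         calibration_meta = x$calibration_meta),
    class = "frozen_pathway_model")
}
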