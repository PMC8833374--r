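#' The six pathway-activity readouts
#'
#' Pathway names used throughout the CD4+ T-cell workflow.  `FOXO` is the
#' transcription-factor activity readout from which PI3K pathway activity
#' is inversely inferred (see [infer_pi3k_from_foxo()]); it is always
#' reported as FOXO activity.
#'
#' @return Character vector of the six pathway names.
#' @export
stp_pathways <- function() {
  c("FOXO", "NFkB", "JAK_STAT1_2", "JAK_STAT3", "TGFB", "Notch")
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
# R's default Mersenne-Twister / inversion streams are used, so identical
# seeds give bit-identical draws across platforms.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Construct a simulation scenario
#'
#' A scenario plants a per-pathway activation level `a` in [0, 1] for a
#' group of samples.  In the generator's linear Gaussian model, an
#' up-regulated target gene of pathway P takes value
#' `mu_g + delta * a_P + noise` (down-regulated genes subtract the shift),
#' so `a` is the ground truth every downstream stage is tested against.
#'
#' @param label Scenario label (e.g. `"resting"`, `"iTreg"`).
#' @param activation Named numeric vector pathway -> a in \[0, 1\].
#' @param n_samples Number of samples to draw.
#' @param delta Effect size: log2 expression shift of a target gene at
#'   full activation (a = 1).  Default 2 log2 units, a strong but
#'   realistic array effect.
#' @param sigma Per-gene Gaussian noise SD in log2 units.  Default 0.5,
#'   typical probe-level scatter after summarization.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(label, activation, n_samples, delta = 2,
                          sigma = 0.5) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(activation), !is.null(names(activation)),
            all(activation >= 0), all(activation <= 1),
            n_samples >= 1, delta > 0, sigma > 0)
  structure(list(label = label, activation = activation,
                 n_samples = n_samples, delta = delta, sigma = sigma),
            class = "scenario_spec")
}

# Per-scenario planted activation levels for the CD4+ T-cell study
# conditions.  Rows follow the qualitative direction anchors of the
# in vitro subset experiments: activation raises NFkB/JAK-STAT1/2/
# JAK-STAT3 and lowers FOXO and TGFB; Th1 raises NFkB and JAK-STAT1/2 over
# Th2 while Th2 keeps higher FOXO; suppressive iTreg cells combine high
# NFkB, JAK-STAT3, TGFB and Notch with reduced JAK-STAT1/2 and recovered
# FOXO; cancer-supernatant treatment partially reverts activation while
# strongly raising TGFB.
preset_activation_table <- function() {
  a <- rbind(
    resting           = c(0.80, 0.10, 0.10, 0.10, 0.30, 0.20),
    activated         = c(0.10, 0.70, 0.50, 0.55, 0.10, 0.20),
    Th1               = c(0.10, 0.90, 0.80, 0.55, 0.15, 0.20),
    Th2               = c(0.50, 0.40, 0.20, 0.55, 0.15, 0.20),
    Treg_resting      = c(0.50, 0.40, 0.35, 0.40, 0.30, 0.50),
    iTreg             = c(0.60, 0.95, 0.20, 0.90, 0.80, 0.90),
    activated_plus_SN = c(0.65, 0.25, 0.20, 0.30, 0.70, 0.20),
    healthy_blood     = c(0.70, 0.15, 0.10, 0.10, 0.20, 0.10))
  colnames(a) <- stp_pathways()
  # Patient compartments are mixtures of a healthy-blood background with an
  # iTreg component; tumor infiltrate carries the largest Treg fraction,
  # peripheral blood the smallest, so blood shows attenuated and TIL
  # pronounced iTreg signatures.
  mix <- function(f) (1 - f) * a["healthy_blood", ] + f * a["iTreg", ]
  rbind(a,
        patient_blood = mix(0.25),
        patient_LN    = mix(0.45),
        patient_TIL   = mix(0.85))
}

#' Scenario presets for the CD4+ T-cell study conditions
#'
#' Returns one [scenario_spec] per emulated condition: resting and
#' activated CD4+ T cells, Th1/Th2, resting and suppressive (iTreg) Treg
#' cells, supernatant-treated activated cells, healthy-donor blood, and
#' patient blood / lymph-node / tumor-infiltrate compartments (modelled as
#' healthy-blood/iTreg mixtures with increasing Treg fraction).  The
#' planted activation orderings reproduce, after scoring, the qualitative
#' sign pattern of the in vitro anchors (see [preset_anchors()]).
#'
#' @param n_samples Samples per scenario (default 6).
#' @param delta,sigma Effect size and noise SD passed to every spec.
#' @return Named list of `scenario_spec`s.
#' @export
scenario_presets <- function(n_samples = 6, delta = 2, sigma = 0.5) {
  tab <- preset_activation_table()
  out <- lapply(rownames(tab), function(lab)
    scenario_spec(lab, tab[lab, ], n_samples = n_samples, delta = delta,
                  sigma = sigma))
  names(out) <- rownames(tab)
  out
}

#' Qualitative direction anchors for the scenario presets
#'
#' Each row states that the `higher` scenario has strictly greater planted
#' activation (hence, after scoring, greater mean log2-odds) than the
#' `lower` scenario for `pathway`.  These are the desk-scale stand-ins for
#' the in vitro subset contrasts: activation, Th1 vs Th2 polarization,
#' iTreg induction, Treg-specific Notch activity and the
#' cancer-supernatant effect.
#'
#' @return Data.frame with columns `higher`, `lower`, `pathway`.
#' @export
preset_anchors <- function() {
  a <- rbind(
    c("activated", "resting", "NFkB"),
    c("activated", "resting", "JAK_STAT1_2"),
    c("activated", "resting", "JAK_STAT3"),
    c("resting", "activated", "FOXO"),
    c("resting", "activated", "TGFB"),
    c("Th1", "Th2", "NFkB"),
    c("Th1", "Th2", "JAK_STAT1_2"),
    c("Th2", "Th1", "FOXO"),
    c("iTreg", "activated", "NFkB"),
    c("iTreg", "activated", "JAK_STAT3"),
    c("iTreg", "activated", "TGFB"),
    c("iTreg", "activated", "Notch"),
    c("iTreg", "activated", "FOXO"),
    c("activated", "iTreg", "JAK_STAT1_2"),
    c("Treg_resting", "activated", "Notch"),
    c("Treg_resting", "resting", "Notch"),
    c("activated", "activated_plus_SN", "NFkB"),
    c("activated", "activated_plus_SN", "JAK_STAT1_2"),
    c("activated", "activated_plus_SN", "JAK_STAT3"),
    c("activated_plus_SN", "activated", "TGFB"),
    c("activated_plus_SN", "activated", "FOXO"))
  data.frame(higher = a[, 1], lower = a[, 2], pathway = a[, 3],
             stringsAsFactors = FALSE)
}

#' Synthetic target-gene sets for the six pathways
#'
#' Deterministic demo gene sets (no real target-gene lists are shipped):
#' `n_genes` synthetic symbols per pathway, every fifth gene marked
#' down-regulated so both CPT branches are exercised.
#'
#' @param pathways Pathway names (default [stp_pathways()]).
#' @param n_genes Genes per set (default 25, within the typical 20-30
#'   range of target-gene signatures).
#' @return Named list of [target_gene_set]s.
#' @export
demo_gene_sets <- function(pathways = stp_pathways(), n_genes = 25) {
  out <- lapply(pathways, function(pw) {
    idx <- seq_len(n_genes)
    target_gene_set(
      pathway_name = pw,
      gene_id = sprintf("%s_T%02d", pw, idx),
      direction = ifelse(idx %% 5 == 0, "down", "up"),
      source = "synthetic demo target genes")
  })
  names(out) <- pathways
  out
}

#' Simulate an expression cohort with planted pathway activation
#'
#' Linear-in-activation Gaussian model: per-gene baselines `mu_g` are drawn
#' once from N(7, 1) log2 units; a target gene of pathway P with direction
#' d (+1 up, -1 down) in a sample with activation `a_P` takes
#' `mu_g + d * delta * a_P + e`, `e ~ N(0, sigma^2)`; background genes take
#' `mu_g + e`.  Identical spec + seed give bit-identical output.
#'
#' @param specs List of [scenario_spec]s.
#' @param gene_sets Named list of [target_gene_set]s with mutually disjoint
#'   gene ids (cross-pathway gene sharing is out of scope).
#' @param n_background_genes Non-target genes added so gene-set lookup and
#'   missing-gene paths are exercised (default 100).
#' @param seed Integer seed for all randomness.
#' @return List with `cohort` (an [expression_matrix] whose annotations
#'   carry the scenario label) and `truth` (data.frame `sample_id`,
#'   `scenario`, `pathway`, `activation`; attribute `seed`).
#' @export
simulate_cohort <- function(specs, gene_sets, n_background_genes = 100,
                            seed = 1) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "scenario_spec")))
  ids_by_set <- lapply(gene_sets, function(gs) gs$genes$gene_id)
  all_target <- unlist(ids_by_set, use.names = FALSE)
  if (anyDuplicated(all_target))
    stop("pathway gene sets overlap; cross-pathway gene sharing is not ",
         "supported", call. = FALSE)
  bg <- if (n_background_genes > 0)
    sprintf("BG%04d", seq_len(n_background_genes)) else character(0)
  if (length(intersect(bg, all_target)))
    stop("background gene ids collide with target gene ids", call. = FALSE)
  gene_ids <- c(all_target, bg)

  pw_of_gene <- rep(names(gene_sets),
                    vapply(ids_by_set, length, integer(1)))
  dir_of_gene <- unlist(lapply(gene_sets, function(gs)
    ifelse(gs$genes$direction == "up", 1, -1)), use.names = FALSE)

  with_seed(seed, {
    mu <- stats::rnorm(length(gene_ids), mean = 7, sd = 1)
    names(mu) <- gene_ids
    cols <- list(); ann <- list(); truth <- list()
    for (spec in specs) {
      a <- spec$activation
      missing_pw <- setdiff(names(gene_sets), names(a))
      if (length(missing_pw))
        stop("scenario '", spec$label, "' lacks activation for pathway(s): ",
             paste(missing_pw, collapse = ", "), call. = FALSE)
      shift <- c(dir_of_gene * spec$delta * a[pw_of_gene],
                 rep(0, length(bg)))
      for (i in seq_len(spec$n_samples)) {
        sid <- sprintf("%s_%02d", spec$label, i)
        if (sid %in% names(cols))
          stop("duplicate sample id '", sid,
               "' (repeated scenario label?)", call. = FALSE)
        cols[[sid]] <- mu + shift +
          stats::rnorm(length(gene_ids), sd = spec$sigma)
        ann[[sid]] <- data.frame(sample_id = sid, scenario = spec$label,
                                 stringsAsFactors = FALSE)
        truth[[sid]] <- data.frame(sample_id = sid, scenario = spec$label,
                                   pathway = names(gene_sets),
                                   activation =
                                     unname(a[names(gene_sets)]),
                                   stringsAsFactors = FALSE)
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- gene_ids
    truth_df <- do.call(rbind, truth)
    rownames(truth_df) <- NULL
    attr(truth_df, "seed") <- seed
    list(cohort = expression_matrix(values, do.call(rbind, ann)),
         truth = truth_df)
  })
}

#' Simulate a calibration cohort and calibrate frozen models
#'
#' Mirrors the calibrate-on-one-cell-type-then-freeze protocol: a dedicated
#' two-class cohort (all pathways at full activation vs fully inactive) is
#' simulated, one model per gene set is calibrated on it, and the frozen
#' models are returned for application to any other cohort without further
#' adaptation.
#'
#' @param gene_sets Named list of [target_gene_set]s.
#' @param n_per_class Samples per class (default 20).
#' @param delta,sigma Generator effect size and noise for the calibration
#'   cohort (defaults 2 and 1).
#' @param seed Integer seed.
#' @param prior_active,pseudocount Passed to [calibrate_model()].
#' @return Named list of `frozen_pathway_model`s (by pathway).
#' @export
calibrate_preset_models <- function(gene_sets, n_per_class = 20, delta = 2,
                                    sigma = 1, seed = 1, prior_active = 0.5,
                                    pseudocount = 1) {
  pw <- names(gene_sets)
  on_lvl <- stats::setNames(rep(1, length(pw)), pw)
  off_lvl <- stats::setNames(rep(0, length(pw)), pw)
  sim <- simulate_cohort(
    list(scenario_spec("calib_active", on_lvl, n_per_class, delta, sigma),
         scenario_spec("calib_inactive", off_lvl, n_per_class, delta, sigma)),
    gene_sets, n_background_genes = 0, seed = seed)
  labels <- ifelse(sim$cohort$annotations$scenario == "calib_active",
                   "active", "inactive")
  models <- lapply(gene_sets, function(gs)
    calibrate_model(sim$cohort, labels, gs, prior_active = prior_active,
                    pseudocount = pseudocount))
  names(models) <- pw
  models
}

#' Simulate a per-sample QC metrics table with planted failures
#'
#' Passing samples draw every metric comfortably inside the enabled rule
#' bounds; each planted failure violates one randomly chosen metric by at
#' least five bound-widths (flags are set `FALSE`), so the default rule set
#' separates passers from failures with 100% sensitivity and specificity.
#'
#' @param n_samples Number of samples.
#' @param n_planted_failures Number of failing samples (<= `n_samples`).
#' @param seed Integer seed.
#' @param rules Rule set the table must respect (default
#'   [default_qc_rules()]).
#' @return List with `metrics` (data.frame, one row per sample),
#'   `failed_sample_ids` (character) and `seed`.
#' @export
simulate_qc_table <- function(n_samples, n_planted_failures = 0, seed = 1,
                              rules = default_qc_rules()) {
  stopifnot(n_planted_failures <= n_samples, n_samples >= 1)
  rules <- rules[rules$enabled, , drop = FALSE]
  count_metrics <- c("n_negative_values", "n_overflow_values")

  draw_pass <- function(r) {
    if (r$type == "flag") return(TRUE)
    if (r$metric %in% count_metrics) return(0L)
    lo <- r$min; hi <- r$max
    if (!is.na(lo) && !is.na(hi)) {
      w <- hi - lo
      return(stats::runif(1, lo + 0.25 * w, hi - 0.25 * w))
    }
    if (!is.na(hi)) return(stats::runif(1, hi - 2.5, hi - 0.5))
    stats::runif(1, lo + 0.5, lo + 2.5)
  }
  draw_fail <- function(r) {
    if (r$type == "flag") return(FALSE)
    if (r$metric %in% count_metrics) return(5L + stats::rpois(1, 10))
    lo <- r$min; hi <- r$max
    w <- if (!is.na(lo) && !is.na(hi)) max(hi - lo, 1) else 1
    if (!is.na(hi)) hi + 5 * w else lo - 5 * w
  }

  with_seed(seed, {
    fail_idx <- if (n_planted_failures > 0)
      sort(sample.int(n_samples, n_planted_failures)) else integer(0)
    rows <- lapply(seq_len(n_samples), function(i) {
      vals <- lapply(seq_len(nrow(rules)), function(j)
        draw_pass(rules[j, ]))
      names(vals) <- rules$metric
      if (i %in% fail_idx) {
        j <- sample.int(nrow(rules), 1)
        vals[[rules$metric[j]]] <- draw_fail(rules[j, ])
      }
      cbind(data.frame(sample_id = sprintf("S%03d", i),
                       stringsAsFactors = FALSE),
            as.data.frame(vals, stringsAsFactors = FALSE))
    })
    metrics <- do.call(rbind, rows)
    list(metrics = metrics,
         failed_sample_ids = metrics$sample_id[fail_idx],
         seed = seed)
  })
}
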