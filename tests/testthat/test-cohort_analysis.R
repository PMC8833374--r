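test_that("normal threshold is mean + k * sample SD", {
  t0 <- normal_threshold(c(0, 0, 0, 0))
  expect_equal(t0$upper, 0)
  t1 <- normal_threshold(c(-6, -8, -7, -9))
  expect_equal(t1$ref_mean, -7.5)
  expect_equal(t1$ref_sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(t1$upper, -7.5 + 2 * sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(t1$upper - t1$ref_mean, 2 * t1$ref_sd)
  expect_equal(normal_threshold(c(-6, -8, -7, -9), k_sd = 0)$upper, -7.5)
  expect_error(normal_threshold(5), "at least 2")
  expect_error(normal_threshold(c(1, NA)), "at least 2")
})

test_that("abnormal-high calls use a strict upper bound", {
  th <- list(P = normal_threshold(c(2, 2)))    # zero SD: upper = 2
  expect_equal(unname(classify_abnormal(c(P = 2), th)), "normal")
  expect_equal(unname(classify_abnormal(c(P = 2 + 1e-9), th)),
               "abnormal_high")
  expect_error(classify_abnormal(c(Q = 0), th), "no threshold")
})

test_that("blood Notch column yields 9/10 abnormal for any separating threshold", {
  # donor-derived thresholds are not printed; any upper bound strictly
  # between the lowest patient score (-8.7) and the next (-8.4) must
  # reproduce the 9-out-of-10 abnormal count
  for (upper in c(-8.699, -8.65, -8.55, -8.45, -8.401)) {
    th <- list(Notch = structure(
      list(pathway_name = "Notch", ref_mean = NA_real_, ref_sd = NA_real_,
           upper = upper, n_ref = 4L),
      class = "reference_threshold"))
    calls <- vapply(blood_notch_published, function(s)
      classify_abnormal(c(Notch = s), th), character(1))
    expect_equal(sum(calls == "abnormal_high"), 9)
    expect_equal(which(calls == "normal"), 3L)   # patient 3 only
  }
})

test_that("raising a score never flips abnormal_high back to normal", {
  th <- list(P = normal_threshold(rnorm(10)))
  set.seed(9)
  s <- sort(rnorm(50, sd = 3))
  calls <- vapply(s, function(x) classify_abnormal(c(P = x), th),
                  character(1))
  expect_true(all(diff(calls == "abnormal_high") >= 0))
})

test_that("Mann-Whitney reproduces the printed TIL subtype comparisons", {
  r <- mann_whitney(til_tgfb_tripleneg, til_tgfb_others, "less")
  expect_equal(r$statistic, 3)
  expect_equal(r$p_value, 7 / 252)
  expect_equal(r$method, "mann_whitney_exact")
  expect_false(r$ties_present)
  r2 <- mann_whitney(til_nfkb_tripleneg, til_nfkb_others, "less")
  expect_equal(r2$statistic, 3)
  expect_equal(r2$p_value, 7 / 252)
})

test_that("Mann-Whitney handles complete separation and identical groups", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 20)
  # smallest attainable two-sided p for groups of 10 and 4
  r2 <- mann_whitney(11:20, 1:4, "two_sided")
  expect_equal(r2$p_value, 2 / 1001)
  # identical groups: ties force the normal approximation, p in the 1 region
  r3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3), "two_sided")
  expect_true(r3$ties_present)
  expect_gte(r3$p_value, 0.99)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches full labeling enumeration", {
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    repeat {                       # tie-free inputs for the exact path
      x <- round(rnorm(n1, 0, 3), 3)
      y <- round(rnorm(n2, 1, 3), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    alt <- sample(c("two_sided", "less", "greater"), 1)
    r <- mann_whitney(x, y, alt)
    expect_equal(r$method, "mann_whitney_exact")
    expect_equal(r$p_value, mw_enum_p(x, y, alt), tolerance = 1e-12)
    expect_gte(r$statistic, 0)
    expect_lte(r$statistic, n1 * n2)
  }
})

test_that("paired Wilcoxon: zero-difference handling and exact tails", {
  x <- c(1, 2, 3, 4)
  expect_warning(r <- wilcoxon_paired(x, x), "all paired differences")
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)
  r2 <- suppressMessages(
    wilcoxon_paired(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6), "greater"))
  expect_equal(r2$p_value, 1 / 64)
  expect_equal(r2$statistic, 21)
  # zero differences are dropped with a message
  expect_message(wilcoxon_paired(c(0, 1, 2, 3), c(0, 0, 0, 0)), "1 zero")
})

test_that("exact Wilcoxon p matches sign-pattern enumeration", {
  set.seed(77)
  for (i in 1:15) {
    n <- sample(4:9, 1)
    repeat {
      d <- round(rnorm(n, 0.3, 1), 3)
      if (all(d != 0) && !anyDuplicated(abs(d))) break
    }
    alt <- sample(c("two_sided", "less", "greater"), 1)
    r <- wilcoxon_paired(d, rep(0, n), alt)
    expect_equal(r$p_value, wsr_enum_p(d, alt), tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches closed forms", {
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1)$estimate, 1)
  expect_equal(pearson_cor(1:5, -(1:5))$estimate, -1)
  r <- pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$estimate, 0.6)
  expect_equal(r$p_value,
               stats::cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))$p.value)
  expect_error(pearson_cor(1:2, 2:3), "n >= 3")
  expect_error(pearson_cor(c(1, 1, 1), 1:3), "zero variance")
})

test_that("new normal samples exceed the mean+2SD threshold at the 2.28% rate", {
  set.seed(314)
  ref <- rnorm(10000, mean = -7, sd = 1.5)
  th <- list(P = normal_threshold(ref, k_sd = 2))
  new <- rnorm(10000, mean = -7, sd = 1.5)
  rate <- mean(new > th$P$upper)
  p0 <- stats::pnorm(-2)            # 0.02275
  half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / 10000)
  expect_gte(rate, p0 - half)
  expect_lte(rate, p0 + half)
})

test_that("profile matching standardizes per pathway and recovers planted type", {
  gs <- demo_gene_sets()
  models <- calibrate_preset_models(gs, seed = 55)
  presets <- scenario_presets()
  sim <- simulate_cohort(presets[c("resting", "activated", "iTreg")], gs,
                         seed = 56)
  pm <- profile_matrix(score_cohort(models, sim$cohort))
  scen <- sim$cohort$annotations$scenario
  refs <- lapply(c(resting = "resting", activated = "activated",
                   iTreg = "iTreg"),
                 function(l) colMeans(pm[scen == l, , drop = FALSE]))
  # self-match: a reference profile matches itself with similarity 1
  m_self <- match_profile(refs$resting, refs)
  expect_equal(m_self$best_label, "resting")
  expect_equal(m_self$similarity, 1, tolerance = 1e-12)
  # every iTreg-scenario sample matches the iTreg reference best
  itreg_ids <- rownames(pm)[scen == "iTreg"]
  for (sid in itreg_ids) {
    expect_equal(match_profile(pm[sid, ], refs)$best_label, "iTreg")
  }
  # disjoint pathway sets are refused
  bad <- c(X = 1, Y = 2)
  expect_error(match_profile(bad, refs), "fewer than 2 pathways")
})

test_that("rank AUC is the Mann-Whitney probability of correct ordering", {
  expect_equal(rank_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(rank_auc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(rank_auc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)), 0.75)
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(5)
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
    expect_equal(rank_auc(s, y == 1),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})
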