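test_that("calibration recovers median cutoff and Laplace-smoothed CPTs", {
  gs <- target_gene_set("P", "g1")
  m <- expression_matrix(matrix(c(8, 8, 8, 8, 2, 2, 2, 2), nrow = 1,
                                dimnames = list("g1", paste0("s", 1:8))))
  labels <- c(rep("active", 4), rep("inactive", 4))
  mod <- calibrate_model(m, labels, gs, pseudocount = 1)
  expect_equal(mod$gene_params$cutoff, 5)
  expect_equal(mod$gene_params$p_high_given_active, 5 / 6)
  expect_equal(mod$gene_params$p_high_given_inactive, 1 / 6)
  expect_true(mod$frozen)
  expect_equal(mod$calibration_meta$n_active, 4)
})

test_that("calibration contracts: label classes, missing and constant genes", {
  gs <- target_gene_set("P", c("g1", "g2", "g3"))
  vals <- rbind(g1 = c(8, 9, 2, 3), g2 = c(5, 5, 5, 5))
  m <- expression_matrix(matrix(vals, nrow = 2,
                                dimnames = list(c("g1", "g2"),
                                                paste0("s", 1:4))))
  labels <- c("active", "active", "inactive", "inactive")
  expect_error(calibrate_model(m, rep("active", 4), gs), "2 samples per label")
  # g3 absent, g2 constant: both dropped with warnings, g1 survives
  w <- capture_warnings(mod <- calibrate_model(m, labels, gs))
  expect_match(w, "g3", all = FALSE)
  expect_match(w, "g2", all = FALSE)
  expect_equal(mod$gene_params$gene_id, "g1")
})

test_that("uninformative training data yields prior-odds scores", {
  gs <- target_gene_set("P", c("g1", "g2"))
  set.seed(4)
  v <- matrix(rnorm(12, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  v[, 4:6] <- v[, 1:3]              # identical distributions per class
  m <- expression_matrix(v)
  labels <- c(rep("active", 3), rep("inactive", 3))
  mod <- calibrate_model(m, labels, gs, prior_active = 0.5)
  expect_equal(mod$gene_params$p_high_given_active,
               mod$gene_params$p_high_given_inactive)
  s <- v[, 1]
  expect_equal(score_sample(mod, s)$log2_odds, 0)
})

test_that("calibration on separable synthetic data recovers gene directions", {
  gs <- demo_gene_sets("P1", n_genes = 20)[["P1"]]
  sim <- simulate_cohort(
    list(scenario_spec("on", c(P1 = 1), 20, delta = 2, sigma = 0.5),
         scenario_spec("off", c(P1 = 0), 20, delta = 2, sigma = 0.5)),
    list(P1 = gs), seed = 101)
  labels <- ifelse(sim$cohort$annotations$scenario == "on",
                   "active", "inactive")
  mod <- calibrate_model(sim$cohort, labels, gs)
  up <- mod$gene_params$direction == "up"
  expect_true(all(mod$gene_params$p_high_given_active[up] >
                    mod$gene_params$p_high_given_inactive[up]))
  expect_true(all(mod$gene_params$p_high_given_active[!up] <
                    mod$gene_params$p_high_given_inactive[!up]))
})

test_that("scoring follows the closed-form likelihood-ratio product", {
  mod <- uniform_model(20)          # every gene LR(high) = 2, prior 0.5
  high <- setNames(rep(10, 20), mod$gene_params$gene_id)
  s <- score_sample(mod, high)
  expect_equal(s$log2_odds, 20)
  expect_equal(s$prob_active, 2^20 / (1 + 2^20), tolerance = 1e-12)
  expect_equal(s$n_genes_used, 20)
  # all model genes missing -> error, not a silent prior return
  expect_error(score_sample(mod, c(other = 1)), "no overlap")
  # partial overlap: missing genes contribute LR = 1
  s2 <- score_sample(mod, high[1:5])
  expect_equal(s2$log2_odds, 5)
  expect_equal(sort(s2$missing_genes),
               sort(mod$gene_params$gene_id[6:20]))
  expect_equal(s2$n_genes_used + length(s2$missing_genes), 20)
})

test_that("log2 odds and probability stay consistent and clamped", {
  mod <- uniform_model(200, p_act = 0.95, p_inact = 0.05)
  high <- setNames(rep(10, 200), mod$gene_params$gene_id)
  s <- score_sample(mod, high)
  expect_equal(s$log2_odds, 60)     # clamp
  low <- setNames(rep(0, 200), mod$gene_params$gene_id)
  expect_equal(score_sample(mod, low)$log2_odds, -60)
  # probability/odds consistency away from the representable-precision edge
  # (1 - prob loses double precision once |log2 odds| grows past ~25)
  for (n in c(1, 2, 3, 4)) {
    sc <- score_sample(mod, high[seq_len(n)])
    expect_equal(sc$log2_odds,
                 log2(sc$prob_active) - log2(1 - sc$prob_active),
                 tolerance = 1e-9)
  }
})

test_that("unfrozen models are refused", {
  mod <- uniform_model(3)
  mod$frozen <- FALSE
  expect_error(score_sample(mod, setNames(rep(10, 3),
                                          mod$gene_params$gene_id)),
               "not frozen")
})

test_that("factorized posterior equals brute-force joint enumeration", {
  for (seed in 1:25) {
    k <- 2 + (seed %% 7)
    mod <- random_model(k, seed)
    set.seed(seed + 1000)
    s <- setNames(rnorm(k, 7, 2), mod$gene_params$gene_id)
    expect_equal(score_sample(mod, s)$prob_active,
                 score_sample_enumeration(mod, s),
                 tolerance = 1e-9)
  }
})

test_that("log2 odds is non-decreasing in the number of genes high", {
  mod <- uniform_model(10)
  vals <- setNames(rep(0, 10), mod$gene_params$gene_id)
  prev <- -Inf
  for (n_high in 0:10) {
    v <- vals
    if (n_high > 0) v[1:n_high] <- 10
    l <- score_sample(mod, v)$log2_odds
    expect_gte(l, prev)
    prev <- l
  }
})

test_that("training-set scores separate the classes when a shift is planted", {
  gs <- demo_gene_sets("P1", n_genes = 20)[["P1"]]
  sim <- simulate_cohort(
    list(scenario_spec("on", c(P1 = 1), 10, delta = 2, sigma = 1),
         scenario_spec("off", c(P1 = 0), 10, delta = 2, sigma = 1)),
    list(P1 = gs), seed = 7)
  labels <- ifelse(sim$cohort$annotations$scenario == "on",
                   "active", "inactive")
  mod <- calibrate_model(sim$cohort, labels, gs)
  sc <- profile_matrix(score_cohort(list(mod), sim$cohort))[, "P1"]
  expect_gt(mean(sc[labels == "active"]), mean(sc[labels == "inactive"]))
})

test_that("cohort scoring is per-sample, order-equivariant and frozen", {
  gs <- demo_gene_sets(c("A", "B"), n_genes = 10)
  sim <- simulate_cohort(
    scenario_spec("mix", c(A = 0.8, B = 0.2), 6), gs, seed = 31)
  models <- calibrate_preset_models(gs, n_per_class = 5, seed = 32)
  prof <- score_cohort(models, sim$cohort)
  # single sample wraps score_sample
  one <- subset_samples(sim$cohort, "mix_01")
  vec <- one$values[, 1]
  names(vec) <- rownames(one$values)
  expect_equal(score_cohort(models, one)[["mix_01"]]$scores$A$log2_odds,
               score_sample(models$A, vec, "mix_01")$log2_odds)
  # permuting samples permutes output identically
  perm <- rev(colnames(sim$cohort$values))
  prof_perm <- score_cohort(models, subset_samples(sim$cohort, perm))
  expect_identical(profile_matrix(prof)[perm, ], profile_matrix(prof_perm))
  # appending unrelated samples leaves original scores bit-identical
  extra <- simulate_cohort(scenario_spec("other", c(A = 0.1, B = 0.9), 10),
                           gs, seed = 33)$cohort
  joined <- expression_matrix(
    cbind(sim$cohort$values, extra$values),
    rbind(sim$cohort$annotations, extra$annotations))
  prof_joined <- score_cohort(models, joined)
  orig <- colnames(sim$cohort$values)
  expect_identical(profile_matrix(prof)[orig, ],
                   profile_matrix(prof_joined)[orig, ])
  # duplicate pathway names across models -> config error
  expect_error(score_cohort(list(models$A, models$A), sim$cohort),
               "duplicate pathway names")
})

test_that("PI3K is inferred inversely from FOXO only without oxidative stress", {
  # activated vs naive CD4+ FOXO scores: high PI3K in the activated sample
  expect_equal(infer_pi3k_from_foxo(-3.8, reference = 10.3), "pi3k_high")
  expect_equal(infer_pi3k_from_foxo(10.3, reference = -3.8), "pi3k_low")
  expect_equal(infer_pi3k_from_foxo(1.0, reference = 1.0), "indeterminate")
  expect_equal(infer_pi3k_from_foxo(-3.8, reference = 10.3,
                                    oxidative_stress = TRUE),
               "indeterminate")
})
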