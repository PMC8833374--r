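# Independent brute-force oracles and small fixture builders shared by the
# test files.  The oracles never call the code paths they validate.

# Exact Mann-Whitney p by full enumeration of the C(n1+n2, n1) group
# labelings, with mid-ranks.
mw_enum_p <- function(x, y, alternative) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(length(pooled), n1), 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  switch(alternative,
         less = lo, greater = hi,
         two_sided = min(1, 2 * min(lo, hi)))
}

# Exact Wilcoxon signed-rank p by enumeration of all 2^n sign patterns.
wsr_enum_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(code) {
    s <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    sum(r[s])
  }, numeric(1))
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  switch(alternative,
         less = lo, greater = hi,
         two_sided = min(1, 2 * min(lo, hi)))
}

# A frozen model with arbitrary (random but valid) parameters, for
# factorized-vs-enumeration equivalence checks.
random_model <- function(k, seed) {
  set.seed(seed)
  structure(
    list(pathway_name = "RND",
         prior_active = runif(1, 0.1, 0.9),
         gene_params = data.frame(
           gene_id = sprintf("g%02d", seq_len(k)),
           direction = sample(c("up", "down"), k, replace = TRUE),
           cutoff = rnorm(k, 7, 1),
           p_high_given_active = runif(k, 0.05, 0.95),
           p_high_given_inactive = runif(k, 0.05, 0.95),
           stringsAsFactors = FALSE),
         frozen = TRUE,
         calibration_meta = list()),
    class = "frozen_pathway_model")
}

# A frozen model where every gene is an up-gene with identical likelihood
# ratios, handy for closed-form score checks.
uniform_model <- function(k, p_act = 2 / 3, p_inact = 1 / 3, prior = 0.5,
                          cutoff = 5) {
  structure(
    list(pathway_name = "UNI",
         prior_active = prior,
         gene_params = data.frame(
           gene_id = sprintf("u%02d", seq_len(k)),
           direction = "up",
           cutoff = cutoff,
           p_high_given_active = p_act,
           p_high_given_inactive = p_inact,
           stringsAsFactors = FALSE),
         frozen = TRUE,
         calibration_meta = list()),
    class = "frozen_pathway_model")
}

# Published blood-derived CD4+ T-cell Notch score column (patients 1..10).
blood_notch_published <- c(1.6, -5.7, -8.7, -6.1, -4.2, -8.4, -7.3, -6.8, -8.0, -8.4)

# Published TIL CD4+ T-cell score columns split by breast-cancer subtype.
til_tgfb_tripleneg <- c(-7.4, -9.0, -10.4, -8.3, -14.2)
til_tgfb_others    <- c(-2.4, -7.5, -4.8, -6.8, -8.5)
til_nfkb_tripleneg <- c(24.8, 22.8, 19.0, 13.6, 18.1)
til_nfkb_others    <- c(30.3, 21.5, 31.3, 26.8, 23.5)
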