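flat_prior <- rvm_prior(1e-12, 1e12)  # a -> 0, 2/b -> 0

test_that("moderated F reduces to the classical one-way F in the flat-prior limit", {
  d <- toy_design(3)
  x <- toy_matrix(c(1, 2, 3, 4, 5, 6), names(d$samples))
  res <- rvm_f_test(x, d, flat_prior)
  # hand one-way ANOVA: MS_between = 13.5, pooled s^2 = 1
  expect_equal(res$f_raw, 13.5)
  expect_equal(res$f_rvm, 13.5, tolerance = 1e-9)

  set.seed(21)
  d5 <- npc_stage_design()
  xr <- expression_matrix(
    matrix(rnorm(50 * 22), 50, 22,
           dimnames = list(sprintf("f%02d", 1:50), names(d5$samples))),
    "miRNA")
  r <- rvm_f_test(xr, d5, flat_prior)
  expect_equal(r$f_rvm, r$f_raw, tolerance = 1e-9)
})

test_that("the shrunk variance is a convex combination and always positive", {
  set.seed(3)
  d <- npc_stage_design()
  x <- expression_matrix(
    matrix(rnorm(100 * 22), 100, 22,
           dimnames = list(sprintf("f%03d", 1:100), names(d$samples))),
    "miRNA")
  prior <- rvm_prior(2, 1.5)
  s2 <- pooled_residual_variances(x, d)
  res <- rvm_f_test(x, d, prior)
  sigma_mod <- (res$f_raw / res$f_rvm) * s2  # recover sigma~^2
  prior_scale <- 1 / (prior$a * prior$b)     # mode-side prior scale 2/b / 2a
  expect_true(all(sigma_mod > 0))
  expect_true(all(sigma_mod > pmin(s2, prior_scale) - 1e-12))
  expect_true(all(sigma_mod < pmax(s2, prior_scale) + 1e-12))
})

test_that("prior fitting recovers generating parameters and is locally optimal", {
  set.seed(42)
  a_true <- 2; b_true <- 1.5; m <- 18
  sigma2 <- 1 / rgamma(5000, shape = a_true, scale = b_true)
  s2 <- sigma2 * rchisq(5000, m) / m
  fit <- fit_rvm_prior(s2, df = m)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - a_true) / a_true, 0.15)
  expect_lt(abs(fit$b - b_true) / b_true, 0.15)

  # brute-force local-optimality probe around the optimum
  nll_fit <- mirstage:::rvm_prior_nll(fit, s2, m)
  set.seed(1)
  for (i in 1:100) {
    pert <- rvm_prior(fit$a * exp(runif(1, -0.2, 0.2)),
                      fit$b * exp(runif(1, -0.2, 0.2)))
    expect_lte(nll_fit, mirstage:::rvm_prior_nll(pert, s2, m) + 1e-8)
  }
})

test_that("degenerate and undersized variance inputs are refused loudly", {
  expect_error(fit_rvm_prior(rep(2, 500), df = 18), "degenerate")
  expect_warning(fit_rvm_prior(exp(rnorm(20)), df = 18), "only 20")
  expect_message(fit_rvm_prior(c(rep(0, 5), exp(rnorm(100))), df = 18),
                 "5 zero/non-finite")
})

test_that("null moderated F is calibrated against its reference distribution", {
  set.seed(8)
  d <- npc_stage_design()
  prior <- rvm_prior(2, 1.5)
  sim <- generate_staged_expression(n_features = 2000, n_de = 0,
                                    prior = prior, seed = 8)
  res <- rvm_f_test(sim$matrix, d, prior)
  # E[F(df1, df2)] = df2 / (df2 - 2) under the null
  ref_mean <- res$df2[1] / (res$df2[1] - 2)
  mc_se <- sd(res$f_rvm) / sqrt(length(res$f_rvm))
  expect_lt(abs(mean(res$f_rvm) - ref_mean), 4 * mc_se)
})

test_that("the statistic depends only on group memberships", {
  set.seed(12)
  d <- npc_stage_design()
  x <- expression_matrix(
    matrix(rnorm(30 * 22), 30, 22,
           dimnames = list(sprintf("f%02d", 1:30), names(d$samples))),
    "miRNA")
  res1 <- rvm_f_test(x, d, rvm_prior(2, 1.5))
  # permute samples within the normal stage
  norm_ids <- names(d$samples)[d$samples == "normal"]
  perm <- colnames(x)
  perm[match(norm_ids, perm)] <- rev(norm_ids)
  res2 <- rvm_f_test(x[, perm], d, rvm_prior(2, 1.5))
  expect_equal(res2$f_rvm, res1$f_rvm)
})

test_that("zero-variance and missing-value features are flagged, not dropped silently", {
  d <- toy_design(3)
  x <- toy_matrix(c(rep(5, 6), 1, 2, NA, 4, 5, 6, 1, 2, 3, 6, 5, 4),
                  names(d$samples))
  expect_message(res <- rvm_f_test(x, d, rvm_prior(2, 1.5)),
                 "1 features with missing")
  expect_identical(res$flag, c("zero_variance", "missing", "ok"))
  expect_equal(res$p_value[1], 1)
  expect_true(is.na(res$p_value[2]))
})

test_that("BH q-values match the hand step-up rule and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")

  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), brute_bh(p))
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
})

test_that("q-values are monotone in p-rank", {
  set.seed(9)
  p <- runif(200)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("stage calls respect the global gate and direction signs", {
  set.seed(31)
  d <- npc_stage_design()
  sim <- generate_staged_expression(n_features = 300, n_de = 30,
                                    pattern_mix = c(1, 0, 0, 0, 0, 0),
                                    seed = 31)
  s2 <- pooled_residual_variances(sim$matrix, d)
  prior <- fit_rvm_prior(s2, df = 17)
  diff <- rvm_f_test(sim$matrix, d, prior)
  calls <- stage_direction_calls(sim$matrix, d, diff)
  listed <- unique(unlist(lapply(calls, unlist)))
  gate <- diff$feature_id[diff$p_value < 0.05 & diff$q_value < 0.05]
  expect_true(all(listed %in% gate))  # nothing bypasses the global gate
  # planted monotone decreases can only ever be called down
  planted <- sim$truth$de$feature_id
  for (s in names(calls))
    expect_length(intersect(calls[[s]]$up, planted), 0L)
  # and the planted features dominate the down calls at metastasis
  expect_gt(length(intersect(calls[["MET"]]$down, planted)), 20L)
})
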