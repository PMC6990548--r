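test_that("design assembly produces the documented column structure", {
  sv <- small_survey()
  ch <- sv$children

  # GAM/geoadditive fixed block: intercept + 15 dummy/continuous columns
  d2 <- build_design(ch, model_spec("m2"))
  expect_equal(d2$n_fixed, 16)
  expect_equal(ncol(d2$X), 16 + 20) # plus 20 spline columns
  expect_equal(length(d2$smooths), 1)
  expect_equal(d2$smooths$age_months$rank, 18)

  # GLM adds the linear age term
  d1 <- build_design(ch, model_spec("m1"))
  expect_equal(d1$n_fixed, 17)
  expect_true("age_months" %in% colnames(d1$X))
  expect_length(d1$smooths, 0)

  # geoadditive model requires and checks the graph
  expect_error(build_design(ch, model_spec("m3")), "adjacency graph")
  d3 <- build_design(ch, model_spec("m3"), sv$graph)
  expect_true(d3$spatial)
  ch_bad <- ch
  ch_bad$district_id[1] <- "atlantis"
  ch_bad$cluster_id[1] <- "atlantis_c" # keep nesting valid
  ch_bad$household_id[1] <- "atlantis_h"
  expect_error(build_design(ch_bad, model_spec("m3"), sv$graph), "atlantis")

  # an absent factor level drops its column with a warning
  ch_no_flush <- ch[ch$toilet != "flush", ]
  expect_warning(d_nf <- build_design(ch_no_flush, model_spec("m2")), "flush")
  expect_false("toilet_flush" %in% colnames(d_nf$X))
})

test_that("the sampler is deterministic under a fixed seed", {
  ch <- toy_children(150, seed = 31, beta0 = -0.4, beta1 = 0.8)
  spec <- model_spec("m1", fixed_terms = "wealth_index")
  des <- build_design(ch, spec)
  cfg <- mcmc_config(n_iter = 300, burn_in = 100, thin = 2, seed = 99)
  f1 <- fit_geoadd(des, mcmc = cfg)
  f2 <- fit_geoadd(des, mcmc = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- fit_geoadd(des, mcmc = mcmc_config(n_iter = 300, burn_in = 100,
                                           thin = 2, seed = 100))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("an intercept-only fit matches the conjugate proportion oracle", {
  ch <- data.frame(anaemic = c(rep(1L, 25), rep(0L, 75)),
                   wealth_index = 0)
  des <- build_design(ch, model_spec("m1", fixed_terms = character(0)))
  f <- fit_geoadd(des, mcmc = mcmc_config(n_iter = 6000, burn_in = 1000,
                                          thin = 1, seed = 3))
  # with an essentially flat prior the posterior of plogis(b0) is ~ Beta(26, 76)
  expect_equal(mean(plogis(f$draws[, "intercept"])), 0.25, tolerance = 0.02)
})

test_that("null data give nominal credible-interval coverage of zero", {
  sv <- small_survey(seed = 55)
  pop <- generate_population(sv$design, sv$graph)
  zero <- stats::setNames(rep(0, length(sv$graph$nodes)), sv$graph$nodes)
  p0 <- true_params(beta = c(intercept = 0),
                    age_curve = function(a) rep(0, length(a)))
  ch <- simulate_outcomes(pop, p0, district_effects(zero, zero), seed = 56)
  des <- build_design(ch[seq_len(2000), ], model_spec("m1"))
  f <- fit_geoadd(des, mcmc = mcmc_config(n_iter = 1200, burn_in = 400,
                                          thin = 2, seed = 57))
  cols <- setdiff(colnames(des$X), "intercept")
  covered <- vapply(cols, function(cn) {
    ci <- quantile(f$draws[, cn], c(0.025, 0.975))
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), length(cols) - 2)
})

test_that("the linear predictor matches a direct dot-product oracle", {
  sv <- small_survey(seed = 61, n_districts = 6, clusters_per_district = 2,
                     households_per_cluster = 8)
  des <- build_design(sv$children, model_spec("m3"), sv$graph)
  f <- fit_geoadd(des, mcmc = mcmc_config(n_iter = 200, burn_in = 100,
                                          thin = 5, seed = 8))
  lp <- linear_predictor(f)
  expect_true(all(lp$pi > 0 & lp$pi < 1))
  nodes <- sv$graph$nodes
  set.seed(1)
  for (k in sample(nrow(f$draws), 5)) {
    for (i in sample(des$n, 4)) {
      eta_direct <- sum(des$X[i, ] * f$draws[k, seq_len(ncol(des$X))]) +
        f$draws[k, paste0("f_str_", sv$children$district_id[i])] +
        f$draws[k, paste0("f_unstr_", sv$children$district_id[i])]
      expect_equal(lp$eta[i, k], eta_direct, tolerance = 1e-10)
    }
  }

  # flipping one dummy changes eta by exactly that coefficient
  ch2 <- sv$children[1, , drop = FALSE]
  ch2$malaria_rdt <- "negative"
  ch3 <- ch2
  ch3$malaria_rdt <- "positive"
  e2 <- linear_predictor(f, ch2)$eta
  e3 <- linear_predictor(f, ch3)$eta
  expect_equal(drop(e3 - e2), unname(f$draws[, "malaria_rdt_positive"]),
               tolerance = 1e-10)
})

test_that("stored deviances match an independent log-likelihood oracle", {
  ch <- toy_children(120, seed = 71, beta0 = 0.2, beta1 = -0.6)
  des <- build_design(ch, model_spec("m1", fixed_terms = "wealth_index"))
  f <- fit_geoadd(des, mcmc = mcmc_config(n_iter = 300, burn_in = 100,
                                          thin = 2, seed = 72))
  lp <- linear_predictor(f)
  for (k in seq_len(min(100, nrow(f$draws)))) {
    expect_equal(f$deviance[k], deviance_oracle(des$y, lp$pi[, k]),
                 tolerance = 1e-8)
  }
  # pi = 1/2 everywhere gives the closed form 2 n log 2
  f0 <- f
  f0$draws[] <- 0
  expect_equal(deviance_draws(f0)$D_at_mean, 2 * des$n * log(2),
               tolerance = 1e-9)
})

test_that("every stored draw satisfies the sum-to-zero constraints exactly", {
  sv <- small_survey(seed = 81, n_districts = 6, clusters_per_district = 2,
                     households_per_cluster = 10)
  des <- build_design(sv$children, model_spec("m3"), sv$graph)
  f <- fit_geoadd(des, mcmc = mcmc_config(n_iter = 300, burn_in = 100,
                                          thin = 1, seed = 82))
  s <- des$smooths$age_months
  idx <- s$start + seq_len(s$basis_spec$M)
  expect_lt(max(abs(f$draws[, idx] %*% s$w)), 1e-10)
  expect_lt(max(abs(rowSums(f$draws[, paste0("f_str_", sv$graph$nodes)]))),
            1e-10)
  expect_lt(max(abs(rowSums(f$draws[, paste0("f_unstr_", sv$graph$nodes)]))),
            1e-10)
  expect_true(all(f$tau2 > 0))
})

test_that("precision draws follow their conjugate Gamma full conditionals", {
  # each stored (theta, tau2) pair was drawn as tau2 | theta ~ Gamma(a + r/2,
  # b + quad/2); the probability integral transform of tau2 given theta must
  # therefore be iid uniform, which a KS test checks at the 1% level.
  sv <- small_survey(seed = 91, n_districts = 9, clusters_per_district = 2,
                     households_per_cluster = 12)
  des <- build_design(sv$children, model_spec("m3"), sv$graph)
  pr <- prior_config()
  f <- fit_geoadd(des, priors = pr,
                  mcmc = mcmc_config(n_iter = 10500, burn_in = 500, thin = 1,
                                     seed = 92))
  s <- des$smooths$age_months
  idx <- s$start + seq_len(s$basis_spec$M)
  nd <- length(sv$graph$nodes)
  pd <- ncol(des$X)
  Q <- des$icar$Q

  quad_sm <- rowSums((f$draws[, idx] %*% s$K) * f$draws[, idx])
  u_sm <- pgamma(f$tau2[, "tau2_age_months"], pr$hyper_a + s$rank / 2,
                 rate = pr$hyper_b + quad_sm / 2)
  fs <- f$draws[, pd + seq_len(nd)]
  quad_str <- rowSums((fs %*% Q) * fs)
  u_str <- pgamma(f$tau2[, "tau2_str"], pr$hyper_a + des$icar$rank / 2,
                  rate = pr$hyper_b + quad_str / 2)
  fu <- f$draws[, pd + nd + seq_len(nd)]
  u_un <- pgamma(f$tau2[, "tau2_unstr"], pr$hyper_a + (nd - 1) / 2,
                 rate = pr$hyper_b + rowSums(fu^2) / 2)
  for (u in list(u_sm, u_str, u_un)) {
    expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  }
})

test_that("missing covariate rows are dropped with a message", {
  sv <- small_survey(seed = 95, n_districts = 4, clusters_per_district = 2,
                     households_per_cluster = 6)
  ch <- sv$children
  ch$wealth_index[c(2, 5)] <- NA
  expect_message(des <- build_design(ch, model_spec("m2")), "2 row")
  expect_equal(des$n, nrow(ch) - 2)
})
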