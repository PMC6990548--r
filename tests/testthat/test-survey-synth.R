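test_that("generated layouts have the expected contiguity", {
  ring <- generate_adjacency(4, "ring")
  expect_true(all(ring$degrees == 2))

  g23 <- generate_adjacency(6, "grid") # 2 x 3
  expect_equal(sort(unname(g23$degrees)), c(2, 2, 2, 2, 3, 3))

  g33 <- generate_adjacency(9, "grid") # 3 x 3
  expect_equal(max(g33$degrees), 4)    # centre cell
  expect_equal(max(graph_components(g33)), 1)

  expect_error(generate_adjacency(7, "grid"), "grid")
})

test_that("structured effects are ICAR draws: centred, autocorrelated, vanishing at infinite precision", {
  ring <- generate_adjacency(50, "ring")
  n <- 50
  # per-component sum is zero
  eff <- generate_spatial_effects(ring, tau2_str = 1, tau2_unstr = 1, seed = 3)
  expect_lt(abs(sum(eff$f_str)), 1e-10 * n)
  expect_lt(abs(sum(eff$f_unstr)), 1e-10 * n)
  # infinite structured precision collapses the structured effect
  eff_inf <- generate_spatial_effects(ring, tau2_str = Inf, tau2_unstr = 1,
                                      seed = 3)
  expect_equal(unname(eff_inf$f_str), rep(0, n))

  # positive lag-1 neighbour correlation of the ICAR draw (Monte Carlo)
  lag1 <- vapply(1:200, function(s) {
    f <- generate_spatial_effects(ring, 1, 1, seed = s)$f_str
    cor(f, f[c(2:n, 1)])
  }, numeric(1))
  expect_gt(mean(lag1), 0)
  expect_gt(mean(lag1 > 0), 0.8)

  # unstructured variance matches 1/tau2 (Monte Carlo, tau2 = 4)
  v <- vapply(1:200, function(s)
    var(generate_spatial_effects(ring, 1, 4, seed = s)$f_unstr), numeric(1))
  expect_equal(mean(v), 0.25, tolerance = 0.2)
})

test_that("per-component centring holds on disconnected graphs", {
  g2 <- adjacency_graph(list(a = "b", b = c("a", "c"), c = "b",
                             d = "e", e = "d"))
  eff <- generate_spatial_effects(g2, 1, 1, seed = 9)
  expect_lt(abs(sum(eff$f_str[c("a", "b", "c")])), 1e-10)
  expect_lt(abs(sum(eff$f_str[c("d", "e")])), 1e-10)
})

test_that("population generation books the nested hierarchy correctly", {
  des <- synth_design(n_districts = 4, layout = "ring",
                      clusters_per_district = 2, households_per_cluster = 5,
                      children_per_household = 1, seed = 2)
  g <- generate_adjacency(4, "ring")
  pop <- generate_population(des, g)
  expect_gte(nrow(pop), 40)
  expect_equal(length(unique(pop$cluster_id)), 8)
  expect_true(all(pop$survey_weight > 0))
  expect_true(all(pop$age_months >= 6 & pop$age_months <= 59))
  validate_child_table(pop)
  # weights constant within cluster
  expect_true(all(tapply(pop$survey_weight, pop$cluster_id, sd) == 0))
  # same seed reproduces the identical table
  pop2 <- generate_population(des, g)
  expect_identical(pop, pop2)
})

test_that("covariate marginals match their generator settings", {
  des <- synth_design(n_districts = 4, layout = "ring",
                      clusters_per_district = 5, households_per_cluster = 100,
                      children_per_household = 5, seed = 3)
  pop <- generate_population(des, generate_adjacency(4, "ring"))
  expect_gt(nrow(pop), 10000)
  fem <- mean(pop$gender == "female")
  expect_gte(fem, 0.48)
  expect_lte(fem, 0.52)
})

test_that("the default age curve rises to a 10-month peak and is centred", {
  grid <- 6:59
  f <- default_age_curve(grid)
  expect_equal(grid[which.max(f)], 10)
  expect_lt(abs(sum(f)), 1e-10)
  expect_lt(default_age_curve(6), default_age_curve(10))
  expect_error(default_age_curve(5), "6, 59")
  expect_error(default_age_curve(60), "6, 59")
})

test_that("simulated outcomes follow the logistic truth", {
  des <- synth_design(n_districts = 4, layout = "ring",
                      clusters_per_district = 5, households_per_cluster = 120,
                      children_per_household = 2, seed = 4)
  g <- generate_adjacency(4, "ring")
  pop <- generate_population(des, g)
  zero <- stats::setNames(rep(0, 4), g$nodes)
  eff0 <- district_effects(zero, zero)
  flat <- function(a) rep(0, length(a))

  # all effects zero: prevalence 1/2
  p0 <- true_params(beta = c(intercept = 0), age_curve = flat)
  out <- simulate_outcomes(pop, p0, eff0, seed = 5)
  expect_equal(mean(out$anaemic), 0.5, tolerance = 0.02)
  expect_equal(unname(attr(out, "linpred")), rep(0, nrow(pop)))

  # deep negative intercept: saturation
  pneg <- true_params(beta = c(intercept = -20), age_curve = flat)
  expect_lt(mean(simulate_outcomes(pop, pneg, eff0, seed = 5)$anaemic), 0.001)

  # unknown coefficient name is rejected by name
  pbad <- true_params(beta = c(intercept = 0, nonexistent_thing = 1),
                      age_curve = flat)
  expect_error(simulate_outcomes(pop, pbad, eff0, seed = 5),
               "nonexistent_thing")
})

test_that("a malaria-only truth reproduces its odds ratio empirically", {
  des <- synth_design(n_districts = 4, layout = "ring",
                      clusters_per_district = 5, households_per_cluster = 500,
                      children_per_household = 5, seed = 6)
  g <- generate_adjacency(4, "ring")
  pop <- generate_population(des, g)
  expect_gt(nrow(pop), 50000)
  zero <- stats::setNames(rep(0, 4), g$nodes)
  pm <- true_params(beta = c(intercept = 0,
                             malaria_rdt_positive = log(4.401)),
                    age_curve = function(a) rep(0, length(a)))
  out <- simulate_outcomes(pop, pm, district_effects(zero, zero), seed = 7)
  tab <- table(out$malaria_rdt, out$anaemic)
  or <- (tab["positive", "1"] / tab["positive", "0"]) /
    (tab["negative", "1"] / tab["negative", "0"])
  expect_equal(or, 4.401, tolerance = 0.15)
})

test_that("an ML fit on the true design recovers the generating coefficients", {
  sv <- simulate_survey(synth_design(n_districts = 12,
                                     clusters_per_district = 6,
                                     households_per_cluster = 60,
                                     children_per_household = 2, seed = 8))
  ch <- sv$children
  expect_gt(nrow(ch), 8000)
  X <- geoanaemia:::.fixed_design(
    ch, c("gender", "malaria_rdt", "household_size", "residence",
          "mother_education", "head_gender", "toilet", "wealth_index",
          "cluster_altitude_100m", "evi", "lst"))$X
  off <- sv$params$age_curve(ch$age_months) +
    sv$effects$f_str[ch$district_id] + sv$effects$f_unstr[ch$district_id]
  fit <- glm(ch$anaemic ~ X + offset(off), family = binomial())
  est <- coef(summary(fit))
  truth <- sv$params$beta
  rownames(est) <- sub("^X", "", rownames(est))
  rownames(est)[1] <- "intercept"
  for (nm in names(truth)) {
    expect_lt(abs(est[nm, "Estimate"] - truth[[nm]]),
              3 * est[nm, "Std. Error"])
  }
})

test_that("identical design seeds give identical surveys", {
  a <- simulate_survey(synth_design(n_districts = 6, seed = 33,
                                    households_per_cluster = 5))
  b <- simulate_survey(synth_design(n_districts = 6, seed = 33,
                                    households_per_cluster = 5))
  expect_identical(a$children, b$children)
  expect_identical(a$effects, b$effects)
})

test_that("synthetic haemoglobin respects the 11 g/dL classification rule", {
  sv <- simulate_survey(synth_design(n_districts = 4, layout = "ring",
                                     households_per_cluster = 10, seed = 12),
                        hb = TRUE)
  ch <- sv$children
  expect_true(all(ch$hb_adjusted_gdl > 0))
  expect_identical(ch$anaemic, classify_anaemia(ch$hb_adjusted_gdl))
})
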