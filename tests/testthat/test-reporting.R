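# A small fitted object whose draws we can overwrite with controlled values.
controlled_fit <- function() {
  sv <- small_survey(seed = 41, n_districts = 6, clusters_per_district = 2,
                     households_per_cluster = 8)
  des <- build_design(sv$children, model_spec("m3"), sv$graph)
  fit_geoadd(des, mcmc = mcmc_config(n_iter = 220, burn_in = 100, thin = 1,
                                     seed = 42))
}

test_that("odds ratio tables summarise exp(beta) draws correctly", {
  f <- controlled_fit()
  nkeep <- nrow(f$draws)

  fz <- f
  fz$draws[] <- 0
  az <- aor_table(fz)
  expect_false("intercept" %in% az$column)
  expect_true(all(az$AOR == 1))
  expect_true(all(az$ci_lo == 1 & az$ci_hi == 1))
  expect_false(any(az$significant))

  set.seed(43)
  fm <- f
  fm$draws[, "malaria_rdt_positive"] <- rnorm(nkeep, log(4.401), 0.01)
  am <- aor_table(fm)
  row <- am[am$column == "malaria_rdt_positive", ]
  expect_equal(row$AOR, 4.401, tolerance = 0.02)
  expect_true(row$significant)
  expect_equal(row$level, "positive")
  expect_equal(row$reference, "negative")

  # percentile oracle: interval endpoints are the order statistics
  ors <- sort(exp(fm$draws[, "malaria_rdt_positive"]))
  expect_equal(row$ci_lo, quantile(ors, 0.025, names = FALSE))
  expect_equal(row$ci_hi, quantile(ors, 0.975, names = FALSE))

  # sign-flipped draws give the reciprocal interval
  ff <- fm
  ff$draws[, "malaria_rdt_positive"] <- -fm$draws[, "malaria_rdt_positive"]
  af <- aor_table(ff)
  rf <- af[af$column == "malaria_rdt_positive", ]
  # equal up to the percentile interpolation rule's rounding
  expect_equal(rf$ci_lo, 1 / row$ci_hi, tolerance = 1e-6)
  expect_equal(rf$ci_hi, 1 / row$ci_lo, tolerance = 1e-6)
})

test_that("variance tables report positive precisions and name the dominant component", {
  f <- controlled_fit()
  vt <- variance_table(f)
  expect_setequal(vt$effect, c("tau2_age_months", "tau2_str", "tau2_unstr"))
  expect_true(all(vt$mean > 0 & vt$ci_lo > 0))
  expect_true(all(vt$ci_lo <= vt$mean & vt$mean <= vt$ci_hi))

  # forced precision draws: structured precision huge => unstructured dominant
  fd <- f
  fd$tau2[, "tau2_str"] <- 800
  fd$tau2[, "tau2_unstr"] <- 4
  expect_equal(attr(variance_table(fd), "dominance"), "unstructured")
  fd$tau2[, "tau2_str"] <- 2
  fd$tau2[, "tau2_unstr"] <- 900
  expect_equal(attr(variance_table(fd), "dominance"), "structured")

  # a pure GLM fit has no variance components
  ch <- toy_children(100, seed = 44)
  f1 <- fit_geoadd(build_design(ch, model_spec("m1",
                                               fixed_terms = "wealth_index")),
                   mcmc = mcmc_config(n_iter = 150, burn_in = 50, thin = 1,
                                      seed = 45))
  expect_equal(nrow(variance_table(f1)), 0)
})

test_that("smooth summaries are centred curves with pointwise bands", {
  f <- controlled_fit()
  fz <- f
  fz$draws[] <- 0
  sz <- smooth_summary(fz)
  expect_equal(sz$mean, rep(0, nrow(sz)))
  expect_equal(sz$ci_lo, rep(0, nrow(sz)))

  ss <- smooth_summary(f)
  expect_true(all(ss$ci_lo <= ss$mean & ss$mean <= ss$ci_hi))
  expect_equal(ss$grid, 6:59)
})

test_that("district summaries classify by credible interval and count consistently", {
  f <- controlled_fit()
  ds <- district_summary(f)
  nd <- length(unique(ds$summary$district))
  expect_equal(nd, 6)
  for (comp in c("structured", "unstructured")) {
    cc <- ds$counts[ds$counts$component == comp, ]
    expect_equal(sum(cc$Freq), nd)
  }
  expect_true(all(ds$summary$class[ds$summary$ci_lo > 0] ==
                    "significantly_positive"))
  expect_true(all(ds$summary$class[ds$summary$ci_hi < 0] ==
                    "significantly_negative"))

  # classification is invariant to the order of the draws
  fp <- f
  set.seed(46)
  fp$draws <- f$draws[sample(nrow(f$draws)), ]
  expect_equal(district_summary(fp)$summary, ds$summary)
})

test_that("district exports round-trip through CSV and flag missing polygons", {
  f <- controlled_fit()
  ds <- district_summary(f)
  csv <- tempfile(fileext = ".csv")
  export_district_summary(ds, csv)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back$mean, ds$summary$mean, tolerance = 1e-12)
  expect_equal(back$class, ds$summary$class)

  # polygons: one district of the fit plus one unknown polygon
  nodes <- unique(ds$summary$district)
  gj_in <- tempfile(fileext = ".geojson")
  squares_geojson(stats::setNames(list(c(0, 0), c(9, 9)),
                                  c(nodes[1], "nowhere")), gj_in)
  gj_out <- tempfile(fileext = ".geojson")
  export_district_summary(ds, csv, polygons_path = gj_in,
                          geojson_path = gj_out)
  gj <- jsonlite::read_json(gj_out)
  props <- lapply(gj$features, function(x) x$properties)
  ids <- vapply(props, function(p) p$id, character(1))
  expect_false(props[[which(ids == nodes[1])]]$no_data)
  expect_true(props[[which(ids == "nowhere")]]$no_data)
  expect_equal(props[[which(ids == nodes[1])]]$unstr_mean,
               ds$summary$mean[ds$summary$district == nodes[1] &
                                 ds$summary$component == "unstructured"],
               tolerance = 1e-9)
})
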