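# Small shared fixtures, built in code.

# A compact complete survey for model-level tests.
small_survey <- function(seed = 101, n_districts = 12,
                         clusters_per_district = 3,
                         households_per_cluster = 12, ...) {
  simulate_survey(synth_design(
    n_districts = n_districts, layout = "grid",
    clusters_per_district = clusters_per_district,
    households_per_cluster = households_per_cluster, seed = seed, ...))
}

# A minimal data frame for models that only use a subset of covariates.
toy_children <- function(n, seed = 1, beta0 = 0, beta1 = 0) {
  set.seed(seed)
  x <- rnorm(n)
  data.frame(wealth_index = x,
             anaemic = rbinom(n, 1, plogis(beta0 + beta1 * x)))
}

# GeoJSON FeatureCollection of unit-square districts at given (x, y) offsets.
squares_geojson <- function(offsets, path) {
  feat <- lapply(names(offsets), function(id) {
    o <- offsets[[id]]
    ring <- list(c(o[1], o[2]), c(o[1] + 1, o[2]), c(o[1] + 1, o[2] + 1),
                 c(o[1], o[2] + 1), c(o[1], o[2]))
    list(type = "Feature", properties = list(id = id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  path
}
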