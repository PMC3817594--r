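straight_route <- function(len_m) cbind(c(0, len_m), c(0, 0))

test_that("build_grid tiles a straight corridor exactly", {
  g <- build_grid(straight_route(900), cell_m = 30, buffer_m = 15)
  expect_equal(nrow(g), 30)                      # single strip of 30 cells
  expect_equal(length(unique(g$y)), 1)
  # geometry oracle: every centroid within 15 m of the axis-aligned line
  expect_true(all(abs(g$y) <= 15 & g$x >= 0 & g$x <= 900))
  expect_equal(g$x, seq(15, 885, by = 30))
  # deterministic
  expect_identical(g, build_grid(straight_route(900), 30, 15))
  expect_error(build_grid(cbind(c(0, 0), c(0, 0)), 30, 15), "positive")
  expect_error(build_grid(straight_route(900), 30, 0), "buffer")
})

test_that("grid growth is monotone in buffer and refines with cell size", {
  base <- nrow(build_grid(straight_route(900), 30, 15))
  for (b in c(30, 60, 200)) {
    expect_gte(nrow(build_grid(straight_route(900), 30, b)), base)
  }
  # halving the cell at fixed buffer >= doubles the strip
  fine <- nrow(build_grid(straight_route(900), 15, 15))
  expect_gte(fine, 2 * base)
  # the wide approach corridor geometrically contains the highway cells
  hwy <- build_grid(straight_route(900), 30, 15, "highway")
  app <- build_grid(straight_route(900), 30, 1000, "approach")
  expect_gt(nrow(app), nrow(hwy))
  expect_true(all(abs(hwy$y) <= 1000))           # centroids inside 1 km
  # bent route: cells exist near the elbow (miter gap filled)
  bent <- build_grid(rbind(c(0, 0), c(300, 0), c(300, 300)), 30, 45)
  d_elbow <- sqrt((bent$x - 300)^2 + (bent$y - 0)^2)
  expect_true(any(d_elbow <= 45))
})

test_that("predict_abundance averages member means over the grid", {
  d <- make_counts(300, "zip", c(intercept = 0.6, x1 = 0.4),
                   c(intercept = -0.3), seed = 13)
  std <- standardize_predictors(d, columns = "x1")
  m <- fit_count_model(std$data, family = "zip", count_predictors = "x1")
  set <- structure(list(models = list(list(model = m, predictors = "x1",
                                           zi_variant = "intercept")),
                        best = NULL, trace = NULL, family = "zip",
                        approach = "200m", criterion = "AICc",
                        retain_delta = 2, filter_log = NULL),
                   class = "candidate_set")
  avg <- average_models(set)
  cells <- build_grid(straight_route(900), 30, 15)
  cells$x1 <- seq(-2, 2, length.out = nrow(cells)) * std$params$sd +
    std$params$mean
  ab <- predict_abundance(avg, cells, std$params)
  expect_true(all(ab >= 0))
  # single member: equals that model's prediction
  std_cells <- standardize_predictors(as.data.frame(cells),
                                      params = std$params)$data
  expect_equal(ab, predict(m, std_cells), tolerance = 1e-12)
  # ZIP mean (1 - pi) lambda against a direct pmf-expectation oracle
  lam <- exp(m$count$estimate[1] + m$count$estimate[2] * std_cells$x1)
  pi0 <- plogis(m$zero$estimate[1])
  y <- 0:300
  expectation <- vapply(lam, function(l)
    sum(y * c(pi0 + (1 - pi0) * dpois(0, l),
              (1 - pi0) * dpois(y[-1], l))), numeric(1))
  expect_equal(ab, expectation, tolerance = 1e-8)
  # missing predictor is reported by name
  cells$x1 <- NULL
  expect_error(predict_abundance(avg, cells, std$params), "x1")
})

test_that("intercept-only averages give a constant surface", {
  d <- make_counts(200, "poisson", c(intercept = 0.5), seed = 14)
  m <- fit_count_model(d, family = "poisson")
  set <- structure(list(models = list(list(model = m,
                                           predictors = character(),
                                           zi_variant = "none")),
                        best = NULL, trace = NULL, family = "poisson",
                        approach = "200m", criterion = "AICc",
                        retain_delta = 2, filter_log = NULL),
                   class = "candidate_set")
  avg <- average_models(set)
  cells <- build_grid(straight_route(300), 30, 15)
  ab <- predict_abundance(avg, cells,
                          standardize_predictors(d,
                                                 columns = character())$params)
  expect_equal(ab, rep(exp(m$count$estimate[1]), nrow(cells)))
})

test_that("decile scores bin correctly and flag degeneracy", {
  x <- 1:100
  s <- decile_scores(x)
  expect_equal(as.vector(table(s)), rep(10, 10))
  expect_false(attr(s, "degenerate"))
  same <- decile_scores(rep(3.2, 50))
  expect_true(all(same == 1))
  expect_true(attr(same, "degenerate"))
  expect_error(decile_scores(1:9), "at least 10")
  # independent sort-and-slice oracle on distinct values
  v <- snowcross:::with_seed(3, runif(1000))
  expect_equal(as.integer(decile_scores(v)),
               as.integer(ceiling(rank(v) / 100)))
  # invariant under strictly monotone transforms
  expect_equal(as.integer(decile_scores(v)),
               as.integer(decile_scores(exp(3 * v))))
})

test_that("community scores are products over 10^(g-1)", {
  all10 <- setNames(rep(list(rep(10L, 12)), 4),
                    c("carnivores", "deer", "elk", "moose"))
  expect_equal(community_score(all10)$community_score, rep(10, 12))
  all1 <- lapply(all10, function(x) rep(1L, 12))
  expect_equal(community_score(all1)$community_score, rep(0.001, 12))
  # strictly monotone in each component; permutation-invariant
  base <- list(a = 3L, b = 5L, c = 2L, d = 7L)
  s0 <- community_score(base)$community_score
  for (g in names(base)) {
    up <- base
    up[[g]] <- up[[g]] + 1L
    expect_gt(community_score(up)$community_score, s0)
  }
  expect_equal(community_score(rev(base))$community_score, s0)
  # two-group generalization keeps the (0, 10] range
  expect_equal(community_score(list(a = 10L, b = 10L))$community_score, 10)
  bad <- list(a = rep(2L, 5), b = rep(2L, 6))
  expect_error(community_score(bad), "mismatched")
})

test_that("overlap_report classifies segments against both maps", {
  km <- 0:20
  cross <- ifelse(km >= 10 & km <= 12, 10, 1)
  appr <- ifelse(km >= 10 & km <= 12, 9, 2)
  rep1 <- overlap_report(km, cross, appr, quantile = 0.75)
  hit <- rep1[rep1$class == "both-high", ]
  expect_equal(nrow(hit), 1)
  expect_lte(hit$from_km, 10)
  expect_gte(hit$to_km, 12)
  # crossing-only-high: the less ideal mitigation case
  appr2 <- ifelse(km >= 2 & km <= 4, 9, 2)
  rep2 <- overlap_report(km, cross, appr2, quantile = 0.75)
  expect_true("crossing-only-high" %in% rep2$class)
  # constant maps: degenerate, single class
  rep3 <- overlap_report(km, rep(1, 21), rep(1, 21))
  expect_true(attr(rep3, "degenerate"))
  expect_equal(length(unique(rep3$class)), 1)
})

test_that("planted spatial preference is recovered on the grid", {
  cfg <- landscape_config(n_highway_points = 300, n_transect_points = 0,
                          highway_length_km = 20, seed = 23)
  landscape <- simulate_landscape(cfg)
  tab <- generate_predictors(cfg, landscape)
  std <- standardize_predictors(tab)
  truth <- simulation_truth("poisson", c(intercept = 0.3, water_500 = 0.8))
  d <- simulate_counts(std$data, truth, seed = 24)
  m <- fit_count_model(d, family = "poisson", count_predictors = "water_500")
  set <- structure(list(models = list(list(model = m,
                                           predictors = "water_500",
                                           zi_variant = "none")),
                        best = NULL, trace = NULL, family = "poisson",
                        approach = "500m", criterion = "AICc",
                        retain_delta = 2, filter_log = NULL),
                   class = "candidate_set")
  avg <- average_models(set)
  grid <- build_grid(straight_route(20000), 30, 15)
  cells <- cell_predictors(landscape, grid, seed = 25)
  ab <- predict_abundance(avg, cells, std$params)
  # truth surface: the generating lambda at the same cells
  std_cells <- standardize_predictors(cells, params = std$params)$data
  lam_true <- exp(0.3 + 0.8 * std_cells$water_500)
  top_pred <- decile_scores(ab) == 10
  top_true <- decile_scores(lam_true) == 10
  overlap <- sum(top_pred & top_true) / sum(top_true)
  expect_gt(overlap, 0.5)      # chance level would be 0.1
})

test_that("cells serialize to GeoJSON polygons", {
  g <- build_grid(straight_route(120), 30, 15)
  g$abundance_deer <- seq_len(nrow(g))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_cells_geojson(g, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(g))
  poly <- gj$features[[1]]$geometry
  expect_equal(poly$type, "Polygon")
  expect_length(poly$coordinates[[1]], 5)        # closed square ring
  expect_equal(gj$features[[2]]$properties$abundance_deer, 2)
})
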