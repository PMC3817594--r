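test_that("lr_test handles degenerate and reversed inputs", {
  tied <- lr_test(-100, -100, 1)
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)
  expect_warning(lr_test(-100, -101, 1), "lower log-likelihood")
  expect_error(lr_test(-100, -90, 0), "df_diff")
})

test_that("vuong_test matches an independent per-observation loop", {
  d <- make_counts(300, "zip", c(intercept = 0.8, x1 = 0.3),
                   c(intercept = 0), seed = 17)
  m_zip <- fit_count_model(d, family = "zip", count_predictors = "x1")
  m_poi <- fit_count_model(d, family = "poisson", count_predictors = "x1")
  v <- vuong_test(m_zip, m_poi, d)

  # brute-force oracle: per-observation probabilities recomputed from the
  # raw coefficient estimates with a scalar loop
  b <- m_zip$count$estimate; g <- m_zip$zero$estimate
  bp <- m_poi$count$estimate
  m_i <- vapply(seq_len(nrow(d)), function(i) {
    lam1 <- exp(b[1] + b[2] * d$x1[i])
    pi1 <- plogis(g[1])
    p1 <- if (d$count[i] == 0) pi1 + (1 - pi1) * exp(-lam1)
          else (1 - pi1) * dpois(d$count[i], lam1)
    p2 <- dpois(d$count[i], exp(bp[1] + bp[2] * d$x1[i]))
    log(p1 / p2)
  }, numeric(1))
  v_loop <- sqrt(length(m_i)) * mean(m_i) / sd(m_i)
  expect_equal(v$V, v_loop, tolerance = 1e-10)

  # identical models: undefined, flagged
  same <- vuong_test(m_zip, m_zip, d)
  expect_false(same$defined)
  expect_equal(same$preference, "undefined")
})

test_that("pick_distribution reproduces the published worked picks", {
  # carnivores / highway intercept-only comparison table
  carn_hwy <- data.frame(
    family = c("poisson", "negbin", "zip", "zinb"),
    logLik = c(-204.677, -203.204, -202.762, -202.762),
    df = c(1, 2, 2, 3))
  expect_equal(pick_distribution(carn_hwy)$pick, "zip")
  # moose / transect
  moose_trans <- data.frame(
    family = c("poisson", "negbin", "zip", "zinb"),
    logLik = c(-162.046, -161.542, -161.253, -161.253),
    df = c(1, 2, 2, 3))
  expect_equal(pick_distribution(moose_trans)$pick, "poisson")
  # exact four-way tie resolves to the simplest family, flagged
  tie <- data.frame(family = c("poisson", "negbin", "zip", "zinb"),
                    logLik = c(-100, -99, -99, -98),
                    df = c(1, 2, 2, 3))       # identical AIC = 202
  out <- pick_distribution(tie)
  expect_equal(out$pick, "poisson")
  expect_true(out$tie)
  expect_error(pick_distribution(tie[1:3, ]), "missing")
})

test_that("compare_distributions picks the planted family", {
  d <- make_counts(800, "zip", c(intercept = log(3)),
                   c(intercept = 0), seed = 55)
  ch <- compare_distributions(d)
  expect_equal(ch$pick, "zip")
  expect_equal(ch$table$pred_zero[ch$table$family == "zip"],
               sum(d$count == 0), tolerance = 0.02)
  expect_gt(ch$table$vuong[ch$table$family == "zip"], 1.96)
})

test_that("iterative_search explores, retains near-ties, and stops", {
  # empty pool -> intercept-only set
  d <- make_counts(200, "poisson", c(intercept = 0.5), seed = 61)
  s0 <- iterative_search(d, "poisson", character())
  expect_length(s0$models, 1)
  expect_length(s0$best$predictors, 0)

  # x2 is a slightly noisier copy of x1: their one-predictor models tie
  # within 2 AICc units, so both must seed iteration 2
  snowcross:::with_seed(71, {
    n <- 400
    x1 <- rnorm(n)
    x2 <- x1 + rnorm(n, sd = 0.01)
    x3 <- rnorm(n)
    d <- data.frame(x1 = x1, x2 = x2, x3 = x3,
                    count = rpois(n, exp(0.3 + 0.5 * x1 + 0.4 * x3)))
  })
  s <- iterative_search(d, "poisson", c("x1", "x2", "x3"))
  one_pred <- subset(s$trace, iteration == 1)
  a1 <- one_pred$criterion[one_pred$predictors == "x1"]
  a2 <- one_pred$criterion[one_pred$predictors == "x2"]
  expect_lt(abs(a1 - a2), 2)            # the constructed near-tie
  iter2 <- subset(s$trace, iteration == 2)$predictors
  expect_true(any(grepl("^x1\\+|\\+x1$|^x1$", iter2) & grepl("x3", iter2)))
  expect_true(any(grepl("x2", iter2)))  # the runner-up stayed a base

  # incumbent best criterion is non-increasing over iterations
  by_iter <- tapply(s$trace$criterion, s$trace$iteration, min,
                    na.rm = TRUE)
  expect_true(all(diff(cummin(by_iter)) <= 0))
  # search best never worse than the intercept-only model
  intercept_aicc <- subset(s$trace, predictors == "")$criterion
  expect_lte(s$best$model$aicc, intercept_aicc)
})

test_that("beam search matches exhaustive enumeration on small pools", {
  for (seed in 1:5) {
    d <- make_counts(300, "poisson",
                     c(intercept = 0.3, x1 = 0.5, x2 = -0.4), seed = seed)
    extra <- make_predictors(300, 3, seed = 900 + seed)
    names(extra) <- paste0("z", 1:3)
    d <- cbind(d, extra)
    pool <- c("x1", "x2", paste0("z", 1:3))
    beam <- iterative_search(d, "poisson", pool)
    exh <- exhaustive_search(d, "poisson", pool)
    expect_gte(beam$best$model$aicc, exh$best$model$aicc - 1e-6)
    expect_lte(beam$best$model$aicc - exh$best$model$aicc, 2)
  }
})

test_that("filter_candidates drops by p-value and magnitude with reasons", {
  good <- stub_model("x1", c(0.1, 0.8), c(0.2, 0.2), c(0.6, 0.01), 100)
  weak <- stub_model("x2", c(0.1, 0.3), c(0.2, 0.25), c(0.6, 0.20), 101)
  huge_se <- stub_model("x3", c(0.1, 0.9), c(0.2, 60), c(0.6, 0.01), 102)
  huge_est <- stub_model("x4", c(0.1, 80), c(0.2, 0.3), c(0.6, 0.01), 103)
  set <- stub_set(list(good, weak, huge_se, huge_est))
  out <- filter_candidates(set)
  expect_length(out$models, 1)
  expect_equal(out$models[[1]]$predictors, "x1")
  expect_setequal(out$filter_log$predictors, c("x2", "x3", "x4"))
  expect_match(out$filter_log$reason[out$filter_log$predictors == "x2"],
               "p>0.15")
  expect_match(out$filter_log$reason[out$filter_log$predictors == "x3"],
               "SE>50")
  expect_match(out$filter_log$reason[out$filter_log$predictors == "x4"],
               "estimate>50")
  # compliant set: unchanged, empty incremental log
  clean <- filter_candidates(stub_set(list(good)))
  expect_length(clean$models, 1)
  expect_equal(nrow(clean$filter_log), 0)
  # intercept p-values are exempt (p 0.6 on intercepts above survived)
  expect_true(all(out$models[[1]]$model$count$p_value[1] > 0.15))
})

test_that("average_models weights by exp(-delta/2) within the window", {
  m0 <- stub_model("x1", c(0.1, 0.5), c(0.1, 0.1), c(0.5, 0.01), 100)
  m2 <- stub_model("x2", c(0.1, 0.4), c(0.1, 0.1), c(0.5, 0.01), 102)
  m_out <- stub_model("x3", c(0.1, 0.4), c(0.1, 0.1), c(0.5, 0.01), 102.5)
  avg <- average_models(stub_set(list(m0, m2, m_out)))
  expect_length(avg$members, 2)           # delta 2.5 excluded
  expect_equal(avg$weights, c(1, exp(-1)) / (1 + exp(-1)))
  expect_equal(sum(avg$weights), 1)
  # full-average coefficient table: absent predictor contributes zero
  x2row <- avg$coef_count[avg$coef_count$term == "x2", ]
  expect_equal(x2row$estimate, 0.4 * exp(-1) / (1 + exp(-1)))
  # weights invariant to a constant shift of every criterion value
  shifted <- stub_set(list(
    stub_model("x1", c(0.1, 0.5), c(0.1, 0.1), c(0.5, 0.01), 600),
    stub_model("x2", c(0.1, 0.4), c(0.1, 0.1), c(0.5, 0.01), 602)))
  expect_equal(average_models(shifted)$weights, avg$weights)
  empty <- structure(list(models = list(), criterion = "AICc"),
                     class = "candidate_set")
  expect_error(average_models(empty), "empty")
})

test_that("single-member averages reproduce the member's predictions", {
  d <- make_counts(200, "poisson", c(intercept = 0.4, x1 = 0.5), seed = 81)
  m <- fit_count_model(d, family = "poisson", count_predictors = "x1")
  set <- structure(list(models = list(list(model = m, predictors = "x1",
                                           zi_variant = "none")),
                        best = NULL, trace = NULL, family = "poisson",
                        approach = "200m", criterion = "AICc",
                        retain_delta = 2, filter_log = NULL),
                   class = "candidate_set")
  avg <- average_models(set)
  expect_equal(avg$weights, 1)
  expect_equal(predict(avg, d), predict(m, d), tolerance = 1e-12)
})

test_that("compare_approaches flags bests, ties, and the remote winner", {
  mk <- function(aicc) stub_set(list(
    stub_model("x1", c(0.1, 0.5), c(0.1, 0.1), c(0.5, 0.01), aicc)))
  res <- list(
    "200m" = list(poisson = mk(120), negbin = mk(118)),
    "500m" = list(poisson = mk(110), negbin = mk(112)),
    "digitized" = list(poisson = mk(105), negbin = mk(121)))
  cmp <- compare_approaches(res)
  tab <- cmp$table
  expect_true(tab$best_in_approach[tab$approach == "200m" &
                                     tab$family == "negbin"])
  expect_equal(cmp$overall_best$approach, "digitized")
  # digitized cannot feed maps: remote winner is 500m/poisson
  expect_equal(cmp$best_remote$approach, "500m")
  expect_equal(cmp$best_remote$family, "poisson")
  # exact ties all flagged
  tied <- compare_approaches(list("200m" = list(poisson = mk(100)),
                                  "500m" = list(poisson = mk(100))))
  expect_true(all(tied$table$best_in_approach))
  expect_true(tied$tie)
})

test_that("a 500 m planted truth is recovered by scale comparison", {
  wins <- 0
  n_seeds <- 8
  for (seed in seq_len(n_seeds)) {
    cfg <- landscape_config(n_highway_points = 350, n_transect_points = 0,
                            cross_scale_correlation = 0.35, seed = seed)
    tab <- standardize_predictors(generate_predictors(cfg))$data
    truth <- simulation_truth("poisson",
                              c(intercept = 0.3, water_500 = 0.6,
                                herbaceous_500 = 0.5))
    d <- simulate_counts(tab, truth, seed = 500 + seed)
    pools <- approach_pools(cfg)[c("200m", "500m", "1km", "3-scales")]
    res <- list()
    for (ap in names(pools)) {
      res[[ap]] <- list(poisson = iterative_search(d, "poisson",
                                                   pools[[ap]],
                                                   approach = ap))
    }
    winner <- compare_approaches(res)$overall_best$approach
    if (winner %in% c("500m", "3-scales")) wins <- wins + 1
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("summed importance collapses scales and splits by route/sign", {
  mk_avg <- function(terms, est) {
    structure(list(coef_count = data.frame(
      term = c("(Intercept)", terms), estimate = c(0.2, est)),
      members = list(), weights = 1), class = "averaged_model")
  }
  fw <- list(
    list(route = "highway", averaged = mk_avg(c("water_200", "buildings_500"),
                                              c(0.4, -0.3))),
    list(route = "transect", averaged = mk_avg("water_1000", 0.2)),
    list(route = "transect", averaged = mk_avg("water_200", -0.1)))
  imp <- summed_importance(fw)
  water <- imp[imp$variable == "water", ]
  expect_equal(water$highway_pos, 1)
  expect_equal(water$transect_pos, 1)
  expect_equal(water$transect_neg, 1)
  expect_equal(imp[imp$variable == "buildings", ]$highway_neg, 1)
})

test_that("search traces serialize as JSON lines", {
  d <- make_counts(150, "poisson", c(intercept = 0.4, x1 = 0.5), seed = 91)
  s <- iterative_search(d, "poisson", "x1")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_search_trace(s, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(s$trace))
  first <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("iteration", "predictors", "criterion", "status")
                  %in% names(first)))
})
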