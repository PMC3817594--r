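# shared fixtures: everything is generated in code, nothing on disk

# plain standardized predictor frame x1..xp ~ N(0,1)
make_predictors <- function(n, p, seed = 1) {
  snowcross:::with_seed(seed, {
    out <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(out) <- paste0("x", seq_len(p))
    out
  })
}

# counts from a named truth on top of make_predictors()
make_counts <- function(n, family, count_coefficients,
                        zero_coefficients = NULL, dispersion = NULL,
                        seed = 1) {
  p <- length(unique(c(names(count_coefficients),
                       names(zero_coefficients))))
  vars <- setdiff(unique(c(names(count_coefficients),
                           names(zero_coefficients))), "intercept")
  x <- make_predictors(n, max(length(vars), 1), seed)
  names(x)[seq_along(vars)] <- vars
  truth <- simulation_truth(family, unlist(count_coefficients),
                            if (!is.null(zero_coefficients))
                              unlist(zero_coefficients),
                            dispersion = dispersion)
  simulate_counts(x, truth, seed = seed + 1)
}

# hand-built fitted-model stub for filter/average tests (only the fields
# those operations read)
stub_model <- function(predictors, estimates, ses, ps, aicc,
                       converged = TRUE, family = "poisson") {
  terms <- c("(Intercept)", predictors)
  list(model = structure(list(
         spec = count_model_spec(family, predictors),
         count = data.frame(term = terms, estimate = estimates,
                            se = ses, p_value = ps),
         zero = NULL, theta = NULL,
         log_likelihood = -100, df = length(terms), n = 100,
         aic = aicc, aicc = aicc, converged = converged,
         boundary = FALSE), class = "count_model"),
       predictors = predictors, zi_variant = "none")
}

stub_set <- function(models, criterion = "AICc") {
  crit <- vapply(models, function(m) m$model$aicc, numeric(1))
  structure(list(models = models, best = models[[which.min(crit)]],
                 trace = NULL, family = "poisson", approach = "200m",
                 criterion = criterion, retain_delta = 2,
                 filter_log = NULL),
            class = "candidate_set")
}

# AICc from a stats::glm fit (independent oracle path)
glm_aicc <- function(fit) {
  ll <- as.numeric(logLik(fit))
  df <- attr(logLik(fit), "df")
  n <- nobs(fit)
  2 * df - 2 * ll + 2 * df * (df + 1) / (n - df - 1)
}
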