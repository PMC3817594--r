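#' Standardize predictor columns to mean 0, sd 1
#'
#' Landscape predictors live on wildly different measurement scales
#' (proportions, areas in m^2, counts), so every predictor is centred
#' and scaled before model fitting. Training calls return the per-column
#' means and sds; applying stored parameters to new rows (prediction
#' grids) reuses the training statistics.
#'
#' @param table data.frame holding the predictor columns.
#' @param columns character vector of columns to standardize (default:
#'   all numeric columns except `point_id`, `position_km`, `highway_km`,
#'   `transect_offset_m`, `count`).
#' @param params optional `standardization_params` from a previous call;
#'   when given, its means/sds are applied instead of recomputing.
#' @return list with `data` (standardized table) and `params`
#'   (`standardization_params`: data.frame `column`, `mean`, `sd`).
#' @export
standardize_predictors <- function(table, columns = NULL, params = NULL) {
  if (is.null(columns)) {
    columns <- if (!is.null(params)) params$column else
      setdiff(names(table)[vapply(table, is.numeric, logical(1))],
              c("point_id", "position_km", "highway_km",
                "transect_offset_m", "count"))
  }
  if (is.null(params)) {
    mu <- vapply(columns, function(c) mean(table[[c]]), numeric(1))
    s <- vapply(columns, function(c) sd(table[[c]]), numeric(1))
    bad <- columns[s == 0 | !is.finite(s)]
    if (length(bad))
      stop_snowcross("constant predictor column(s): ",
                     paste(bad, collapse = ", "))
    params <- structure(data.frame(column = columns, mean = mu, sd = s,
                                   row.names = NULL),
                        class = c("standardization_params", "data.frame"))
  }
  for (i in seq_len(nrow(params))) {
    c <- params$column[i]
    if (!c %in% names(table))
      stop_snowcross("column '", c, "' missing from table")
    table[[c]] <- (table[[c]] - params$mean[i]) / params$sd[i]
  }
  list(data = table, params = params)
}

#' @rdname standardize_predictors
#' @param data standardized table to map back to original units.
#' @export
destandardize_predictors <- function(data, params) {
  for (i in seq_len(nrow(params))) {
    c <- params$column[i]
    data[[c]] <- data[[c]] * params$sd[i] + params$mean[i]
  }
  data
}

#' Specification of one count model
#'
#' @param family `"poisson"`, `"negbin"`, `"zip"` or `"zinb"`.
#' @param count_predictors predictor names for the count (log-link)
#'   component; intercept is implicit.
#' @param zero_predictors predictor names for the zero-inflation
#'   (logit-link) component: `NULL` for non-zero-inflated families,
#'   `character(0)` for an intercept-only zero part, or typically the
#'   mirror of `count_predictors`.
#' @return object of class `count_model_spec`.
#' @export
count_model_spec <- function(family, count_predictors = character(),
                             zero_predictors = NULL) {
  family <- match.arg(family, c("poisson", "negbin", "zip", "zinb"))
  zi <- family %in% c("zip", "zinb")
  if (zi && is.null(zero_predictors)) zero_predictors <- character()
  if (!zi && !is.null(zero_predictors))
    stop_snowcross("zero_predictors only apply to zip/zinb")
  structure(list(family = family,
                 count_predictors = as.character(count_predictors),
                 zero_predictors = zero_predictors),
            class = "count_model_spec")
}

.design_matrix <- function(data, predictors) {
  missing <- setdiff(predictors, names(data))
  if (length(missing))
    stop_snowcross("predictor column(s) missing: ",
                   paste(missing, collapse = ", "))
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  for (v in predictors) X <- cbind(X, data[[v]])
  colnames(X) <- c("(Intercept)", predictors)
  X
}

# ---- negative log-likelihoods with analytic gradients ----------------------
# parameter layout: beta (ncol X), then gamma (ncol Z, zero-inflated
# families), then log(theta) (negbin-type families)

.nll_poisson <- function(par, X, y) {
  eta <- drop(X %*% par)
  sum(exp(eta) - y * eta + lgamma(y + 1))
}
.grad_poisson <- function(par, X, y) {
  drop(crossprod(X, exp(drop(X %*% par)) - y))
}

# NB log-likelihood written via log1p(lambda/theta) so the theta -> Inf
# (Poisson) boundary is numerically flat instead of catastrophically
# cancelling; theta capped at exp(30) for the same reason
.nll_negbin <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[1:p])
  theta <- exp(min(par[p + 1], 30))
  lambda <- exp(eta)
  -sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
         y * (eta - log(theta + lambda)) - theta * log1p(lambda / theta))
}
.grad_negbin <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[1:p])
  theta <- exp(min(par[p + 1], 30))
  lambda <- exp(eta)
  gb <- -drop(crossprod(X, y - (theta + y) * lambda / (theta + lambda)))
  gt <- -theta * sum(digamma(y + theta) - digamma(theta) -
                       log1p(lambda / theta) +
                       (lambda - y) / (theta + lambda))
  c(gb, gt)
}

.nll_zip <- function(par, X, Z, y) {
  p <- ncol(X); q <- ncol(Z)
  eta <- drop(X %*% par[1:p])
  u <- drop(Z %*% par[p + 1:q])
  lambda <- exp(eta)
  lp <- plogis(u, log.p = TRUE)           # log pi
  l1p <- plogis(-u, log.p = TRUE)         # log (1 - pi)
  z <- y == 0
  ll <- numeric(length(y))
  # log(pi + (1-pi) e^-lambda) via log-sum-exp
  a <- lp[z]; b <- l1p[z] - lambda[z]
  m <- pmax(a, b)
  ll[z] <- m + log(exp(a - m) + exp(b - m))
  ll[!z] <- l1p[!z] + y[!z] * eta[!z] - lambda[!z] - lgamma(y[!z] + 1)
  -sum(ll)
}
.grad_zip <- function(par, X, Z, y) {
  p <- ncol(X); q <- ncol(Z)
  eta <- drop(X %*% par[1:p])
  u <- drop(Z %*% par[p + 1:q])
  lambda <- exp(eta)
  pi0 <- plogis(u)
  l1p <- plogis(-u, log.p = TRUE)
  z <- y == 0
  B <- exp(l1p - lambda)                  # (1-pi) e^-lambda
  S <- pi0 + B
  deta <- ifelse(z, -lambda * B / S, y - lambda)
  du <- ifelse(z, (pi0 * (1 - pi0) - pi0 * B) / S, -pi0)
  -c(drop(crossprod(X, deta)), drop(crossprod(Z, du)))
}

.nll_zinb <- function(par, X, Z, y) {
  p <- ncol(X); q <- ncol(Z)
  eta <- drop(X %*% par[1:p])
  u <- drop(Z %*% par[p + 1:q])
  theta <- exp(min(par[p + q + 1], 30))
  lambda <- exp(eta)
  lp <- plogis(u, log.p = TRUE)
  l1p <- plogis(-u, log.p = TRUE)
  lf0 <- -theta * log1p(lambda / theta)
  z <- y == 0
  ll <- numeric(length(y))
  a <- lp[z]; b <- l1p[z] + lf0[z]
  m <- pmax(a, b)
  ll[z] <- m + log(exp(a - m) + exp(b - m))
  yp <- y[!z]
  ll[!z] <- l1p[!z] + lgamma(yp + theta) - lgamma(theta) - lgamma(yp + 1) +
    yp * (eta[!z] - log(theta + lambda[!z])) -
    theta * log1p(lambda[!z] / theta)
  -sum(ll)
}
.grad_zinb <- function(par, X, Z, y) {
  p <- ncol(X); q <- ncol(Z)
  eta <- drop(X %*% par[1:p])
  u <- drop(Z %*% par[p + 1:q])
  theta <- exp(min(par[p + q + 1], 30))
  lambda <- exp(eta)
  pi0 <- plogis(u)
  l1p <- plogis(-u, log.p = TRUE)
  lf0 <- -theta * log1p(lambda / theta)
  z <- y == 0
  B <- exp(l1p + lf0)
  S <- pi0 + B
  deta <- ifelse(z, -B * theta * lambda / (theta + lambda) / S,
                 y - (theta + y) * lambda / (theta + lambda))
  du <- ifelse(z, (pi0 * (1 - pi0) - pi0 * B) / S, -pi0)
  dth_zero <- B * theta *
    (-log1p(lambda / theta) + lambda / (theta + lambda)) / S
  dth_pos <- theta * (digamma(y + theta) - digamma(theta) -
                        log1p(lambda / theta) +
                        (lambda - y) / (theta + lambda))
  dth <- sum(ifelse(z, dth_zero, dth_pos))
  -c(drop(crossprod(X, deta)), drop(crossprod(Z, du)), dth)
}

# moment estimate of theta, clamped away from the boundary
.theta_start <- function(y) {
  m <- mean(y); v <- var(y)
  th <- if (is.finite(v) && v > m) m^2 / (v - m) else 100
  min(max(th, 0.05), 1e4)
}

#' Fit a count model by maximum likelihood
#'
#' Joint quasi-Newton (BFGS) optimization of the negative log-likelihood
#' with analytic gradients. The count mean uses a log link; the
#' structural-zero probability of the zero-inflated families uses a
#' logit link, with the mixture likelihood
#' `P(0) = pi + (1 - pi) f(0)` and `P(y > 0) = (1 - pi) f(y)` for base
#' pmf `f`. Dispersion theta is estimated on the log scale; standard
#' errors come from the observed-information Hessian at the optimum and
#' Wald p-values are reported for count- and zero-part coefficients
#' alike. Zero-inflated fits are initialized from the corresponding base
#' family fit plus a logit intercept derived from the excess-zero
#' fraction.
#'
#' @param data data.frame with the response and predictor columns
#'   (predictors are used as-is; standardize first).
#' @param spec a [count_model_spec()]; alternatively pass `family`,
#'   `count_predictors`, `zero_predictors` directly.
#' @param response name of the count column (default `"count"`).
#' @param family,count_predictors,zero_predictors used when `spec` is
#'   missing; see [count_model_spec()].
#' @param control passed to [stats::optim()] (on top of sane defaults).
#' @return object of class `count_model`: coefficient tables for both
#'   parts, `theta`, `log_likelihood`, `df`, `n`, `converged`,
#'   `boundary`, `aic`, `aicc`.
#' @export
fit_count_model <- function(data, spec = NULL, response = "count",
                            family = NULL, count_predictors = character(),
                            zero_predictors = NULL, control = list()) {
  if (is.null(spec))
    spec <- count_model_spec(family, count_predictors, zero_predictors)
  y <- data[[response]]
  if (is.null(y)) stop_snowcross("response column '", response, "' missing")
  if (any(y < 0) || any(y != floor(y)))
    stop_snowcross("response must be non-negative integers")
  X <- .design_matrix(data, spec$count_predictors)
  zi <- spec$family %in% c("zip", "zinb")
  nb <- spec$family %in% c("negbin", "zinb")
  Z <- if (zi) .design_matrix(data, spec$zero_predictors) else NULL
  df <- ncol(X) + (if (zi) ncol(Z) else 0L) + (if (nb) 1L else 0L)
  n <- length(y)
  if (n < df + 1)
    stop_snowcross("need at least df + 1 = ", df + 1, " rows, got ", n)
  boundary <- zi && all(y == 0)

  # start values: Poisson part from a short convex BFGS run
  b0 <- c(log(mean(y) + 0.01), rep(0, ncol(X) - 1))
  pois <- optim(b0, .nll_poisson, .grad_poisson, X = X, y = y,
                method = "BFGS", control = list(maxit = 200))
  start <- switch(spec$family,
    poisson = pois$par,
    negbin = c(pois$par, log(.theta_start(y))),
    zip = , zinb = {
      p0_obs <- mean(y == 0)
      lam <- exp(drop(X %*% pois$par))
      p0_base <- mean(if (spec$family == "zip") exp(-lam) else {
        th <- .theta_start(y); (th / (th + lam))^th
      })
      excess <- (p0_obs - p0_base) / max(1 - p0_base, 1e-6)
      g0 <- qlogis(min(max(excess, 0.02), 0.95))
      c(pois$par, g0, rep(0, ncol(Z) - 1),
        if (spec$family == "zinb") log(.theta_start(y)))
    })

  fn <- switch(spec$family, poisson = .nll_poisson, negbin = .nll_negbin,
               zip = .nll_zip, zinb = .nll_zinb)
  gr <- switch(spec$family, poisson = .grad_poisson, negbin = .grad_negbin,
               zip = .grad_zip, zinb = .grad_zinb)
  args <- if (zi) list(X = X, Z = Z, y = y) else list(X = X, y = y)
  ctrl <- modifyList(list(maxit = 500, reltol = 1e-12), control)

  fit <- tryCatch(
    do.call(optim, c(list(par = start, fn = fn, gr = gr, method = "BFGS",
                          control = ctrl), args)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {  # fall back to Nelder-Mead
    fit <- tryCatch(
      do.call(optim, c(list(par = start, fn = fn,
                            control = list(maxit = 2000)), args)),
      error = function(e) NULL)
  }
  if (is.null(fit))
    return(.count_model(spec, X, Z, rep(NA_real_, df), NA_real_, n,
                        converged = FALSE, boundary = boundary,
                        message = "optimization failed"))
  hess <- tryCatch(
    do.call(optimHess, c(list(par = fit$par, fn = fn, gr = gr), args)),
    error = function(e) NULL)
  se <- rep(NA_real_, length(fit$par))
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) {
      d <- diag(vc)
      ok <- is.finite(d) & d > 0
      se[ok] <- sqrt(d[ok])
    }
  }
  converged <- fit$convergence == 0 && is.finite(fit$value) && !boundary
  .count_model(spec, X, Z, fit$par, -fit$value, n, se = se,
               converged = converged, boundary = boundary,
               message = fit$message %||% "")
}

.count_model <- function(spec, X, Z, par, ll, n, se = rep(NA_real_,
                         length(par)), converged, boundary, message = "") {
  p <- ncol(X)
  q <- if (!is.null(Z)) ncol(Z) else 0L
  nb <- spec$family %in% c("negbin", "zinb")
  zval <- par / se
  pval <- 2 * pnorm(-abs(zval))
  count_tab <- data.frame(term = colnames(X), estimate = par[1:p],
                          se = se[1:p], p_value = pval[1:p],
                          row.names = NULL)
  zero_tab <- if (q) data.frame(term = colnames(Z),
                                estimate = par[p + 1:q], se = se[p + 1:q],
                                p_value = pval[p + 1:q], row.names = NULL)
  theta <- theta_se <- NULL
  if (nb) {
    lt <- min(par[p + q + 1], 30)   # same cap as the likelihood
    theta <- exp(lt)
    theta_se <- theta * se[p + q + 1]   # delta method from log scale
  }
  df <- p + q + nb
  ic <- information_criteria(ll, df, n)
  structure(list(spec = spec, count = count_tab, zero = zero_tab,
                 theta = theta, theta_se = theta_se,
                 log_likelihood = ll, df = df, n = n,
                 aic = ic$AIC, aicc = ic$AICc,
                 converged = converged, boundary = boundary,
                 message = message),
            class = "count_model")
}

#' Akaike information criteria
#'
#' `AIC = 2 df - 2 logLik`; the small-sample correction is
#' `AICc = AIC + 2 df (df + 1) / (n - df - 1)`, undefined (`NA`, with a
#' warning-free flag) when `n <= df + 1`.
#'
#' @param log_likelihood fitted log-likelihood.
#' @param df number of estimated parameters.
#' @param n number of observations (optional; without it only AIC is
#'   returned).
#' @return list with `AIC` and `AICc`.
#' @export
information_criteria <- function(log_likelihood, df, n = NULL) {
  aic <- 2 * df - 2 * log_likelihood
  aicc <- if (is.null(n)) NA_real_
          else if (n <= df + 1) NA_real_
          else aic + 2 * df * (df + 1) / (n - df - 1)
  list(AIC = aic, AICc = aicc)
}

# fitted count mean and zero-inflation probability on (new) data
.model_means <- function(model, data) {
  X <- .design_matrix(data, model$spec$count_predictors)
  lambda <- exp(drop(X %*% model$count$estimate))
  pi0 <- if (!is.null(model$zero)) {
    Z <- .design_matrix(data, model$spec$zero_predictors)
    plogis(drop(Z %*% model$zero$estimate))
  } else rep(0, nrow(data))
  list(lambda = lambda, pi = pi0)
}

#' Per-observation probability of the observed count
#'
#' The fitted model's probability mass at each observed response value;
#' the ingredient of the Vuong test and of predicted-zero counts.
#'
#' @param model fitted [fit_count_model()] object.
#' @param data data.frame with predictors and response.
#' @param response response column name.
#' @return numeric vector of probabilities, one per row.
#' @export
count_model_prob <- function(model, data, response = "count") {
  y <- data[[response]]
  mm <- .model_means(model, data)
  base <- switch(model$spec$family,
    poisson = , zip = dpois(y, mm$lambda),
    negbin = , zinb = dnbinom(y, size = model$theta, mu = mm$lambda))
  if (model$spec$family %in% c("zip", "zinb"))
    ifelse(y == 0, mm$pi + (1 - mm$pi) * base, (1 - mm$pi) * base)
  else base
}

#' Expected number of zero counts under a fitted model
#'
#' `round(sum_i P_hat(y_i = 0))`; a diagnostic column of the
#' distribution-comparison table (a good model predicts about as many
#' zeros as were observed).
#'
#' @inheritParams count_model_prob
#' @param data data to evaluate on (default: refuses silently missing
#'   data; pass the training frame).
#' @return integer expected zero count.
#' @export
predicted_zeros <- function(model, data, response = "count") {
  if (!nrow(data)) return(0L)
  mm <- .model_means(model, data)
  p0 <- switch(model$spec$family,
    poisson = exp(-mm$lambda),
    negbin = (model$theta / (model$theta + mm$lambda))^model$theta,
    zip = mm$pi + (1 - mm$pi) * exp(-mm$lambda),
    zinb = mm$pi + (1 - mm$pi) *
      (model$theta / (model$theta + mm$lambda))^model$theta)
  as.integer(round(sum(p0)))
}

#' @export
logLik.count_model <- function(object, ...) {
  structure(object$log_likelihood, df = object$df, nobs = object$n,
            class = "logLik")
}

#' Predicted mean abundance
#'
#' @param object fitted `count_model`.
#' @param newdata data.frame of predictors.
#' @param type `"response"` (unconditional mean `(1 - pi) lambda`),
#'   `"count"` (lambda) or `"zero"` (pi).
#' @param ... unused.
#' @export
predict.count_model <- function(object, newdata,
                                type = c("response", "count", "zero"), ...) {
  type <- match.arg(type)
  mm <- .model_means(object, newdata)
  switch(type, response = (1 - mm$pi) * mm$lambda,
         count = mm$lambda, zero = mm$pi)
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf("<count_model> family=%s  n=%d  df=%d\n", x$spec$family,
              x$n, x$df))
  cat(sprintf("  logLik=%.3f  AIC=%.3f  AICc=%.3f  converged=%s%s\n",
              x$log_likelihood, x$aic, x$aicc, x$converged,
              if (x$boundary) "  [boundary: all-zero response]" else ""))
  cat("  count part:\n")
  print(x$count, digits = 4)
  if (!is.null(x$zero)) {
    cat("  zero part:\n")
    print(x$zero, digits = 4)
  }
  if (!is.null(x$theta))
    cat(sprintf("  theta=%.4f (se %.4f)\n", x$theta, x$theta_se))
  invisible(x)
}

#' Serialize a fitted model summary to JSON
#'
#' @param model fitted `count_model`.
#' @param path output path.
#' @param data optional data for the predicted-zeros column.
#' @export
write_model_json <- function(model, path, data = NULL) {
  out <- list(family = model$spec$family,
              count = model$count, zero = model$zero,
              theta = model$theta, theta_se = model$theta_se,
              log_likelihood = model$log_likelihood, df = model$df,
              n = model$n, aic = model$aic, aicc = model$aicc,
              converged = model$converged, boundary = model$boundary)
  if (!is.null(data)) out$predicted_zeros <- predicted_zeros(model, data)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
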