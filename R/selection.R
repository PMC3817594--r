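#' Likelihood-ratio test between nested count models
#'
#' `statistic = 2 (logLik_general - logLik_restricted)`, clamped at zero,
#' against a chi-squared reference with `df_diff` degrees of freedom.
#' Used to compare Poisson against negative binomial (and ZIP against
#' ZINB), where the Poisson arises as the theta -> Inf restriction.
#' The plain (uncorrected) chi-squared reference is used; for a
#' dispersion parameter on its boundary this is conservative.
#'
#' @param ll_restricted,ll_general fitted log-likelihoods.
#' @param df_diff positive integer difference in parameter count.
#' @return list with `statistic` and `p`.
#' @export
lr_test <- function(ll_restricted, ll_general, df_diff = 1) {
  if (df_diff < 1) stop_snowcross("df_diff must be >= 1")
  stat <- 2 * (ll_general - ll_restricted)
  # small negative values occur when the general model's optimum sits on
  # a flat dispersion boundary; only warn beyond optimizer tolerance
  if (stat < -1e-2)
    warning("general model has lower log-likelihood than restricted ",
            "model; upstream optimizer failure likely", call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, p = pchisq(stat, df_diff, lower.tail = FALSE))
}

#' Vuong test for non-nested count models
#'
#' Compares two models fitted on identical observations through the
#' per-observation log-ratios `m_i = log(P1(y_i) / P2(y_i))` of their
#' predicted probabilities of the observed counts:
#' `V = sqrt(N) * mean(m) / sd(m)`, asymptotically standard normal.
#' `V > 1.96` prefers model 1 (conventionally the zero-inflated model),
#' `V < -1.96` model 2, otherwise neither. The reported p-value is the
#' one-sided normal tail `P(|Z| > |V|)/... = pnorm(-|V|)`, matching the
#' convention of the usual count-model software.
#'
#' @param model1,model2 fitted [fit_count_model()] objects (same data).
#' @param data the shared observations.
#' @param response response column name.
#' @return object of class `vuong_test`: `V`, `N`, `m_bar`, `s_m`, `p`,
#'   `preference` (`"model1"`, `"model2"`, `"neither"` or
#'   `"undefined"`), `defined`.
#' @export
vuong_test <- function(model1, model2, data, response = "count") {
  if (model1$n != model2$n)
    stop_snowcross("both models must use the same observations")
  p1 <- pmax(count_model_prob(model1, data, response), .Machine$double.xmin)
  p2 <- pmax(count_model_prob(model2, data, response), .Machine$double.xmin)
  m <- log(p1 / p2)
  N <- length(m)
  s_m <- sd(m)
  if (!is.finite(s_m) || s_m == 0) {
    return(structure(list(V = NA_real_, N = N, m_bar = mean(m), s_m = s_m,
                          p = NA_real_, preference = "undefined",
                          defined = FALSE), class = "vuong_test"))
  }
  V <- sqrt(N) * mean(m) / s_m
  structure(list(V = V, N = N, m_bar = mean(m), s_m = s_m,
                 p = pnorm(-abs(V)),
                 preference = if (V > 1.96) "model1"
                              else if (V < -1.96) "model2" else "neither",
                 defined = TRUE),
            class = "vuong_test")
}

#' Choose among the four count distributions
#'
#' Combines three lines of evidence for one group/dataset: the
#' likelihood-ratio tests (Poisson vs NB, ZIP vs ZINB), the Vuong tests
#' (each base family vs its zero-inflated version, when fitted models
#' are available or V statistics are supplied), and the information
#' criterion ranking. The final pick is the family with the lowest
#' criterion value (AICc when `n` is known, otherwise AIC), with the
#' test results reported as the justification chain; exact ties go to
#' the simplest family (Poisson < NB = ZIP < ZINB) with a tie flag.
#'
#' @param table data.frame with columns `family` (all four of
#'   `poisson`, `negbin`, `zip`, `zinb`), `logLik`, `df`, optionally
#'   `n`, `pred_zero`, `vuong` (V of family vs its base).
#' @return object of class `distribution_choice`: augmented `table`,
#'   `pick`, `tie`, `lrt` (list), `justification` text.
#' @export
pick_distribution <- function(table) {
  fams <- c("poisson", "negbin", "zip", "zinb")
  if (!all(fams %in% table$family))
    stop_snowcross("need all four families; missing: ",
                   paste(setdiff(fams, table$family), collapse = ", "))
  table <- table[match(fams, table$family), , drop = FALSE]
  ll <- setNames(table$logLik, fams)
  df <- setNames(table$df, fams)
  table$aic <- 2 * df - 2 * ll
  has_n <- "n" %in% names(table) && all(is.finite(table$n))
  table$aicc <- if (has_n)
    mapply(function(l, d, n) information_criteria(l, d, n)$AICc,
           ll, df, table$n)
  else NA_real_
  crit <- if (has_n) table$aicc else table$aic
  lrt <- list(
    poisson_vs_negbin = lr_test(ll["poisson"], ll["negbin"],
                                df["negbin"] - df["poisson"]),
    zip_vs_zinb = lr_test(ll["zip"], ll["zinb"], df["zinb"] - df["zip"]))
  # ties to the printed precision resolve to the simplest family
  complexity <- c(poisson = 1, negbin = 2, zip = 2, zinb = 3)
  best <- min(crit)
  tied <- fams[abs(crit - best) < 1e-9]
  tie <- length(tied) > 1
  pick <- tied[order(complexity[tied])][1]
  just <- c(
    sprintf("LRT Poisson vs NB: %.3f (p=%.3g)",
            lrt$poisson_vs_negbin$statistic, lrt$poisson_vs_negbin$p),
    sprintf("LRT ZIP vs ZINB: %.3f (p=%.3g)",
            lrt$zip_vs_zinb$statistic, lrt$zip_vs_zinb$p),
    if ("vuong" %in% names(table))
      sprintf("Vuong %s vs base: V=%.3f", table$family, table$vuong),
    sprintf("%s ranking picks %s%s", if (has_n) "AICc" else "AIC",
            pick, if (tie) " (tie, simplest family)" else ""))
  structure(list(table = table, pick = pick, tie = tie, lrt = lrt,
                 justification = just),
            class = "distribution_choice")
}

#' Fit and compare all four distributions on one dataset
#'
#' Fits intercept-only models of each family (intercept-only zero part
#' for ZIP/ZINB), runs the likelihood-ratio and Vuong tests, tabulates
#' log-likelihood, df, AIC(c) and correctly-predicted zeros, and picks a
#' distribution via [pick_distribution()].
#'
#' @param data data.frame with the response.
#' @param response response column name.
#' @return `distribution_choice` with the fitted `models` attached.
#' @export
compare_distributions <- function(data, response = "count") {
  fams <- c("poisson", "negbin", "zip", "zinb")
  models <- lapply(fams, function(f)
    fit_count_model(data, family = f, response = response))
  names(models) <- fams
  vuong <- c(NA, NA,
             vuong_test(models$zip, models$poisson, data, response)$V,
             vuong_test(models$zinb, models$negbin, data, response)$V)
  tab <- data.frame(
    family = fams,
    logLik = vapply(models, function(m) m$log_likelihood, numeric(1)),
    df = vapply(models, function(m) m$df, numeric(1)),
    n = vapply(models, function(m) m$n, numeric(1)),
    pred_zero = vapply(models, predicted_zeros, integer(1), data = data),
    vuong = vuong, row.names = NULL)
  out <- pick_distribution(tab)
  out$models <- models
  out$true_zeros <- sum(data[[response]] == 0)
  out
}

# criterion value of a fitted model; NA (e.g. AICc undefined) sorts last
.crit_value <- function(model, criterion) {
  v <- if (criterion == "AICc") model$aicc else model$aic
  if (is.null(v) || !is.finite(v)) Inf else v
}

.set_key <- function(preds, variant) {
  paste(paste(sort(preds), collapse = "+"), variant, sep = "|")
}

#' Branching AICc beam search over a predictor pool
#'
#' Forward model search for large predictor pools where exhaustive
#' enumeration (2^45 models at the full pool) is infeasible. Starting
#' from the intercept-only base model, each iteration extends every
#' current base model with each absent pool predictor, fits all
#' extensions, and keeps *all* models within `retain_delta` of the
#' iteration's best criterion value as bases for the next iteration, as
#' long as the best criterion value keeps strictly decreasing. Duplicate
#' predictor sets reached along different branches are fitted once;
#' failed fits are logged and skipped. For zero-inflated families the
#' zero component either stays intercept-only (`zi_variant =
#' "intercept"`), mirrors the count predictors (`"mirror"`), or both
#' lists are searched and pooled (`"both"`, the default).
#'
#' @param data model-ready data.frame (standardized predictors).
#' @param family count family.
#' @param predictor_pool character vector of candidate predictors.
#' @param response response column name.
#' @param zi_variant zero-part handling for zip/zinb (ignored otherwise).
#' @param retain_delta beam retention window on the criterion
#'   (default 2).
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @param approach optional label carried through to reports.
#' @return object of class `candidate_set`: `models` (every distinct
#'   fitted model, each carrying its spec), `trace` (one row per fit:
#'   iteration, predictors, variant, logLik, df, criterion, status),
#'   `best`, `family`, `approach`, `criterion`, `filter_log`.
#' @export
iterative_search <- function(data, family, predictor_pool,
                             response = "count",
                             zi_variant = c("both", "intercept", "mirror"),
                             retain_delta = 2,
                             criterion = c("AICc", "AIC"),
                             approach = NA_character_) {
  zi_variant <- match.arg(zi_variant)
  criterion <- match.arg(criterion)
  zi <- family %in% c("zip", "zinb")
  variants <- if (!zi) "none"
              else if (zi_variant == "both") c("intercept", "mirror")
              else zi_variant

  cache <- new.env(parent = emptyenv())
  trace <- list()
  fit_one <- function(preds, variant, iteration) {
    key <- .set_key(preds, variant)
    if (!is.null(cache[[key]])) return(cache[[key]])
    zp <- if (!zi) NULL
          else if (variant == "mirror") preds else character()
    model <- tryCatch(
      fit_count_model(data, family = family, response = response,
                      count_predictors = preds, zero_predictors = zp),
      error = function(e) e)
    failed <- inherits(model, "error")
    trace[[length(trace) + 1]] <<- data.frame(
      iteration = iteration,
      predictors = paste(preds, collapse = "+"),
      zi_variant = variant, family = family,
      logLik = if (failed) NA_real_ else model$log_likelihood,
      df = if (failed) NA_integer_ else model$df,
      criterion = if (failed) NA_real_ else .crit_value(model, criterion),
      status = if (failed) paste("error:", conditionMessage(model))
               else if (!model$converged) "not converged" else "ok")
    if (failed) model <- NULL
    cache[[key]] <- list(model = model, predictors = preds,
                         zi_variant = variant)
    cache[[key]]
  }

  out_models <- list()
  for (variant in variants) {
    base0 <- fit_one(character(), variant, 0L)
    incumbent <- if (!is.null(base0$model) && base0$model$converged)
      .crit_value(base0$model, criterion) else Inf
    bases <- list(character())
    iteration <- 0L
    repeat {
      iteration <- iteration + 1L
      cand <- list()
      for (b in bases) {
        for (v in setdiff(predictor_pool, b)) {
          cand[[length(cand) + 1]] <- fit_one(c(b, v), variant, iteration)
        }
      }
      if (!length(cand)) break
      ok <- vapply(cand, function(c)
        !is.null(c$model) && c$model$converged, logical(1))
      if (!any(ok)) break
      crit <- vapply(cand[ok], function(c)
        .crit_value(c$model, criterion), numeric(1))
      iter_best <- min(crit)
      if (!(iter_best < incumbent)) break       # no reduction: stop
      incumbent <- iter_best
      keep <- crit <= iter_best + retain_delta
      bases <- unique(lapply(cand[ok][keep], `[[`, "predictors"))
    }
  }
  keys <- ls(cache)
  models <- lapply(keys, function(k) cache[[k]])
  models <- Filter(function(m) !is.null(m$model), models)
  crit_all <- vapply(models, function(m)
    if (m$model$converged) .crit_value(m$model, criterion) else Inf,
    numeric(1))
  structure(list(models = models,
                 best = if (length(models)) models[[which.min(crit_all)]]
                        else NULL,
                 trace = do.call(rbind, trace),
                 family = family, approach = approach,
                 criterion = criterion, retain_delta = retain_delta,
                 filter_log = NULL),
            class = "candidate_set")
}

#' Exhaustively fit every predictor subset
#'
#' Companion to [iterative_search()] for small pools (used for the
#' remaining spatial approaches, and as the search's test oracle).
#'
#' @inheritParams iterative_search
#' @return a `candidate_set` containing all `2^length(pool)` models
#'   (times zero-part variants for zip/zinb).
#' @export
exhaustive_search <- function(data, family, predictor_pool,
                              response = "count",
                              zi_variant = c("both", "intercept", "mirror"),
                              criterion = c("AICc", "AIC"),
                              approach = NA_character_) {
  zi_variant <- match.arg(zi_variant)
  criterion <- match.arg(criterion)
  if (length(predictor_pool) > 16)
    stop_snowcross("pool too large for exhaustive enumeration; ",
                   "use iterative_search()")
  zi <- family %in% c("zip", "zinb")
  variants <- if (!zi) "none"
              else if (zi_variant == "both") c("intercept", "mirror")
              else zi_variant
  models <- list()
  trace <- list()
  for (variant in variants) {
    for (mask in 0:(2^length(predictor_pool) - 1)) {
      preds <- predictor_pool[bitwAnd(mask, 2^(seq_along(predictor_pool) -
                                                 1)) > 0]
      if (variant == "mirror" && !length(preds)) next  # same as intercept
      zp <- if (!zi) NULL
            else if (variant == "mirror") preds else character()
      model <- tryCatch(
        fit_count_model(data, family = family, response = response,
                        count_predictors = preds, zero_predictors = zp),
        error = function(e) NULL)
      if (is.null(model)) next
      models[[length(models) + 1]] <- list(model = model,
                                           predictors = preds,
                                           zi_variant = variant)
    }
  }
  crit_all <- vapply(models, function(m)
    if (m$model$converged) .crit_value(m$model, criterion) else Inf,
    numeric(1))
  structure(list(models = models,
                 best = if (length(models)) models[[which.min(crit_all)]]
                        else NULL,
                 trace = NULL, family = family, approach = approach,
                 criterion = criterion, retain_delta = NA_real_,
                 filter_log = NULL),
            class = "candidate_set")
}

#' Filter candidate models on predictor significance and estimate size
#'
#' Post-processing of a candidate set before averaging: removes any
#' model containing a non-intercept coefficient (count or zero part)
#' with Wald `p > p_cutoff` (default 0.15, a deliberately liberal
#' stepwise-style cutoff that mostly weeds out uninformative fits), any
#' model with `|estimate| > magnitude_cap` or `SE > magnitude_cap`
#' (default 50; such values indicate lack of fit / separation), and any
#' non-converged model. Intercepts are exempt from the p-value rule so
#' intercept-only models survive. Every removal is logged with its
#' reason.
#'
#' @param set a `candidate_set`.
#' @param p_cutoff p-value cutoff for non-intercept predictors.
#' @param magnitude_cap cap on `|estimate|` and SE.
#' @return the filtered `candidate_set`; removals appended to
#'   `$filter_log` (data.frame `predictors`, `zi_variant`, `reason`).
#' @export
filter_candidates <- function(set, p_cutoff = 0.15, magnitude_cap = 50) {
  log <- list()
  keep <- vapply(set$models, function(entry) {
    m <- entry$model
    label <- paste(entry$predictors, collapse = "+")
    reason <- NULL
    tabs <- list(m$count, m$zero)
    if (!m$converged) {
      reason <- "not converged"
    } else {
      for (tab in tabs) {
        if (is.null(tab)) next
        nonint <- tab$term != "(Intercept)"
        if (any(!is.finite(tab$se))) reason <- c(reason, "SE unavailable")
        if (any(abs(tab$estimate) > magnitude_cap, na.rm = TRUE))
          reason <- c(reason, sprintf("estimate>%g", magnitude_cap))
        if (any(tab$se > magnitude_cap, na.rm = TRUE))
          reason <- c(reason, sprintf("SE>%g", magnitude_cap))
        if (any(tab$p_value[nonint] > p_cutoff, na.rm = TRUE))
          reason <- c(reason, sprintf("p>%g", p_cutoff))
      }
    }
    if (length(reason)) {
      log[[length(log) + 1]] <<- data.frame(
        predictors = label, zi_variant = entry$zi_variant,
        reason = paste(unique(reason), collapse = "; "))
      FALSE
    } else TRUE
  }, logical(1))
  set$models <- set$models[keep]
  crit_all <- vapply(set$models, function(m)
    .crit_value(m$model, set$criterion), numeric(1))
  set$best <- if (length(set$models)) set$models[[which.min(crit_all)]]
              else NULL
  new_log <- if (length(log)) do.call(rbind, log) else
    data.frame(predictors = character(), zi_variant = character(),
               reason = character())
  set$filter_log <- rbind(set$filter_log, new_log)
  set
}

#' Average the top-ranked candidate models by Akaike weight
#'
#' Members are the models within `delta` (default 2) criterion units of
#' the best model; each gets weight proportional to `exp(-delta_i / 2)`.
#' Predictions are the weight-averaged per-model predicted abundances.
#' The averaged coefficient table is a full average: a predictor absent
#' from a member contributes 0 through that member.
#'
#' @param set a (typically filtered) `candidate_set`.
#' @param delta averaging window on the criterion.
#' @return object of class `averaged_model`: `members`, `delta_values`,
#'   `weights`, `coef_count`, `coef_zero`, `family`, `criterion`.
#' @export
average_models <- function(set, delta = 2) {
  if (!length(set$models))
    stop_snowcross("no candidate models to average (set empty after ",
                   "filtering)")
  crit <- vapply(set$models, function(m)
    .crit_value(m$model, set$criterion), numeric(1))
  best <- min(crit)
  idx <- which(crit - best <= delta)
  d <- crit[idx] - best
  w <- exp(-d / 2)
  w <- w / sum(w)
  members <- set$models[idx]

  avg_table <- function(part) {
    terms <- unique(unlist(lapply(members, function(m)
      m$model[[part]]$term)))
    if (!length(terms)) return(NULL)
    est <- sapply(terms, function(t) {
      sum(vapply(seq_along(members), function(i) {
        tab <- members[[i]]$model[[part]]
        v <- if (!is.null(tab) && t %in% tab$term)
          tab$estimate[tab$term == t] else 0
        w[i] * v
      }, numeric(1)))
    })
    data.frame(term = terms, estimate = unname(est), row.names = NULL)
  }
  structure(list(members = members, delta_values = d, weights = w,
                 coef_count = avg_table("count"),
                 coef_zero = avg_table("zero"),
                 family = set$family, criterion = set$criterion,
                 approach = set$approach),
            class = "averaged_model")
}

#' @export
predict.averaged_model <- function(object, newdata, ...) {
  pred <- vapply(seq_along(object$members), function(i)
    object$weights[i] * predict(object$members[[i]]$model, newdata),
    numeric(nrow(newdata)))
  if (is.null(dim(pred))) sum(pred) else rowSums(pred)
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> family=%s  members=%d  criterion=%s\n",
              x$family, length(x$members), x$criterion))
  print(data.frame(
    predictors = vapply(x$members, function(m)
      paste(m$predictors, collapse = "+"), character(1)),
    delta = x$delta_values, weight = x$weights), digits = 3)
  invisible(x)
}

# ---- approaches ------------------------------------------------------------

.scale_label <- function(s) {
  ifelse(s >= 1000, paste0(s / 1000, "km"), paste0(s, "m"))
}

#' Candidate predictor pools of the six spatial approaches
#'
#' One pool per modeling approach: each single remote-sensed scale, all
#' remote-sensed scales together, the digitized perceptual-area
#' variables, and everything combined (45 candidates at the default
#' catalogue, which is what makes exhaustive enumeration infeasible).
#'
#' @param config a [landscape_config()] (its catalogue defines the
#'   columns).
#' @return named list of character vectors; names like `"200m"`,
#'   `"500m"`, `"1km"`, `"3-scales"`, `"digitized"`, `"combined"`.
#' @export
approach_pools <- function(config) {
  cat <- config$catalogue
  scales <- config$scale_set
  pools <- lapply(scales, function(s) paste(cat$remote, s, sep = "_"))
  names(pools) <- .scale_label(scales)
  pools[[paste0(length(scales), "-scales")]] <- unlist(
    lapply(scales, function(s) paste(cat$remote, s, sep = "_")),
    use.names = FALSE)
  pools[["digitized"]] <- cat$digitized
  pools[["combined"]] <- c(pools[[paste0(length(scales), "-scales")]],
                           cat$digitized)
  pools
}

#' Rank spatial approaches and families by best candidate AICc
#'
#' Takes the per-approach, per-family candidate sets of one
#' group/dataset and reports the best criterion value in every cell,
#' flagging the best family within each approach, the overall best
#' cell, and separately the best cell among the remote-sensed
#' approaches (single scales and all-scales; the digitized variables
#' have no landscape-wide coverage, so only remote-sensed frameworks
#' can feed the prediction maps).
#'
#' @param results nested named list: `results[[approach]][[family]]` is
#'   a `candidate_set` (or `NULL` for an empty cell).
#' @return object of class `approach_comparison`: long data.frame
#'   `table` (`approach`, `family`, `best_value`, `n_models`, flags),
#'   plus `overall_best` and `best_remote` (lists with `approach`,
#'   `family`).
#' @export
compare_approaches <- function(results) {
  rows <- list()
  for (ap in names(results)) {
    for (fam in names(results[[ap]])) {
      set <- results[[ap]][[fam]]
      val <- if (is.null(set) || is.null(set$best)) NA_real_
             else .crit_value(set$best$model, set$criterion)
      rows[[length(rows) + 1]] <- data.frame(
        approach = ap, family = fam, best_value = val,
        n_models = if (is.null(set)) 0L else length(set$models))
    }
  }
  tab <- do.call(rbind, rows)
  tab$best_in_approach <- FALSE
  for (ap in unique(tab$approach)) {
    i <- which(tab$approach == ap)
    v <- tab$best_value[i]
    if (all(is.na(v))) next
    tab$best_in_approach[i[which(v <= min(v, na.rm = TRUE) + 1e-9)]] <- TRUE
  }
  pick_best <- function(sub) {
    if (all(is.na(sub$best_value))) return(NULL)
    j <- which.min(sub$best_value)
    list(approach = sub$approach[j], family = sub$family[j],
         value = sub$best_value[j])
  }
  overall <- pick_best(tab)
  remote_aps <- setdiff(unique(tab$approach), c("digitized", "combined"))
  best_remote <- pick_best(tab[tab$approach %in% remote_aps, , drop = FALSE])
  tab$overall_best <- !is.null(overall) &
    tab$approach == overall$approach & tab$family == overall$family &
    abs(tab$best_value - overall$value) < 1e-9
  tie <- sum(tab$best_value <= min(tab$best_value, na.rm = TRUE) + 1e-9,
             na.rm = TRUE) > 1
  structure(list(table = tab, overall_best = overall,
                 best_remote = best_remote, tie = tie),
            class = "approach_comparison")
}

#' Summed importance of predictors across mapping frameworks
#'
#' Counts how often each base landscape variable entered an averaged
#' mapping model as a positive or a negative predictor (sign of its
#' averaged count-part coefficient), split by route type, across the
#' frameworks used for prediction maps. Scale suffixes are collapsed so
#' `water_200` and `water_1000` both tally as `water`.
#'
#' @param frameworks list of entries `list(route =
#'   "highway"|"transect", averaged = <averaged_model>)`.
#' @return data.frame `variable`, `highway_pos`, `highway_neg`,
#'   `transect_pos`, `transect_neg`.
#' @export
summed_importance <- function(frameworks) {
  tally <- list()
  bump <- function(var, col) {
    if (is.null(tally[[var]]))
      tally[[var]] <<- c(highway_pos = 0, highway_neg = 0,
                         transect_pos = 0, transect_neg = 0)
    tally[[var]][col] <<- tally[[var]][col] + 1
  }
  for (fw in frameworks) {
    tab <- fw$averaged$coef_count
    tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
    for (i in seq_len(nrow(tab))) {
      var <- sub("_\\d+$", "", tab$term[i])
      side <- if (fw$route == "highway") "highway" else "transect"
      sign_col <- paste0(side, if (tab$estimate[i] >= 0) "_pos" else "_neg")
      bump(var, sign_col)
    }
  }
  if (!length(tally))
    return(data.frame(variable = character(), highway_pos = integer(),
                      highway_neg = integer(), transect_pos = integer(),
                      transect_neg = integer()))
  out <- data.frame(variable = names(tally),
                    do.call(rbind, tally), row.names = NULL)
  out[order(out$variable), ]
}

#' Write a search trace as JSON lines
#'
#' One fitted model per line: predictors, family, zero-part variant,
#' log-likelihood, df, criterion value and status.
#'
#' @param set a `candidate_set` with a `trace`.
#' @param path output path.
#' @export
write_search_trace <- function(set, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  tr <- set$trace
  for (i in seq_len(nrow(tr))) {
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}
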