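#' Catalogue of candidate landscape predictors
#'
#' Names the two predictor families used throughout the package: 12
#' hand-digitized habitat proportions measured inside a 200 m "perceptual
#' area" around each survey point, and 11 remote-sensed land-cover /
#' infrastructure variables measured in buffers at each spatial scale.
#' Remote-sensed columns carry a `_<radius>` suffix per scale, so the
#' default three-scale catalogue exposes 12 + 11 x 3 = 45 candidate
#' predictors.
#'
#' @param scale_set numeric vector of buffer radii in metres,
#'   strictly increasing.
#' @return list with `digitized`, `remote` (base names) and `columns`
#'   (all candidate predictor column names).
#' @export
predictor_catalogue <- function(scale_set = c(200, 500, 1000)) {
  digitized <- c("forest", "shrub", "herb", "riparian", "freshwater",
                 "unvegetated", "highway", "road", "railroad",
                 "residential", "disturbed", "wetland_pap")
  remote <- c("water", "exposed", "low_shrub", "wetland", "herbaceous",
              "dense_conifer", "open_conifer", "open_broadleaf",
              "gravel_road_len", "paved_road_len", "buildings")
  cols <- c(digitized,
            as.vector(t(outer(remote, scale_set, paste, sep = "_"))))
  if (anyDuplicated(cols))
    stop_snowcross("predictor catalogue name collision: ",
                   paste(unique(cols[duplicated(cols)]), collapse = ", "))
  list(digitized = digitized, remote = remote, columns = cols)
}

#' Configuration of a synthetic survey landscape
#'
#' Describes the world the generator draws from: how many highway and
#' transect survey points, the highway length, the number of off-road
#' transects (1 km each, roughly parallel to the highway), the buffer
#' radii of the remote-sensed predictors, and how strongly the scale
#' variants of one variable are correlated with each other
#' (`cross_scale_correlation`, the latent shared-field weight that
#' reproduces the multicollinearity of nested buffers).
#'
#' Defaults follow the reference study design: 463 highway points, 308
#' transect points, a 95 km highway, ten transects, scales 200/500/1000 m,
#' and the four modeled mammal groups.
#'
#' @param n_highway_points,n_transect_points positive integer counts.
#' @param highway_length_km positive highway length (km).
#' @param n_transects positive integer number of 1 km transects.
#' @param scale_set strictly increasing positive radii (m).
#' @param cross_scale_correlation value in `[0, 1)`.
#' @param species character vector of modeled groups.
#' @param seed integer seed controlling every random draw.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(n_highway_points = 463,
                             n_transect_points = 308,
                             highway_length_km = 95,
                             n_transects = 10,
                             scale_set = c(200, 500, 1000),
                             cross_scale_correlation = 0.6,
                             species = c("carnivores", "deer", "elk", "moose"),
                             seed = 1L) {
  if (n_highway_points + n_transect_points <= 0)
    stop_snowcross("at least one survey point must be requested")
  if (n_highway_points < 0 || n_transect_points < 0)
    stop_snowcross("point counts must be non-negative")
  if (highway_length_km <= 0)
    stop_snowcross("highway_length_km must be positive")
  if (n_transects <= 0)
    stop_snowcross("n_transects must be positive")
  if (any(scale_set <= 0) || is.unsorted(scale_set, strictly = TRUE))
    stop_snowcross("scale_set radii must be positive and strictly increasing")
  if (cross_scale_correlation < 0 || cross_scale_correlation >= 1)
    stop_snowcross("cross_scale_correlation must lie in [0, 1)")
  catalogue <- predictor_catalogue(scale_set)
  structure(list(n_highway_points = as.integer(n_highway_points),
                 n_transect_points = as.integer(n_transect_points),
                 highway_length_km = highway_length_km,
                 n_transects = as.integer(n_transects),
                 scale_set = scale_set,
                 cross_scale_correlation = cross_scale_correlation,
                 species = species,
                 catalogue = catalogue,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Ground truth for count and track simulation
#'
#' Bundles the generating parameters of one species group: the count
#' family, log-link coefficients for the count mean, logit-link
#' coefficients for the structural-zero probability (zero-inflated
#' families only), the negative-binomial dispersion theta (variance
#' mu + mu^2/theta), and the true highway permeability used by the track
#' simulator.
#'
#' @param family one of `"poisson"`, `"negbin"`, `"zip"`, `"zinb"`.
#' @param count_coefficients named numeric vector; must contain
#'   `"intercept"`, other names must match predictor columns.
#' @param zero_coefficients named numeric vector for the zero part, or
#'   `NULL` for non-zero-inflated families.
#' @param dispersion positive theta, required iff family is `negbin`
#'   or `zinb`.
#' @param permeability_truth value in `[0, 1]`; probability that a
#'   simulated highway crossing attempt succeeds.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(family,
                             count_coefficients = c(intercept = 0),
                             zero_coefficients = NULL,
                             dispersion = NULL,
                             permeability_truth = NA_real_) {
  family <- match.arg(family, c("poisson", "negbin", "zip", "zinb"))
  zi <- family %in% c("zip", "zinb")
  nb <- family %in% c("negbin", "zinb")
  if (is.null(names(count_coefficients)) ||
      !"intercept" %in% names(count_coefficients))
    stop_snowcross("count_coefficients must be named and include 'intercept'")
  if (zi) {
    if (is.null(zero_coefficients) || !length(zero_coefficients))
      stop_snowcross("zero-inflated family '", family,
                     "' needs zero_coefficients")
  } else if (length(zero_coefficients)) {
    stop_snowcross("zero_coefficients must be empty for family '", family, "'")
  }
  if (nb) {
    if (is.null(dispersion) || dispersion <= 0)
      stop_snowcross("family '", family, "' needs dispersion > 0")
  } else if (!is.null(dispersion)) {
    stop_snowcross("dispersion only applies to negbin/zinb")
  }
  if (!is.na(permeability_truth) &&
      (permeability_truth < 0 || permeability_truth > 1))
    stop_snowcross("permeability_truth must lie in [0, 1]")
  structure(list(family = family,
                 count_coefficients = count_coefficients,
                 zero_coefficients = zero_coefficients,
                 dispersion = dispersion,
                 permeability_truth = permeability_truth),
            class = "simulation_truth")
}

# ---- latent landscape ------------------------------------------------------

# Smooth 1-d random field along the highway axis: a low-order Fourier
# series with 1/k amplitude decay, normalized to unit variance over the
# route, so spatial structure (and hence plantable preference regions)
# exists without any raster input.
.random_field <- function(n_harmonics = 6) {
  a <- rnorm(n_harmonics) / seq_len(n_harmonics)
  b <- rnorm(n_harmonics) / seq_len(n_harmonics)
  norm <- sqrt(sum(a^2 + b^2) / 2)
  list(a = a / norm, b = b / norm)
}

.eval_field <- function(field, km, length_km) {
  k <- seq_along(field$a)
  ang <- outer(2 * pi * km / length_km, k)
  drop(sin(ang) %*% field$a + cos(ang) %*% field$b)
}

#' Draw the latent landscape shared by all survey points and grid cells
#'
#' The landscape is a set of smooth unit-variance random fields along the
#' highway axis, one per remote-sensed variable. Survey points and
#' prediction-grid cells sample the same fields, so highway, transect and
#' map predictors are mutually consistent views of one terrain.
#'
#' @param config a [landscape_config()].
#' @return object of class `landscape` (field coefficients plus config).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    fields <- lapply(config$catalogue$remote, function(v) .random_field())
    names(fields) <- config$catalogue$remote
    structure(list(config = config, fields = fields), class = "landscape")
  })
}

# map each digitized class onto the remote latent it is a noisy view of
.digitized_map <- c(forest = "dense_conifer", shrub = "low_shrub",
                    herb = "herbaceous", riparian = "water",
                    freshwater = "water", unvegetated = "exposed",
                    highway = "paved_road_len", road = "gravel_road_len",
                    railroad = "exposed", residential = "buildings",
                    disturbed = "exposed", wetland_pap = "wetland")

# baseline log-abundance of each digitized class in the composition
.digitized_base <- c(forest = 1.5, shrub = 0.5, herb = 0.5, riparian = -0.5,
                     freshwater = -1, unvegetated = -0.5, highway = -0.5,
                     road = -1, railroad = -2, residential = -1,
                     disturbed = -1.5, wetland_pap = -1)

# typical buffer-area proportions of the EOSD-style classes
.remote_base_prop <- c(water = 0.05, exposed = 0.08, low_shrub = 0.15,
                       wetland = 0.07, herbaceous = 0.20,
                       dense_conifer = 0.35, open_conifer = 0.25,
                       open_broadleaf = 0.12)

# Sample the 45 predictor columns for points at the given highway-axis
# positions.  Caller owns the RNG state (deterministic under with_seed).
.sample_predictors <- function(landscape, highway_km) {
  cfg <- landscape$config
  n <- length(highway_km)
  rho <- cfg$cross_scale_correlation
  remote <- cfg$catalogue$remote
  scales <- cfg$scale_set
  w_field <- 0.7                       # field vs point-level noise split

  # per-point scale-free latent of each remote variable
  shared <- sapply(remote, function(v) {
    w_field * .eval_field(landscape$fields[[v]], highway_km,
                          cfg$highway_length_km) +
      sqrt(1 - w_field^2) * rnorm(n)
  })
  shared <- matrix(shared, nrow = n,
                   dimnames = list(NULL, remote))

  out <- list()
  # digitized composition: correlated noisy views of the shared latents,
  # squashed through a softmax so the 12 proportions lie in [0,1]
  dig <- cfg$catalogue$digitized
  lat <- sapply(dig, function(j) {
    0.7 * shared[, .digitized_map[[j]]] + sqrt(1 - 0.49) * rnorm(n)
  })
  lat <- matrix(lat, nrow = n)
  expo <- exp(sweep(0.9 * lat, 2, .digitized_base[dig], `+`))
  prop <- expo / rowSums(expo)
  for (i in seq_along(dig)) out[[dig[i]]] <- prop[, i]

  # remote-sensed variables: shared latent mixed with scale-specific
  # noise (cross-scale correlation ~ rho), then transformed to natural
  # units (areas in m^2, road lengths in m, building counts)
  for (v in remote) {
    for (r in scales) {
      z <- sqrt(rho) * shared[, v] + sqrt(1 - rho) * rnorm(n)
      col <- paste(v, r, sep = "_")
      # transform slopes kept gentle (0.4) so the Pearson correlation of
      # the delivered columns stays near the latent cross-scale value
      out[[col]] <- if (v %in% names(.remote_base_prop)) {
        plogis(0.4 * z + qlogis(.remote_base_prop[[v]])) * pi * r^2
      } else if (v == "gravel_road_len") {
        exp(0.4 * z) * 150 * (r / 200)
      } else if (v == "paved_road_len") {
        exp(0.4 * z) * 250 * (r / 200)
      } else {                                   # buildings
        floor(exp(0.4 * z + log(2)) * (r / 200)^2)
      }
    }
  }
  as.data.frame(out[cfg$catalogue$columns], optional = TRUE)
}

.survey_points <- function(config) {
  nh <- config$n_highway_points
  nt <- config$n_transect_points
  hw <- data.frame(point_id = seq_len(nh),
                   route = rep("highway", nh),
                   position_km = sort(runif(nh, 0, config$highway_length_km)),
                   transect_offset_m = NA_real_)
  hw$highway_km <- hw$position_km
  tr <- NULL
  if (nt > 0) {
    id <- rep(seq_len(config$n_transects), length.out = nt)
    anchor <- config$highway_length_km * (id - 0.5) / config$n_transects
    along <- runif(nt, 0, 1)                    # 1 km transects
    tr <- data.frame(point_id = nh + seq_len(nt),
                     route = paste0("transect-", id),
                     position_km = along,
                     transect_offset_m = runif(nt, 10, 900),
                     highway_km = pmin(anchor + along,
                                       config$highway_length_km))
  }
  rbind(hw, tr)
}

#' Generate the multi-scale predictor table for a synthetic survey
#'
#' One row per survey point (highway rows flagged by `route == "highway"`,
#' transect rows by `"transect-<k>"`), 45 candidate predictor columns at
#' the default three-scale catalogue. Scale variants of each remote-sensed
#' variable are correlated near `cross_scale_correlation`; digitized
#' proportions lie in `[0, 1]`. Fully deterministic given `config$seed`.
#'
#' @param config a [landscape_config()].
#' @param landscape optionally a pre-built [simulate_landscape()] object
#'   (to share one terrain between surveys and prediction grids).
#' @return data.frame with point metadata columns (`point_id`, `route`,
#'   `position_km`, `highway_km`, `transect_offset_m`) and one column per
#'   catalogue predictor; the catalogue is attached as attribute
#'   `"catalogue"`.
#' @export
generate_predictors <- function(config, landscape = NULL) {
  stopifnot(inherits(config, "landscape_config"))
  landscape <- landscape %||% simulate_landscape(config)
  pts <- with_seed(config$seed + 1L, .survey_points(config))
  pred <- with_seed(config$seed + 2L,
                    .sample_predictors(landscape, pts$highway_km))
  out <- cbind(pts[c("point_id", "route", "position_km",
                     "transect_offset_m", "highway_km")], pred)
  attr(out, "catalogue") <- config$catalogue
  out
}

# ---- count simulation ------------------------------------------------------

.linear_predictor <- function(predictors, coefficients) {
  vars <- setdiff(names(coefficients), "intercept")
  missing <- setdiff(vars, names(predictors))
  if (length(missing))
    stop_snowcross("coefficient names not in predictor table: ",
                   paste(missing, collapse = ", "))
  eta <- rep(coefficients[["intercept"]], nrow(predictors))
  for (v in vars) eta <- eta + coefficients[[v]] * predictors[[v]]
  eta
}

#' Simulate per-point track counts from a known count family
#'
#' Draws integer counts with a log link for the count mean and a logit
#' link for the structural-zero probability, following the stated family.
#' Coefficients apply to the predictor columns exactly as passed (pass a
#' standardized table for directly interpretable effect sizes).
#'
#' @param predictors predictor table ([generate_predictors()] output or
#'   any data.frame containing the named columns).
#' @param truth a [simulation_truth()].
#' @param seed integer seed.
#' @return the predictor table plus a `count` column; generating `truth`
#'   and `seed` attached as attributes.
#' @export
simulate_counts <- function(predictors, truth, seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  n <- nrow(predictors)
  lambda <- exp(.linear_predictor(predictors, truth$count_coefficients))
  with_seed(seed, {
    y <- switch(truth$family,
      poisson = rpois(n, lambda),
      negbin  = rnbinom(n, size = truth$dispersion, mu = lambda),
      zip     = ,
      zinb    = {
        pi0 <- plogis(.linear_predictor(predictors,
                                        truth$zero_coefficients))
        base <- if (truth$family == "zip") rpois(n, lambda)
                else rnbinom(n, size = truth$dispersion, mu = lambda)
        ifelse(rbinom(n, 1, pi0) == 1, 0L, base)
      })
    out <- cbind(predictors, count = as.integer(y))
    attr(out, "truth") <- truth
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

# ---- track simulation ------------------------------------------------------

#' Simulate raw snow-track survey records
#'
#' Tracks arrive as a Poisson process along each route (the highway and
#' `n_transects` 1 km transects) at `intensity_per_km` expected records
#' per km per species group, optionally modulated by a relative intensity
#' profile along the highway axis. Every highway attempt is recorded; its
#' `success` flag (continuing tracks on the far side) is drawn with
#' probability `truth$permeability_truth`. Transect records carry
#' `success = NA`. Surveys start at least 12 h after snowfall.
#'
#' @param config a [landscape_config()].
#' @param truth a [simulation_truth()] with `permeability_truth` set.
#' @param seed integer seed.
#' @param intensity_per_km expected track records per km per group;
#'   scalar or named per `config$species`.
#' @param intensity_profile optional function(km) giving relative
#'   intensity in `[0, 1]` along the highway (used for both route types).
#' @return data.frame of track records: `species`, `route`,
#'   `position_km`, `count`, `success`, `hours_since_snowfall`,
#'   `survey_date`.
#' @export
simulate_tracks <- function(config, truth, seed = 1L,
                            intensity_per_km = 2,
                            intensity_profile = NULL) {
  stopifnot(inherits(config, "landscape_config"),
            inherits(truth, "simulation_truth"))
  if (is.na(truth$permeability_truth))
    stop_snowcross("simulate_tracks needs truth$permeability_truth")
  species <- config$species
  mu <- if (length(intensity_per_km) == 1)
    setNames(rep(intensity_per_km, length(species)), species)
  else intensity_per_km[species]
  routes <- data.frame(
    route = c("highway", paste0("transect-", seq_len(config$n_transects))),
    length_km = c(config$highway_length_km,
                  rep(1, config$n_transects)))
  with_seed(seed, {
    recs <- list()
    for (sp in species) {
      for (i in seq_len(nrow(routes))) {
        rt <- routes$route[i]
        len <- routes$length_km[i]
        n <- rpois(1, mu[[sp]] * len)
        if (n == 0) next
        pos <- runif(n, 0, len)
        if (!is.null(intensity_profile)) {
          km <- if (rt == "highway") pos else
            pmin(pos + config$highway_length_km *
                   (as.integer(sub("transect-", "", rt)) - 0.5) /
                   config$n_transects,
                 config$highway_length_km)
          keep <- runif(n) < pmax(pmin(intensity_profile(km), 1), 0)
          pos <- pos[keep]
          n <- length(pos)
          if (n == 0) next
        }
        hours <- if (rt == "highway") runif(n, 12, 48) else runif(n, 12, 96)
        recs[[length(recs) + 1]] <- data.frame(
          species = sp, route = rt, position_km = pos,
          count = 1L + rpois(n, 0.3),
          success = if (rt == "highway")
            rbinom(n, 1, truth$permeability_truth) == 1 else NA,
          hours_since_snowfall = hours,
          survey_date = as.Date("2007-01-05") +
            sample(0:80, n, replace = TRUE))
      }
    }
    if (!length(recs))
      return(data.frame(species = character(), route = character(),
                        position_km = numeric(), count = integer(),
                        success = logical(),
                        hours_since_snowfall = numeric(),
                        survey_date = as.Date(character())))
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

# ---- plain-text I/O --------------------------------------------------------

#' Write / read a dataset as tab-delimited UTF-8 text
#'
#' `write_dataset()` writes any data.frame with a header row and "."
#' decimal separator; if the object carries a `simulation_truth`
#' attribute it is stored next to the table as `<path>.truth.json`
#' together with the generator seed. `read_dataset()` reads it back.
#'
#' @param x data.frame.
#' @param path output file path.
#' @return `write_dataset()` the path invisibly; `read_dataset()` a
#'   data.frame.
#' @export
write_dataset <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    meta <- list(family = truth$family,
                 count_coefficients = as.list(truth$count_coefficients),
                 zero_coefficients = as.list(truth$zero_coefficients),
                 dispersion = truth$dispersion,
                 permeability_truth = truth$permeability_truth,
                 seed = attr(x, "seed"))
    jsonlite::write_json(meta, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
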