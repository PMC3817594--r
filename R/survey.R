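#' Flag possible repeat crossings within a distance radius
#'
#' Within each species x route combination, records are scanned left to
#' right along the route (sorted by position, then date) and any record
#' closer than `radius_m` to the last *kept* record is flagged as a
#' possible repeat crossing of the same individual rather than an
#' independent attempt. With `radius_m = 0` everything is kept.
#'
#' @param records track-record data.frame (see [simulate_tracks()]): at
#'   least `species`, `route`, `position_km`; `survey_date` used as a
#'   sort tie-break when present.
#' @param radius_m non-negative flagging radius in metres (default 300).
#' @return list with `kept` and `flagged` data.frames; the union is the
#'   input (row order by route position).
#' @export
deduplicate_tracks <- function(records, radius_m = 300) {
  if (radius_m < 0) stop_snowcross("radius_m must be non-negative")
  if (!nrow(records))
    return(list(kept = records, flagged = records[0, ]))
  ord <- if ("survey_date" %in% names(records))
    order(records$species, records$route, records$position_km,
          records$survey_date)
  else order(records$species, records$route, records$position_km)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$species, records$route)
  repeat_flag <- logical(nrow(records))
  for (k in unique(key)) {
    idx <- which(key == k)
    last_kept <- -Inf
    for (i in idx) {
      if ((records$position_km[i] - last_kept) * 1000 < radius_m &&
          is.finite(last_kept)) {
        repeat_flag[i] <- TRUE
      } else {
        last_kept <- records$position_km[i]
      }
    }
  }
  list(kept = records[!repeat_flag, , drop = FALSE],
       flagged = records[repeat_flag, , drop = FALSE])
}

#' Standardize a track count by elapsed 12 h periods
#'
#' Track counts accumulate between snowfalls, so raw counts are divided
#' by the number of 12 h periods elapsed since the last snowfall
#' (`ceiling(hours / 12)`, always >= 1 because surveys start at least
#' 12 h after snowfall).
#'
#' @param count non-negative track count(s).
#' @param hours_since_snowfall hours since last snowfall, >= 12.
#' @return standardized count(s).
#' @export
standardize_effort <- function(count, hours_since_snowfall) {
  if (any(hours_since_snowfall < 12))
    stop_snowcross("hours_since_snowfall < 12 violates the survey protocol")
  count / ceiling(hours_since_snowfall / 12)
}

#' Crossings (or tracks) per kilometre of survey effort
#'
#' @param total_tracks non-negative total number of tracks.
#' @param km_surveyed positive total survey length (km).
#' @return rate per km.
#' @export
crossing_rate <- function(total_tracks, km_surveyed) {
  if (any(km_surveyed <= 0)) stop_snowcross("km_surveyed must be positive")
  total_tracks / km_surveyed
}

#' Highway permeability relative to off-road movement
#'
#' Permeability is the highway crossing rate divided by the transect
#' (off-road) crossing rate: 1 means the highway is no barrier at all, 0
#' an absolute barrier. Undefined (flagged `NA`) when no off-road
#' movement was observed.
#'
#' @param highway_rate highway crossings per km.
#' @param transect_rate transect crossings per km.
#' @param group optional species/group label.
#' @param basis `"all tracks"` or `"successful crossings"`.
#' @return one-row data.frame of class `permeability_result` with
#'   columns `group`, `highway_rate`, `transect_rate`, `permeability`,
#'   `basis`, `defined`.
#' @export
permeability <- function(highway_rate, transect_rate, group = NA_character_,
                         basis = c("all tracks", "successful crossings")) {
  basis <- match.arg(basis)
  defined <- transect_rate > 0
  value <- if (!defined) NA_real_ else highway_rate / transect_rate
  if (isTRUE(highway_rate == 0) && defined) value <- 0
  structure(data.frame(group = group, highway_rate = highway_rate,
                       transect_rate = transect_rate, permeability = value,
                       basis = basis, defined = defined),
            class = c("permeability_result", "data.frame"))
}

#' Assign a species to its modeled group
#'
#' Carnivore species (coyote, fox, wolf, cougar, bobcat, lynx, marten,
#' wolverine) pool into `"carnivores"`; ungulates (deer, elk, moose) are
#' modeled separately; anything already named after a group passes
#' through.
#'
#' @param species character vector of species labels.
#' @return character vector of group labels.
#' @export
species_group <- function(species) {
  carn <- c("coyote", "fox", "wolf", "cougar", "bobcat", "lynx",
            "marten", "wolverine")
  ifelse(tolower(species) %in% carn, "carnivores", tolower(species))
}

#' Permeability table from raw track records
#'
#' Applies the survey pipeline to raw records: per-record 12 h effort
#' standardization, per-group totals on the highway and transects, rates
#' per km, and the permeability ratio, on both bases (all tracks and
#' successful crossings only).
#'
#' @param records track-record data.frame.
#' @param highway_km,transect_km total survey effort (km).
#' @param groups optional group labels to report (default: all present).
#' @param dedup flag repeat crossings first (default `FALSE`; both
#'   choices are defensible, so the caller decides and the basis is
#'   recorded).
#' @return data.frame, one row per group x basis.
#' @export
permeability_table <- function(records, highway_km, transect_km,
                               groups = NULL, dedup = FALSE) {
  if (dedup) records <- deduplicate_tracks(records)$kept
  records$group <- species_group(records$species)
  records$std_count <- standardize_effort(records$count,
                                          records$hours_since_snowfall)
  groups <- groups %||% sort(unique(records$group))
  rows <- lapply(groups, function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    hwy <- sub[sub$route == "highway", , drop = FALSE]
    trn <- sub[sub$route != "highway", , drop = FALSE]
    t_rate <- crossing_rate(sum(trn$std_count), transect_km)
    rbind(
      permeability(crossing_rate(sum(hwy$std_count), highway_km),
                   t_rate, g, "all tracks"),
      permeability(crossing_rate(sum(hwy$std_count[hwy$success %in% TRUE]),
                                 highway_km),
                   t_rate, g, "successful crossings"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Track accumulation curve along a route
#'
#' Cumulative track count versus route kilometre, a monotone step
#' function whose flat stretches reveal highway segments that are rarely
#' or never crossed (candidate barrier segments).
#'
#' @param records records to accumulate (e.g. successful highway
#'   crossings); needs `position_km` and `count`.
#' @param length_km route length; positions must lie in `[0, length_km]`.
#' @param flat_min_km minimum flat stretch length (km) reported as a
#'   candidate barrier segment (default 5).
#' @return data.frame of class `accumulation_curve` with columns `km`
#'   and `cumulative` (step knots at 0, each track position, and
#'   `length_km`); candidate barrier segments attached as attribute
#'   `"flat_segments"` (data.frame `from_km`, `to_km`).
#' @export
accumulation_curve <- function(records, length_km, flat_min_km = 5) {
  if (nrow(records) &&
      (any(records$position_km < 0) || any(records$position_km > length_km)))
    stop_snowcross("positions outside [0, length_km]")
  ord <- order(records$position_km)
  pos <- records$position_km[ord]
  cnt <- if ("count" %in% names(records)) records$count[ord]
         else rep(1L, length(pos))
  km <- c(0, pos, length_km)
  cumulative <- c(0, cumsum(cnt), sum(cnt))
  # flat stretches: gaps between consecutive knots with no accumulation
  gap_from <- c(0, pos)
  gap_to <- c(pos, length_km)
  flat <- data.frame(from_km = gap_from, to_km = gap_to)
  flat <- flat[flat$to_km - flat$from_km >= flat_min_km, , drop = FALSE]
  rownames(flat) <- NULL
  structure(data.frame(km = km, cumulative = cumulative),
            flat_segments = flat,
            class = c("accumulation_curve", "data.frame"))
}

#' Estimate permeability from simulated tracks
#'
#' Convenience estimator for generator-recovery checks: successful
#' highway crossings per km divided by all transect tracks per km, the
#' quantity the track simulator's `permeability_truth` governs.
#'
#' @param records output of [simulate_tracks()].
#' @param config the [landscape_config()] that produced them.
#' @return estimated permeability (scalar).
#' @export
estimate_permeability <- function(records, config) {
  hwy <- records[records$route == "highway", , drop = FALSE]
  trn <- records[records$route != "highway", , drop = FALSE]
  hwy_rate <- crossing_rate(sum(hwy$success %in% TRUE),
                            config$highway_length_km)
  trn_rate <- crossing_rate(nrow(trn), config$n_transects * 1)
  permeability(hwy_rate, trn_rate, basis = "successful crossings")$permeability
}
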