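# perpendicular distance of points to one segment, flat-capped: Inf when
# the projection falls outside the segment
.seg_perp_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  d <- abs((px - x1) * dy - (py - y1) * dx) / sqrt(len2)
  d[t < 0 | t > 1] <- Inf
  d
}

#' Build a square prediction grid along a route corridor
#'
#' Tiles the corridor of width `2 * buffer_m` around a planar polyline
#' with `cell_m`-sized square cells and keeps every cell whose centroid
#' lies inside the corridor (perpendicular distance to some segment at
#' most `buffer_m`, with flat end caps, or within `buffer_m` of an
#' interior vertex to fill the miter gaps at bends). The grid is
#' anchored at the corridor's bounding-box minimum corner, so the
#' construction is deterministic; cells are ordered by (row, column).
#'
#' Coordinates are planar metres in a local frame (no geodesy); the
#' highway corridor uses `buffer_m = 15` and the 1 km approach corridor
#' `buffer_m = 1000` in the reference design, both at 30 m resolution.
#'
#' @param route two-column matrix (x, y in metres) of polyline vertices.
#' @param cell_m cell edge length (m), default 30.
#' @param buffer_m corridor half-width (m), positive.
#' @param corridor label stored on the cells (`"highway"` or
#'   `"approach"`).
#' @return data.frame of class `prediction_grid`: `cell_id`, `row`,
#'   `col`, `x`, `y` (centroids), `cell_m`, `corridor`.
#' @export
build_grid <- function(route, cell_m = 30, buffer_m,
                       corridor = "highway") {
  route <- as.matrix(route)
  if (nrow(route) < 2 ||
      sum(sqrt(diff(route[, 1])^2 + diff(route[, 2])^2)) <= 0)
    stop_snowcross("route polyline must have positive length")
  if (buffer_m <= 0) stop_snowcross("buffer_m must be positive")

  # corridor bounding box from the per-segment buffered rectangles
  xs <- ys <- numeric(0)
  for (i in seq_len(nrow(route) - 1)) {
    dx <- route[i + 1, 1] - route[i, 1]
    dy <- route[i + 1, 2] - route[i, 2]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    nx <- -dy / len * buffer_m
    ny <- dx / len * buffer_m
    xs <- c(xs, route[i:(i + 1), 1] + nx, route[i:(i + 1), 1] - nx)
    ys <- c(ys, route[i:(i + 1), 2] + ny, route[i:(i + 1), 2] - ny)
  }
  x0 <- min(xs); y0 <- min(ys)
  ncol_ <- max(1, ceiling((max(xs) - x0) / cell_m - 1e-9))
  nrow_ <- max(1, ceiling((max(ys) - y0) / cell_m - 1e-9))
  cells <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  cx <- x0 + (cells$col - 0.5) * cell_m
  cy <- y0 + (cells$row - 0.5) * cell_m

  dist <- rep(Inf, length(cx))
  for (i in seq_len(nrow(route) - 1)) {
    if (all(route[i, ] == route[i + 1, ])) next
    dist <- pmin(dist, .seg_perp_dist(cx, cy, route[i, 1], route[i, 2],
                                      route[i + 1, 1], route[i + 1, 2]))
  }
  vert_idx <- if (nrow(route) > 2) 2:(nrow(route) - 1) else integer()
  for (i in vert_idx) {                    # fill miter gaps at bends
    dist <- pmin(dist, sqrt((cx - route[i, 1])^2 + (cy - route[i, 2])^2))
  }
  keep <- dist <= buffer_m + 1e-9
  out <- data.frame(cell_id = seq_len(sum(keep)),
                    row = cells$row[keep], col = cells$col[keep],
                    x = cx[keep], y = cy[keep],
                    cell_m = cell_m, corridor = corridor)
  class(out) <- c("prediction_grid", "data.frame")
  out
}

#' Sample landscape predictors at prediction-grid centroids
#'
#' Evaluates the same latent landscape fields used for survey points at
#' each cell centroid (x-coordinate mapped to highway kilometre), so
#' prediction grids and training data describe one terrain.
#'
#' @param landscape a [simulate_landscape()] object.
#' @param cells a [build_grid()] data.frame.
#' @param seed integer seed for the point-level predictor noise.
#' @return `cells` with the 45 predictor columns appended.
#' @export
cell_predictors <- function(landscape, cells, seed = 1L) {
  km <- pmin(pmax(cells$x / 1000, 0), landscape$config$highway_length_km)
  pred <- with_seed(seed, .sample_predictors(landscape, km))
  cbind(as.data.frame(cells), pred)
}

#' Predict per-cell abundance from an averaged model
#'
#' Standardizes the cell predictors with the *training*
#' standardization parameters and returns the Akaike-weight-averaged
#' predicted mean abundance for each cell.
#'
#' @param averaged an [average_models()] object.
#' @param cells grid cells carrying raw predictor columns.
#' @param standardization `standardization_params` from the training
#'   call to [standardize_predictors()].
#' @return numeric vector of non-negative abundances, one per cell.
#' @export
predict_abundance <- function(averaged, cells, standardization) {
  needed <- unique(unlist(lapply(averaged$members, function(m)
    c(m$model$spec$count_predictors, m$model$spec$zero_predictors))))
  missing <- setdiff(needed, names(cells))
  if (length(missing))
    stop_snowcross("cell predictor column(s) missing: ",
                   paste(missing, collapse = ", "))
  std <- standardize_predictors(as.data.frame(cells),
                                params = standardization)$data
  predict(averaged, std)
}

#' Decile scores of an abundance surface
#'
#' Bins per-cell abundances into empirical deciles, 1 = lowest tenth,
#' 10 = highest. Tied values share the lowest bin containing their
#' common value; with zero-heavy surfaces whole bins can collapse,
#' which is flagged (attribute `"degenerate"`) rather than jittered.
#'
#' @param values numeric abundances (at least 10 cells).
#' @return integer vector of scores in 1..10.
#' @export
decile_scores <- function(values) {
  if (length(values) < 10)
    stop_snowcross("need at least 10 cells for decile scores")
  breaks <- quantile(values, probs = seq(0.1, 0.9, by = 0.1),
                     names = FALSE, type = 7)
  score <- 1L + vapply(values, function(v) sum(breaks < v), integer(1))
  structure(score, degenerate = anyDuplicated(breaks) > 0)
}

#' Community crossing-site preference score
#'
#' Multiplies the per-group decile scores of each cell and standardizes
#' by `10^(g - 1)` so the score always lies in `(0, 10]`: 10 means every
#' group scores the top decile, `10^(1 - g)` (0.001 for four groups)
#' means every group scores the bottom decile. With the reference four
#' groups this is the familiar product-over-1000 score.
#'
#' @param decile_maps named list of equal-length integer decile vectors,
#'   one per group, aligned on the same cell set.
#' @param cell_id optional cell identifiers (defaults to position).
#' @return data.frame `cell_id`, `community_score`.
#' @export
community_score <- function(decile_maps, cell_id = NULL) {
  lens <- vapply(decile_maps, length, integer(1))
  if (length(unique(lens)) != 1)
    stop_snowcross("decile maps have mismatched cell sets")
  g <- length(decile_maps)
  prod <- Reduce(`*`, lapply(decile_maps, as.numeric))
  data.frame(cell_id = cell_id %||% seq_len(lens[1]),
             community_score = prod / 10^(g - 1))
}

#' Classify highway segments by crossing vs approach preference
#'
#' Compares the crossing-model (highway-corridor) and approach-model
#' (1 km-corridor) community scores along the route axis. Positions are
#' binned; a bin is "high" on a map when its score reaches that map's
#' `quantile` threshold (default top quartile). Contiguous runs of the
#' same class merge into segments: `both-high` marks mitigation
#' priorities, `crossing-only-high` the less-ideal case of a preferred
#' crossing without preferred approach habitat.
#'
#' @param km position along the route (km), common axis for both maps.
#' @param crossing_score,approach_score community scores at `km`.
#' @param quantile high-score threshold quantile (default 0.75).
#' @param bin_km aggregation bin width (km), default 1.
#' @return data.frame `from_km`, `to_km`, `class`; attribute
#'   `"degenerate"` flags all-constant score maps.
#' @export
overlap_report <- function(km, crossing_score, approach_score,
                           quantile = 0.75, bin_km = 1) {
  bin <- floor(km / bin_km)
  agg <- function(score) {
    m <- tapply(score, bin, mean)
    m[order(as.numeric(names(m)))]
  }
  cs <- agg(crossing_score)
  as <- agg(approach_score)
  degenerate <- sd(crossing_score) == 0 || sd(approach_score) == 0
  # strict comparison: with tie-heavy scores a >= rule would flag every
  # bin sharing the threshold value as "high"
  hi_c <- cs > stats::quantile(cs, quantile)
  hi_a <- as > stats::quantile(as, quantile)
  cls <- as.vector(ifelse(hi_c & hi_a, "both-high",
                   ifelse(hi_c, "crossing-only-high",
                   ifelse(hi_a, "approach-only-high", "both-low"))))
  b <- as.numeric(names(cs))
  runs <- rle(cls)
  to_i <- cumsum(runs$lengths)
  from_i <- c(1, head(to_i, -1) + 1)
  structure(data.frame(from_km = b[from_i] * bin_km,
                       to_km = (b[to_i] + 1) * bin_km,
                       class = runs$values),
            degenerate = degenerate)
}

#' Write prediction cells as GeoJSON
#'
#' Each cell becomes a square Polygon feature (planar coordinates)
#' whose properties carry every non-geometry column (per-group
#' abundances, decile scores, community score, ...).
#'
#' @param cells prediction-grid data.frame with `x`, `y`, `cell_m`.
#' @param path output path.
#' @export
write_cells_geojson <- function(cells, path) {
  h <- cells$cell_m / 2
  features <- lapply(seq_len(nrow(cells)), function(i) {
    x <- cells$x[i]; y <- cells$y[i]; hh <- h[i]
    props <- as.list(cells[i, setdiff(names(cells),
                                      c("x", "y", "row", "col", "cell_m")),
                           drop = FALSE])
    list(type = "Feature",
         geometry = list(
           type = "Polygon",
           coordinates = list(list(c(x - hh, y - hh), c(x + hh, y - hh),
                                   c(x + hh, y + hh), c(x - hh, y + hh),
                                   c(x - hh, y - hh)))),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
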