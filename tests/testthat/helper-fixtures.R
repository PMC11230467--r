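# Shared builders for geometry fixtures and tiny GeoJSON/CSV inputs.

unit_square <- function() planar_rect(0, 0, 1, 1)

rect_ring <- function(xmin, ymin, xmax, ymax, close = FALSE) {
  xy <- cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
  if (close) xy <- rbind(xy, xy[1, ])
  xy
}

# Random convex polygon: convex hull of n uniform points in a box.
random_convex <- function(n = 8, xmin = 0, ymin = 0, xmax = 2, ymax = 2) {
  pts <- cbind(runif(n, xmin, xmax), runif(n, ymin, ymax))
  planar_geom(pts[chull(pts), , drop = FALSE])
}

geojson_feature <- function(rings, props) {
  close <- function(xy) {
    xy <- rbind(xy, xy[1, ])
    lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
  }
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon",
                       coordinates = lapply(rings, close)))
}

write_feature_collection <- function(features, path = tempfile(fileext = ".geojson")) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# One-square-per-grade toy layers.
toy_graded_geojson <- function(grades = c("A", "B", "C", "D"),
                               path = tempfile(fileext = ".geojson")) {
  feats <- lapply(seq_along(grades), function(i) {
    geojson_feature(list(rect_ring(i - 1, 0, i, 1)),
                    list(region_id = paste0("R", i), holc_grade = grades[i]))
  })
  write_feature_collection(feats, path)
}

toy_zone_geojson <- function(n = 4, path = tempfile(fileext = ".geojson")) {
  feats <- lapply(seq_len(n), function(i) {
    geojson_feature(list(rect_ring(i - 1, 0, i, 1)),
                    list(zone_id = sprintf("Z%02d", i)))
  })
  write_feature_collection(feats, path)
}

toy_population_csv <- function(ids, populations,
                               path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(zone_id = ids, population = populations),
                   path, row.names = FALSE, quote = FALSE)
  path
}

records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
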