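# Readers and writers for the two polygon layers and the tabular inputs.
#
# GeoJSON (RFC 7946) is the only polygon format supported; CSV (header row,
# UTF-8) is used for zone populations and injury records. All geometries are
# emitted in planar coordinates: geographic (lon/lat) layers must be
# reprojected through the configurable equal-area projection, because
# intersection areas are only meaningful in an equal-area plane.

#' Equal-area projection specification
#'
#' Cylindrical equal-area projection (Lambert) used to bring geographic
#' coordinates into a planar equal-area system before any area computation.
#' Synthetic layers are already planar and use `projection = NULL`.
#'
#' @param lon0 central meridian in degrees.
#' @param lat_ts latitude of true scale in degrees.
#' @param radius sphere radius in metres (authalic Earth radius by default).
#' @return a projection specification list.
#' @export
projection_cea <- function(lon0 = 0, lat_ts = 0, radius = 6371007.2) {
  structure(list(type = "cea", lon0 = lon0, lat_ts = lat_ts, radius = radius),
            class = "rs_projection")
}

project_coords <- function(xy, projection) {
  if (is.null(projection)) return(xy)
  stopifnot(inherits(projection, "rs_projection"))
  k <- cos(projection$lat_ts * pi / 180)
  cbind(projection$radius * (xy[, 1] - projection$lon0) * (pi / 180) * k,
        projection$radius * sin(xy[, 2] * pi / 180) / k)
}

read_geojson_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("not parseable as GeoJSON: ", path,
                                           " (", conditionMessage(e), ")"))
  if (!identical(doc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", path)
  doc$features
}

coords_to_matrix <- function(ring) {
  m <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
  m
}

# Convert a GeoJSON Polygon/MultiPolygon geometry into a pgeom, repairing
# self-intersecting rings. Returns NULL for non-polygonal geometries.
geojson_to_pgeom <- function(geom, projection = NULL, label = "feature") {
  if (is.null(geom) || is.null(geom$type)) return(NULL)
  polys <- switch(geom$type,
    Polygon = list(geom$coordinates),
    MultiPolygon = geom$coordinates,
    return(NULL)
  )
  rings <- list(); signs <- integer(0); repaired <- FALSE
  for (poly in polys) {
    for (k in seq_along(poly)) {
      xy <- project_coords(coords_to_matrix(poly[[k]]), projection)
      pieces <- repair_ring(xy)
      if (length(pieces) > 1) repaired <- TRUE
      for (p in pieces) {
        rings[[length(rings) + 1]] <- p
        signs <- c(signs, if (k == 1) 1L else -1L)
      }
    }
  }
  if (!length(rings)) return(NULL)
  if (repaired)
    warning("repaired self-intersecting ring in ", label, call. = FALSE)
  planar_geom(rings, signs)
}

pgeom_to_geojson <- function(g) {
  outer <- Filter(function(r) r$sign > 0, g$rings)
  holes <- Filter(function(r) r$sign < 0, g$rings)
  close_ring <- function(xy) {
    xy <- rbind(xy, xy[1, ])
    lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
  }
  if (length(outer) == 1) {
    list(type = "Polygon",
         coordinates = c(list(close_ring(outer[[1]]$xy)),
                         lapply(holes, function(r) close_ring(r$xy))))
  } else {
    # holes are attached to the first outer that bbox-contains them
    parts <- lapply(outer, function(r) list(close_ring(r$xy)))
    for (h in holes) {
      for (i in seq_along(outer)) {
        b <- outer[[i]]$bbox; hb <- h$bbox
        if (hb[1] >= b[1] && hb[2] >= b[2] && hb[3] <= b[3] && hb[4] <= b[4]) {
          parts[[i]] <- c(parts[[i]], list(close_ring(h$xy)))
          break
        }
      }
    }
    list(type = "MultiPolygon", coordinates = parts)
  }
}

#' Read a graded (HOLC-style) polygon layer
#'
#' Each polygonal feature with a grade in A-D becomes one graded region;
#' features with any other grade (e.g. ungraded commercial areas) are
#' returned in a `rejected` list rather than silently dropped. Invalid
#' (self-intersecting) rings are repaired with a warning.
#'
#' @param path GeoJSON FeatureCollection file.
#' @param grade_property name of the feature property holding the grade
#'   letter (default `"holc_grade"`).
#' @param projection `NULL` for planar input, or a [projection_cea()]
#'   specification for geographic input.
#' @return object of class `graded_layer`: list with `accepted` (list of
#'   regions, each `list(region_id, grade, geom)`) and `rejected` (list of
#'   `list(feature_index, region_id, reason)`).
#' @export
read_graded_layer <- function(path, grade_property = "holc_grade",
                              projection = NULL) {
  feats <- read_geojson_features(path)
  accepted <- list(); rejected <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties
    if (is.null(props) || !grade_property %in% names(props))
      stop("feature ", i, " lacks the grade property '", grade_property, "'")
    rid <- as.character(
      props$region_id %||% props$area_id %||% props$id %||% paste0("feature-", i))
    grade <- toupper(trimws(as.character(props[[grade_property]] %||% "")))
    if (!grade %in% c("A", "B", "C", "D")) {
      rejected[[length(rejected) + 1]] <-
        list(feature_index = i, region_id = rid, reason = "unknown grade")
      next
    }
    g <- geojson_to_pgeom(f$geometry, projection, label = paste0("feature ", i))
    if (is.null(g)) {
      rejected[[length(rejected) + 1]] <-
        list(feature_index = i, region_id = rid, reason = "non-polygonal geometry")
      next
    }
    accepted[[length(accepted) + 1]] <-
      structure(list(region_id = rid, grade = grade, geom = g),
                class = "graded_region")
  }
  structure(list(accepted = accepted, rejected = rejected,
                 n_features = length(feats)),
            class = "graded_layer")
}

#' Write a graded layer back to GeoJSON
#'
#' Inverse of [read_graded_layer()] (in planar coordinates): preserves
#' region ids, grades and areas.
#'
#' @param layer a `graded_layer` or list of graded regions.
#' @param path output file.
#' @export
write_graded_layer <- function(layer, path) {
  regions <- if (inherits(layer, "graded_layer")) layer$accepted else layer
  feats <- lapply(regions, function(r) {
    list(type = "Feature",
         properties = list(region_id = r$region_id, holc_grade = r$grade),
         geometry = pgeom_to_geojson(r$geom))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a zone (zip/ZCTA) polygon layer with populations
#'
#' Zone polygons are joined to a population CSV by exact id string match;
#' zone ids are treated as opaque strings (the ZCTA/zip equivalence is a
#' stated modelling assumption, logged via message).
#'
#' @param path GeoJSON FeatureCollection of zone polygons.
#' @param id_property feature property holding the zone id (default
#'   `"zone_id"`).
#' @param population_table CSV with columns `zone_id,population`.
#' @param projection as in [read_graded_layer()].
#' @return object of class `zone_layer`: list of zones, each
#'   `list(zone_id, geom, population)`.
#' @export
read_zone_layer <- function(path, id_property = "zone_id", population_table,
                            projection = NULL) {
  feats <- read_geojson_features(path)
  pop <- utils::read.csv(population_table, colClasses = c(zone_id = "character"))
  if (!all(c("zone_id", "population") %in% names(pop)))
    stop("population table must have columns zone_id,population")
  if (anyDuplicated(pop$zone_id))
    stop("duplicate zone_id in population table: ",
         paste(unique(pop$zone_id[duplicated(pop$zone_id)]), collapse = ", "))
  if (any(pop$population < 0)) stop("negative population")
  zones <- list(); ids <- character(0)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties
    if (is.null(props) || !id_property %in% names(props))
      stop("feature ", i, " lacks the id property '", id_property, "'")
    zid <- as.character(props[[id_property]])
    g <- geojson_to_pgeom(f$geometry, projection, label = paste0("zone ", zid))
    if (is.null(g)) stop("zone ", zid, " has no polygonal geometry")
    zones[[length(zones) + 1]] <- list(zone_id = zid, geom = g)
    ids <- c(ids, zid)
  }
  if (anyDuplicated(ids))
    stop("duplicate zone_id in zone layer: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  orphan <- setdiff(ids, pop$zone_id)
  if (length(orphan))
    stop("zones without a population row: ", paste(orphan, collapse = ", "))
  for (i in seq_along(zones)) {
    zones[[i]]$population <- pop$population[match(zones[[i]]$zone_id, pop$zone_id)]
  }
  message("zone layer read with ", length(zones),
          " zones; zone ids treated as opaque (ZCTA ~ zip assumption)")
  structure(zones, class = "zone_layer")
}

#' Read injury records from CSV
#'
#' Expected header: `record_id,zone_id,icd10,age_years,sex,race,ethnicity,`
#' `insured,state_resident` (`record_id` and the demographic columns are
#' optional). Unparseable field values are retained as missing and reported
#' in the `parse_issues` attribute with their line numbers, never silently
#' dropped.
#'
#' @param path CSV file.
#' @return data frame of class `injury_records` with one row per input
#'   record and attribute `parse_issues`.
#' @export
read_injury_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  req <- c("zone_id", "icd10")
  if (!all(req %in% names(raw)))
    stop("missing required columns: ",
         paste(setdiff(req, names(raw)), collapse = ", "))
  n <- nrow(raw)
  get_col <- function(nm, default) {
    if (nm %in% names(raw)) raw[[nm]] else rep(default, n)
  }
  issues <- data.frame(line = integer(0), field = character(0),
                       value = character(0))
  age_raw <- get_col("age_years", "")
  age <- suppressWarnings(as.integer(age_raw))
  bad_age <- which(!is.na(age_raw) & age_raw != "" & is.na(age))
  if (length(bad_age)) {
    issues <- rbind(issues, data.frame(line = bad_age + 1L,
                                       field = "age_years",
                                       value = age_raw[bad_age]))
    warning(length(bad_age), " record(s) with unparseable age retained with ",
            "age missing", call. = FALSE)
  }
  neg <- which(!is.na(age) & age < 0)
  if (length(neg)) {
    issues <- rbind(issues, data.frame(line = neg + 1L, field = "age_years",
                                       value = age_raw[neg]))
    age[neg] <- NA_integer_
  }
  parse_enum <- function(x, levels, default = "missing") {
    x <- tolower(trimws(x))
    x[!x %in% levels] <- default
    x
  }
  res <- data.frame(
    record_id = {
      rid <- get_col("record_id", "")
      rid[rid == ""] <- paste0("rec-", which(rid == ""))
      rid
    },
    zone_id = {
      z <- trimws(get_col("zone_id", ""))
      z[z == ""] <- NA_character_
      z
    },
    icd10 = trimws(raw$icd10),
    age_years = age,
    sex = parse_enum(get_col("sex", ""), c("male", "female", "other")),
    race = parse_enum(get_col("race", ""), c("white", "black", "other"),
                      default = "other"),
    ethnicity = parse_enum(get_col("ethnicity", ""),
                           c("hispanic", "non_hispanic", "other"),
                           default = "other"),
    insured = parse_enum(get_col("insured", ""),
                         c("insured", "uninsured")),
    state_resident = {
      sr <- tolower(trimws(get_col("state_resident", "true")))
      sr %in% c("true", "t", "1", "yes")
    },
    stringsAsFactors = FALSE
  )
  if (any(res$icd10 == ""))
    stop("empty icd10 code at line(s): ",
         paste(which(res$icd10 == "") + 1L, collapse = ", "))
  attr(res, "parse_issues") <- issues
  class(res) <- c("injury_records", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
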