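# Synthetic planar city generator: a rectangular zone tessellation, a
# partial graded partition overlapping it, zone populations, and per-zone
# counts drawn from the same NB2 rate model the analysis fits. All geometry
# is axis-aligned rectangles, so intersection areas have closed forms and
# the crosswalk has an exact independent oracle. Output is written as
# GeoJSON/CSV and only ever consumed through the package's public readers.

#' Synthetic city configuration
#'
#' Defaults describe a study-like city: a 6 x 6 grid of 36 zones (the size
#' of the real analysis), populations uniform on 2,000-60,000 persons,
#' graded coverage over ~65% of the city, and counts from
#' `log mu = -8.8 + 0.72 * score + log N` with NB2 dispersion 0.3 — a
#' city-wide injury rate of order 1e-3 with the observed real-data score
#' effect and moderate overdispersion.
#'
#' @param n_zones_x,n_zones_y zone grid dimensions.
#' @param zone_size zone edge length in abstract planar units.
#' @param holc_cover_fraction fraction of city area covered by the graded
#'   sub-rectangle.
#' @param grade_mixing Dirichlet concentration for the city grade mix
#'   (smaller = more polarised cities).
#' @param n_patches number of graded patches (guillotine splits).
#' @param population_range `c(min, max)` persons per zone.
#' @param true_beta0,true_beta1 log-rate intercept and score coefficient.
#' @param true_alpha NB2 dispersion (0 draws Poisson counts).
#' @param covariate_spec named list of `c(min, max)` uniform ranges for
#'   additional per-zone covariates (default a median-age covariate on
#'   25-45 years).
#' @param contamination fraction of extra junk records (non-firearm codes,
#'   missing or foreign zips, non-residents) added by
#'   [generate_records()].
#' @param seed integer; fully determines all output via per-stage
#'   substreams.
#' @return object of class `city_config`.
#' @export
city_config <- function(n_zones_x = 6, n_zones_y = 6, zone_size = 1000,
                        holc_cover_fraction = 0.65, grade_mixing = 1,
                        n_patches = 48,
                        population_range = c(2000, 60000),
                        true_beta0 = -8.8, true_beta1 = 0.72,
                        true_alpha = 0.3,
                        covariate_spec = list(median_age = c(25, 45)),
                        contamination = 0, seed = 1L) {
  stopifnot(n_zones_x >= 1, n_zones_y >= 1, zone_size > 0,
            holc_cover_fraction > 0, holc_cover_fraction <= 1,
            grade_mixing > 0, n_patches >= 1,
            length(population_range) == 2,
            population_range[1] >= 0, diff(population_range) >= 0,
            true_alpha >= 0, contamination >= 0, contamination < 1,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "city_config")
}

# Per-stage substream seeds derived from the single master seed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 101L
}

#' Generate the city's polygon layers and population table
#'
#' Zones are a rectangular tessellation; the graded layer is a randomly
#' placed sub-rectangle of the configured area fraction, recursively split
#' into `n_patches` patches by guillotine cuts, each patch assigned a grade
#' drawn from a Dirichlet city mix. Everything is written to disk as
#' GeoJSON/CSV so the real readers are exercised.
#'
#' @param cfg a [city_config()].
#' @param dir output directory (created if needed).
#' @return list with file paths `holc`, `zones`, `population`, and `dir`.
#' @export
generate_city <- function(cfg, dir = tempfile("city")) {
  stopifnot(inherits(cfg, "city_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- local_seed(stage_seed(cfg$seed, 1L))
  on.exit(restore_seed(old))
  W <- cfg$n_zones_x * cfg$zone_size
  H <- cfg$n_zones_y * cfg$zone_size
  # zones
  zfeat <- list(); pops <- data.frame(zone_id = character(0),
                                      population = integer(0))
  covs <- list()
  for (iy in seq_len(cfg$n_zones_y)) {
    for (ix in seq_len(cfg$n_zones_x)) {
      zid <- sprintf("Z%02d%02d", ix, iy)
      x0 <- (ix - 1) * cfg$zone_size; y0 <- (iy - 1) * cfg$zone_size
      ring <- list(c(x0, y0), c(x0 + cfg$zone_size, y0),
                   c(x0 + cfg$zone_size, y0 + cfg$zone_size),
                   c(x0, y0 + cfg$zone_size), c(x0, y0))
      zfeat[[length(zfeat) + 1]] <- list(
        type = "Feature", properties = list(zone_id = zid),
        geometry = list(type = "Polygon", coordinates = list(ring)))
      pops <- rbind(pops, data.frame(
        zone_id = zid,
        population = as.integer(round(stats::runif(
          1, cfg$population_range[1], cfg$population_range[2])))))
    }
  }
  for (nm in names(cfg$covariate_spec)) {
    rng <- cfg$covariate_spec[[nm]]
    covs[[nm]] <- round(stats::runif(nrow(pops), rng[1], rng[2]), 1)
  }
  for (nm in names(covs)) pops[[nm]] <- covs[[nm]]
  # graded sub-rectangle, same aspect ratio as the city
  s <- sqrt(cfg$holc_cover_fraction)
  gw <- W * s; gh <- H * s
  gx <- stats::runif(1, 0, W - gw); gy <- stats::runif(1, 0, H - gh)
  rects <- list(c(gx, gy, gx + gw, gy + gh))
  while (length(rects) < cfg$n_patches) {
    areas <- vapply(rects, function(r) (r[3] - r[1]) * (r[4] - r[2]), 0)
    i <- which.max(areas)
    r <- rects[[i]]
    frac <- stats::runif(1, 0.3, 0.7)
    if ((r[3] - r[1]) >= (r[4] - r[2])) {
      cut <- r[1] + frac * (r[3] - r[1])
      new <- list(c(r[1], r[2], cut, r[4]), c(cut, r[2], r[3], r[4]))
    } else {
      cut <- r[2] + frac * (r[4] - r[2])
      new <- list(c(r[1], r[2], r[3], cut), c(r[1], cut, r[3], r[4]))
    }
    rects <- c(rects[-i], new)
  }
  mix <- stats::rgamma(4, shape = cfg$grade_mixing)
  mix <- mix / sum(mix)
  grades <- sample(GRADES, length(rects), replace = TRUE, prob = mix)
  gfeat <- lapply(seq_along(rects), function(i) {
    r <- rects[[i]]
    ring <- list(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]),
                 c(r[1], r[4]), c(r[1], r[2]))
    list(type = "Feature",
         properties = list(region_id = sprintf("H%03d", i),
                           holc_grade = grades[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  # sanity: the graded rectangle always overlaps the zone grid by construction
  holc_path <- file.path(dir, "holc.geojson")
  zones_path <- file.path(dir, "zones.geojson")
  pop_path <- file.path(dir, "population.csv")
  jsonlite::write_json(list(type = "FeatureCollection", features = gfeat),
                       holc_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(type = "FeatureCollection", features = zfeat),
                       zones_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(pops, pop_path, row.names = FALSE, quote = FALSE)
  list(holc = holc_path, zones = zones_path, population = pop_path, dir = dir)
}

#' Draw per-zone injury counts from the NB2 rate model
#'
#' `y_z ~ NB2(N_z exp(b0 + b1 S_z), alpha)`; `alpha = 0` draws Poisson.
#' Zones with an undefined score get `NA` counts (they carry no graded
#' signal to draw from).
#'
#' @param scores a `score_table` or data frame with `zone_id` and
#'   `redlining_score`/`score`.
#' @param populations data frame with `zone_id` and `population` (e.g. the
#'   generated population CSV read back), or a `zone_layer`.
#' @param cfg a [city_config()] (supplies `true_beta0`, `true_beta1`,
#'   `true_alpha` and the count substream of `seed`).
#' @return data frame `zone_id, count, population, score`.
#' @export
generate_counts <- function(scores, populations, cfg) {
  stopifnot(inherits(cfg, "city_config"))
  if (inherits(populations, "zone_layer"))
    populations <- data.frame(
      zone_id = vapply(populations, function(z) z$zone_id, ""),
      population = vapply(populations, function(z) as.numeric(z$population), 0))
  s <- if ("redlining_score" %in% names(scores)) scores$redlining_score
       else scores$score
  d <- data.frame(zone_id = scores$zone_id, score = s)
  d$population <- populations$population[match(d$zone_id,
                                               populations$zone_id)]
  old <- local_seed(stage_seed(cfg$seed, 2L))
  on.exit(restore_seed(old))
  mu <- d$population * exp(cfg$true_beta0 + cfg$true_beta1 * d$score)
  if (any(is.finite(mu) & mu > 1e9)) stop("mean overflow in count model")
  n <- nrow(d)
  d$count <- NA_integer_
  ok <- !is.na(mu)
  d$count[ok] <- if (cfg$true_alpha == 0)
    stats::rpois(sum(ok), mu[ok])
  else
    stats::rnbinom(sum(ok), mu = mu[ok], size = 1 / cfg$true_alpha)
  d[, c("zone_id", "count", "population", "score")]
}

#' Default demographic and code-mix profile for record generation
#'
#' Category probabilities follow the published study-population summary
#' (91.5% male, the six age-bin shares, ethnicity/race/insurance mix) and
#' the published per-stem code distribution.
#'
#' @return list of named probability vectors.
#' @export
demographics_profile <- function() {
  list(
    sex = c(male = 965, female = 90) / 1055,
    age_bin = c(`2-14` = 13, `15-24` = 334, `25-34` = 403, `35-49` = 203,
                `50-64` = 91, `65+` = 11) / 1055,
    ethnicity = c(hispanic = 20, non_hispanic = 1000, other = 35) / 1055,
    race = c(white = 91, black = 919, other = 45) / 1055,
    insured = c(insured = 920, uninsured = 135) / 1055,
    icd10 = c(W32 = 168, W33 = 56, W34 = 3, X93 = 737, X94 = 49, X95 = 1,
              Y22 = 39, Y23 = 1, Y24 = 1) / 1055
  )
}

sample_age <- function(n, p_bin) {
  lo <- c(2, 15, 25, 35, 50, 65); hi <- c(14, 24, 34, 49, 64, 90)
  b <- sample(length(p_bin), n, replace = TRUE, prob = p_bin)
  as.integer(round(stats::runif(n, lo[b], hi[b])))
}

#' Generate individual injury records consistent with per-zone counts
#'
#' Emits exactly `count` firearm records per zone with demographics and
#' code stems drawn from `profile`, plus (at `contamination > 0`) a
#' seasoning of junk records — non-firearm codes, missing zips, zips
#' outside the study area, non-residents — that the filter must remove.
#'
#' @param counts data frame `zone_id, count` (e.g. from
#'   [generate_counts()]); `NA` counts contribute no records.
#' @param profile a [demographics_profile()]-shaped list.
#' @param contamination junk fraction (of the clean record count).
#' @param seed integer seed.
#' @return data frame shaped like [read_injury_records()] output.
#' @export
generate_records <- function(counts, profile = demographics_profile(),
                             contamination = 0, seed = 1L) {
  old <- local_seed(stage_seed(seed, 3L))
  on.exit(restore_seed(old))
  n <- sum(counts$count, na.rm = TRUE)
  zone <- rep(counts$zone_id, ifelse(is.na(counts$count), 0L, counts$count))
  draw <- function(p, m) sample(names(p), m, replace = TRUE, prob = p)
  rec <- data.frame(
    record_id = sprintf("rec-%05d", seq_len(n)),
    zone_id = zone,
    icd10 = draw(profile$icd10, n),
    age_years = sample_age(n, profile$age_bin),
    sex = draw(profile$sex, n),
    race = draw(profile$race, n),
    ethnicity = draw(profile$ethnicity, n),
    insured = draw(profile$insured, n),
    state_resident = TRUE,
    stringsAsFactors = FALSE
  )
  n_junk <- round(contamination * n)
  if (n_junk > 0) {
    kind <- sample(c("code", "missing_zip", "foreign_zip", "nonresident"),
                   n_junk, replace = TRUE)
    junk <- data.frame(
      record_id = sprintf("junk-%05d", seq_len(n_junk)),
      zone_id = ifelse(kind == "missing_zip", NA_character_,
                ifelse(kind == "foreign_zip", "99999",
                       sample(counts$zone_id, n_junk, replace = TRUE))),
      icd10 = ifelse(kind == "code",
                     sample(c("S72.0", "T14.9", "V43.5"), n_junk,
                            replace = TRUE),
                     draw(profile$icd10, n_junk)),
      age_years = sample_age(n_junk, profile$age_bin),
      sex = draw(profile$sex, n_junk),
      race = draw(profile$race, n_junk),
      ethnicity = draw(profile$ethnicity, n_junk),
      insured = draw(profile$insured, n_junk),
      state_resident = kind != "nonresident",
      stringsAsFactors = FALSE
    )
    rec <- rbind(rec, junk)
  }
  class(rec) <- c("injury_records", class(rec))
  rec
}

#' Write generated records to CSV (the format the reader consumes)
#' @param records an `injury_records` data frame.
#' @param path output CSV path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
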