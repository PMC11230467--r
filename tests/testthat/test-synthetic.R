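run_city_scores <- function(cfg, dir = tempfile()) {
  paths <- generate_city(cfg, dir)
  graded <- read_graded_layer(paths$holc)
  zones <- suppressMessages(read_zone_layer(paths$zones,
                                            population_table = paths$population))
  cov <- compute_coverage(graded, zones, overlap_diagnostic = FALSE)
  list(paths = paths, zones = zones, cov = cov,
       scores = suppressMessages(compute_scores(cov)))
}

test_that("an all-grade-D city scores 4.0 everywhere through the real pipeline", {
  cfg <- city_config(n_zones_x = 2, n_zones_y = 2, holc_cover_fraction = 1,
                     grade_mixing = 1, n_patches = 8, seed = 21)
  paths <- generate_city(cfg)
  # force every patch to grade D, rewriting through the public format
  doc <- jsonlite::fromJSON(paths$holc, simplifyVector = FALSE)
  for (i in seq_along(doc$features))
    doc$features[[i]]$properties$holc_grade <- "D"
  jsonlite::write_json(doc, paths$holc, auto_unbox = TRUE, digits = NA)
  graded <- read_graded_layer(paths$holc)
  zones <- suppressMessages(read_zone_layer(paths$zones,
                                            population_table = paths$population))
  st <- suppressMessages(compute_scores(compute_coverage(graded, zones)))
  expect_equal(st$redlining_score, rep(4, 4), tolerance = 1e-9)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- city_config(seed = 33)
  p1 <- generate_city(cfg, tempfile())
  p2 <- generate_city(cfg, tempfile())
  for (f in c("holc", "zones", "population"))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("the generated coverage matrix satisfies the crosswalk invariants", {
  out <- run_city_scores(city_config(n_zones_x = 4, n_zones_y = 4, seed = 8))
  cov <- out$cov
  expect_true(all(cov$a >= 0))
  expect_true(all(rowSums(cov$a) <= cov$zone_total_area + 1e-6))
  # the graded patches tile the graded sub-rectangle: total coverage equals
  # its area
  expect_equal(sum(cov$a),
               0.65 * sum(cov$zone_total_area), tolerance = 1e-6)
})

test_that("graded coverage tracks the configured fraction across seeds", {
  fracs <- vapply(1:8, function(s) {
    out <- run_city_scores(city_config(n_zones_x = 3, n_zones_y = 3,
                                       holc_cover_fraction = 0.5,
                                       n_patches = 12, seed = s))
    sum(out$cov$a) / sum(out$cov$zone_total_area)
  }, 0)
  expect_true(all(abs(fracs - 0.5) < 0.05))
})

test_that("counts drawn from the model recover the score coefficient", {
  out <- run_city_scores(city_config(n_zones_x = 6, n_zones_y = 6,
                                     true_beta1 = log(2), seed = 55))
  pops <- read.csv(out$paths$population, colClasses = c(zone_id = "character"))
  cfg <- city_config(n_zones_x = 6, n_zones_y = 6, true_beta1 = log(2),
                     seed = 55)
  counts <- generate_counts(out$scores, pops, cfg)
  f <- suppressMessages(fit_nb(counts, terms = "score"))
  expect_true(f$converged)
  expect_lt(abs(f$coefficients["score"] - log(2)), 3 * f$se["score"])
})

test_that("a zero score effect leaves rate and score uncorrelated", {
  set.seed(77)
  n <- 400
  scores <- data.frame(zone_id = sprintf("z%03d", 1:n),
                       redlining_score = runif(n, 1, 4))
  pops <- data.frame(zone_id = scores$zone_id,
                     population = round(runif(n, 2000, 60000)))
  cfg <- city_config(true_beta1 = 0, true_alpha = 0.3, seed = 77)
  counts <- generate_counts(scores, pops, cfg)
  expect_lt(abs(rate_correlation(counts)$r), 0.2)
})

test_that("Poisson draws have variance ~ mean across replicate zones", {
  cfg <- city_config(true_alpha = 0, true_beta0 = -6, true_beta1 = 0,
                     seed = 9)
  scores <- data.frame(zone_id = sprintf("z%03d", 1:500),
                       redlining_score = rep(2.5, 500))
  pops <- data.frame(zone_id = scores$zone_id, population = rep(40000, 500))
  counts <- generate_counts(scores, pops, cfg)
  ratio <- var(counts$count) / mean(counts$count)
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
})

test_that("record generation conserves counts and contaminates as configured", {
  counts <- data.frame(zone_id = c("A1", "A2"), count = c(30L, 20L))
  clean <- generate_records(counts, seed = 5)
  out <- filter_records(clean, valid_zones = c("A1", "A2"))
  expect_equal(nrow(out$included), 50)
  expect_equal(nrow(out$excluded), 0)

  dirty <- generate_records(counts, contamination = 0.1, seed = 5)
  out <- filter_records(dirty, valid_zones = c("A1", "A2"))
  expect_equal(nrow(out$included) + nrow(out$excluded), nrow(dirty))
  expect_equal(nrow(out$excluded), round(0.1 * 50))
  expect_true(all(out$excluded$reason %in%
                    c("non-firearm code", "missing zip",
                      "zip outside study area", "non-resident")))
})

test_that("generated demographics follow the configured profile at large n", {
  prof <- demographics_profile()
  prof$sex <- c(male = 0.915, female = 0.085)
  recs <- generate_records(data.frame(zone_id = "A1", count = 5000L),
                           profile = prof, seed = 13)
  tabs <- tabulate_injuries(recs, data.frame(zone_id = "A1",
                                             population = 1e5))
  male_pct <- tabs$demographics$pct[tabs$demographics$variable == "gender" &
                                    tabs$demographics$category == "male"]
  expect_lt(abs(male_pct - 91.5), 1.5)
})
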