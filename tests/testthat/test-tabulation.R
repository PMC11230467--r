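mk_records <- function(icd10, zone_id = "21217", resident = TRUE, ...) {
  n <- max(length(icd10), length(zone_id), length(resident))
  data.frame(record_id = paste0("r", seq_len(n)), zone_id = zone_id,
             icd10 = icd10, age_years = 25L, sex = "male", race = "black",
             ethnicity = "non_hispanic", insured = "insured",
             state_resident = resident, stringsAsFactors = FALSE)
}

test_that("intent classification follows the external-cause stem map", {
  expect_equal(classify_intent("X93"), "assault")
  expect_equal(classify_intent("W32"), "accidental")
  expect_equal(classify_intent("Y22"), "undetermined")
  expect_equal(classify_intent("X93.0XXA"), "assault")  # stem matching
  expect_equal(classify_intent(c("X72", "Y35")),
               c("self_harm", "legal_intervention"))
  expect_error(classify_intent("S72"), "S72")
  # methods-list variant swaps X72 for W72 and drops Y24
  mb <- codebook("methods")
  expect_true("W72" %in% mb$include_prefixes)
  expect_false(any(c("X72", "Y24") %in% mb$include_prefixes))
  expect_equal(classify_intent("W72", mb), "self_harm")
})

test_that("filtering applies one primary reason in the documented order", {
  recs <- rbind(
    mk_records("X93", "21217"),                     # included
    mk_records("X93", NA_character_),               # missing zip
    mk_records("S72", "21217"),                     # non-firearm code first
    mk_records("S72", NA_character_),               # code outranks missing zip
    mk_records("X93", "99999"),                     # foreign zip
    mk_records("X93", "21217", resident = FALSE))   # non-resident
  out <- filter_records(recs, valid_zones = "21217")
  expect_equal(nrow(out$included), 1)
  expect_equal(out$excluded$reason,
               c("missing zip", "non-firearm code", "non-firearm code",
                 "zip outside study area", "non-resident"))
  expect_equal(nrow(out$included) + nrow(out$excluded), nrow(recs))
})

test_that("tabulation conserves counts and keeps empty zones", {
  zones <- data.frame(zone_id = c("A1", "A2", "A3"),
                      population = c(100, 200, 300))
  recs <- mk_records(rep("X93", 5), zone_id = c("A1", "A1", "A1", "A2", "A2"))
  tabs <- tabulate_injuries(recs, zones)
  expect_equal(tabs$counts$count, c(3, 2, 0))
  expect_equal(sum(tabs$counts$count), nrow(recs))
  # record referencing an unknown zone violates the filter contract
  expect_error(tabulate_injuries(mk_records("X93", "nowhere"), zones),
               "filter contract")
  # zero records: all-zero counts
  tabs0 <- tabulate_injuries(recs[0, ], zones)
  expect_equal(tabs0$counts$count, c(0, 0, 0))
})

test_that("summary tables mirror the published layout with percentages to 1 dp", {
  set.seed(3)
  recs <- generate_records(data.frame(zone_id = "A1", count = 400L),
                           seed = 3)
  zones <- data.frame(zone_id = "A1", population = 1e4)
  tabs <- tabulate_injuries(recs, zones)
  dem <- tabs$demographics
  expect_setequal(unique(dem$variable),
                  c("gender", "age", "ethnicity", "race", "insurance"))
  for (v in unique(dem$variable)) {
    expect_equal(sum(dem$count[dem$variable == v]), 400)
    expect_lte(abs(sum(dem$pct[dem$variable == v]) - 100), 0.2 + 1e-9)
  }
  expect_equal(sum(tabs$intents$count), 400)
  expect_lte(abs(sum(tabs$intents$pct) - 100), 0.2 + 1e-9)
  # ages below the youngest bin go to a logged 'unbinned' category
  young <- mk_records("X93", "A1"); young$age_years <- 1L
  expect_message(t2 <- tabulate_injuries(young, zones), "unbinned")
  expect_equal(t2$demographics$count[t2$demographics$category == "unbinned"], 1)
})

test_that("chi-square matches the closed-form 2x2 formula", {
  # independence: equal cells
  res <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # closed 2x2 form: n(ad-bc)^2 / (r1 r2 c1 c2)
  tab <- matrix(c(20, 10, 10, 20), 2)
  res <- chi_square(tab)
  n <- sum(tab)
  expected <- n * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  expect_equal(res$statistic, expected, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_gte(res$statistic, 0)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("published intent tabulation reconciles with its totals", {
  t2 <- c(W32 = 168, W33 = 56, W34 = 3, W72 = 0, X73 = 0, X74 = 0,
          X93 = 737, X94 = 49, X95 = 1, Y22 = 39, Y23 = 1, Y24 = 1, Y35 = 0)
  expect_equal(sum(t2), 1055)
  intent <- classify_intent(sub("W72", "X72", names(t2)))
  sums <- tapply(t2, intent, sum)
  expect_equal(unname(sums["accidental"]), 227)
  expect_equal(unname(sums["assault"]), 787)
  expect_equal(unname(sums["undetermined"]), 41)
  expect_equal(unname(sums["self_harm"]), 0)
  expect_equal(unname(sums["legal_intervention"]), 0)
})
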