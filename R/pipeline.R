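# End-to-end pipeline driver: read -> crosswalk -> score -> tabulate ->
# correlate -> fit (univariable models per term, then multivariable) ->
# AIC ranking, with stable CSV/JSON artifacts and a run manifest.

#' Run the full analysis pipeline
#'
#' Three input modes, exactly one of which must be given:
#' * real inputs: `holc`, `zones`, `population` (and optionally `records`)
#'   file paths;
#' * `synthetic`: a [city_config()] — the city, counts and records are
#'   generated, written to disk and read back through the public readers;
#' * `fixture = "table3"`: the packaged 36-zone published dataset (no
#'   geometry stage).
#'
#' Writes `scores.csv`, `counts.csv`, `demographics.csv`, `intents.csv`,
#' `models.json` and `manifest.json` (inputs, seed, per-stage row counts,
#' warnings, output hashes) into `out_dir`. Any stage error aborts with the
#' stage name.
#'
#' @param holc,zones,population,records input file paths (real mode).
#' @param synthetic a [city_config()] (synthetic mode).
#' @param fixture `"table3"` (fixture mode).
#' @param grade_property,id_property GeoJSON property names.
#' @param projection `NULL` or [projection_cea()].
#' @param book a [codebook()].
#' @param terms covariates for the rate models (default `"score"`); each
#'   term is fitted univariably, then all jointly when more than one.
#' @param out_dir output directory.
#' @param seed integer seed (synthetic mode).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(holc = NULL, zones = NULL, population = NULL,
                         records = NULL, synthetic = NULL, fixture = NULL,
                         grade_property = "holc_grade",
                         id_property = "zone_id", projection = NULL,
                         book = codebook(), terms = "score",
                         out_dir = tempfile("run"), seed = 1L) {
  modes <- c(real = !is.null(holc), synthetic = !is.null(synthetic),
             fixture = !is.null(fixture))
  if (sum(modes) != 1)
    stop("exactly one of real inputs, synthetic config, or fixture must ",
         "be given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = names(modes)[modes], seed = seed,
                   package_version = as.character(
                     utils::packageVersion("redscore")),
                   stages = list(), warnings = character(0))
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  warn <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = warn),
             error = function(e)
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }

  if (!is.null(fixture)) {
    stopifnot(identical(fixture, "table3"))
    tbl <- baltimore_table3()
    scores <- data.frame(zone_id = tbl$zone_id,
                         pct_A = tbl$pct_A, pct_B = tbl$pct_B,
                         pct_C = tbl$pct_C, pct_D = tbl$pct_D,
                         redlining_score = tbl$score,
                         graded_fraction = NA_real_, scoreable = TRUE)
    counts <- data.frame(zone_id = tbl$zone_id, count = tbl$count,
                         population = tbl$population, score = tbl$score)
    demographics <- intents <- NULL
    note("fixture", n_zones = nrow(tbl), n_records = sum(tbl$count))
  } else {
    if (!is.null(synthetic)) {
      cfg <- synthetic
      paths <- stage("simulate", generate_city(cfg, file.path(out_dir,
                                                              "inputs")))
      holc <- paths$holc; zones <- paths$zones; population <- paths$population
    }
    graded <- stage("read_graded", read_graded_layer(
      holc, grade_property = grade_property, projection = projection))
    note("read_graded", n_features = graded$n_features,
         n_accepted = length(graded$accepted),
         n_rejected = length(graded$rejected))
    zl <- stage("read_zones", suppressMessages(read_zone_layer(
      zones, id_property = id_property, population_table = population,
      projection = projection)))
    note("read_zones", n_zones = length(zl))
    cov <- stage("crosswalk", compute_coverage(graded, zl))
    scores <- stage("score", suppressMessages(compute_scores(cov)))
    note("score", n_zones = nrow(scores), n_scoreable = sum(scores$scoreable))
    write_coverage_csv(cov, file.path(out_dir, "coverage.csv"))
    note("crosswalk", n_zones = length(cov$zone_ids),
         ungraded_zones = cov$ungraded_zones,
         double_claimed_area = cov$double_claimed_area)

    pop_tbl <- utils::read.csv(population,
                               colClasses = c(zone_id = "character"))
    if (!is.null(synthetic)) {
      counts0 <- stage("simulate_counts",
                       generate_counts(scores, pop_tbl, cfg))
      recs <- stage("simulate_records",
                    generate_records(counts0,
                                     contamination = cfg$contamination,
                                     seed = cfg$seed))
      records <- file.path(out_dir, "inputs", "records.csv")
      write_records_csv(recs, records)
    }
    if (!is.null(records)) {
      recs <- stage("read_records", read_injury_records(records))
      note("read_records", n_records = nrow(recs),
           n_parse_issues = nrow(attr(recs, "parse_issues")))
      flt <- stage("filter", filter_records(
        recs, valid_zones = scores$zone_id[scores$scoreable], book = book))
      note("filter", n_included = nrow(flt$included),
           n_excluded = nrow(flt$excluded),
           exclusion_reasons = as.list(table(flt$excluded$reason)))
      tabs <- stage("tabulate", suppressMessages(
        tabulate_injuries(flt$included, zl, scores, book = book)))
      counts <- tabs$counts
      demographics <- tabs$demographics
      intents <- tabs$intents
      note("tabulate", n_zones = nrow(counts),
           total_count = sum(counts$count))
    } else {
      stop("real-input mode requires a records CSV")
    }
    # attach any extra per-zone covariates carried in the population table
    extra <- setdiff(names(pop_tbl), c("zone_id", "population"))
    for (nm in extra)
      counts[[nm]] <- pop_tbl[[nm]][match(counts$zone_id, pop_tbl$zone_id)]
  }

  corr <- stage("correlate", rate_correlation(counts))
  note("correlate", r = corr$r, p = corr$p, n = corr$n)
  # common analysis set: all candidate models must see identical rows
  ok <- !is.na(counts$count) & counts$population > 0
  for (tm in terms) ok <- ok & !is.na(counts[[tm]])
  fit_data <- counts[ok, , drop = FALSE]
  fits <- list()
  for (tm in terms)
    fits[[tm]] <- stage("fit", suppressMessages(fit_nb(fit_data,
                                                       terms = tm)))
  if (length(terms) > 1)
    fits[[paste(terms, collapse = "+")]] <-
      stage("fit", suppressMessages(fit_nb(fit_data, terms = terms)))
  ranking <- compare_aic(fits)
  note("fit", models = names(fits), best_model = ranking$model[1])

  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(counts, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)
  if (!is.null(demographics))
    utils::write.csv(demographics, file.path(out_dir, "demographics.csv"),
                     row.names = FALSE)
  if (!is.null(intents))
    utils::write.csv(intents, file.path(out_dir, "intents.csv"),
                     row.names = FALSE)
  write_models_json(fits, file.path(out_dir, "models.json"),
                    correlation = corr)
  outs <- list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  outs <- setdiff(outs, file.path(out_dir, "manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(outs))
  names(manifest$outputs) <- basename(outs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
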