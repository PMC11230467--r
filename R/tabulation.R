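# Study-population filtering, ICD-10 external-cause classification, and the
# per-zone count dataset plus demographic / intent summary tables.

#' ICD-10 firearm-injury codebook
#'
#' Three-character external-cause stems and their intent classes. The
#' `"standard"` variant follows the published intent tabulation (W32-W34
#' accidental, X72-X74 self-harm, X93-X95 assault, Y22-Y24 undetermined,
#' Y35 legal intervention). The `"methods"` variant reproduces the study's
#' methods-section list verbatim (which names W72 instead of X72 and omits
#' Y24), kept available because the two lists disagree.
#'
#' @param variant `"standard"` (default) or `"methods"`.
#' @return object of class `codebook`: list with `include_prefixes` and
#'   `intent_map`.
#' @export
codebook <- function(variant = c("standard", "methods")) {
  variant <- match.arg(variant)
  m <- c(W32 = "accidental", W33 = "accidental", W34 = "accidental",
         X72 = "self_harm", X73 = "self_harm", X74 = "self_harm",
         Y22 = "undetermined", Y23 = "undetermined", Y24 = "undetermined",
         X93 = "assault", X94 = "assault", X95 = "assault",
         Y35 = "legal_intervention")
  if (variant == "methods") {
    m <- m[setdiff(names(m), c("X72", "Y24"))]
    m <- c(m, W72 = "self_harm")
  }
  structure(list(include_prefixes = names(m), intent_map = m,
                 variant = variant),
            class = "codebook")
}

icd_stem <- function(icd10) toupper(substr(trimws(icd10), 1, 3))

#' Classify a firearm-injury code by intent
#'
#' Matching is on the 3-character stem, so full codes with extensions
#' (e.g. `"X93.0XXA"`) classify like their stem.
#'
#' @param icd10 character vector of ICD-10 codes.
#' @param book a [codebook()].
#' @return character vector of intents.
#' @export
classify_intent <- function(icd10, book = codebook()) {
  stems <- icd_stem(icd10)
  unknown <- setdiff(unique(stems), book$include_prefixes)
  if (length(unknown))
    stop("code(s) outside the firearm codebook: ",
         paste(unknown, collapse = ", "))
  unname(book$intent_map[stems])
}

#' Filter raw records to the study population
#'
#' A record is included iff its code stem is in the codebook AND it has a
#' zone id AND the zone id is one of the study zones AND the patient is a
#' state resident. Each excluded record carries exactly one primary reason,
#' assigned in the order: non-firearm code, missing zip, zip outside study
#' area, non-resident. Filtering never raises.
#'
#' @param records an `injury_records` data frame ([read_injury_records()]).
#' @param valid_zones character vector of study zone ids.
#' @param book a [codebook()].
#' @return list with `included` (data frame) and `excluded` (data frame
#'   with an extra `reason` column).
#' @export
filter_records <- function(records, valid_zones, book = codebook()) {
  stems <- icd_stem(records$icd10)
  reason <- rep(NA_character_, nrow(records))
  reason[!stems %in% book$include_prefixes] <- "non-firearm code"
  miss <- is.na(reason) & is.na(records$zone_id)
  reason[miss] <- "missing zip"
  foreign <- is.na(reason) & !records$zone_id %in% valid_zones
  reason[foreign] <- "zip outside study area"
  nonres <- is.na(reason) & !records$state_resident
  reason[nonres] <- "non-resident"
  included <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  rownames(included) <- rownames(excluded) <- NULL
  list(included = included, excluded = excluded)
}

AGE_BINS <- c("2-14", "15-24", "25-34", "35-49", "50-64", "65+")

age_bin <- function(age) {
  cut(age, breaks = c(2, 15, 25, 35, 50, 65, Inf), labels = AGE_BINS,
      right = FALSE)
}

one_way <- function(variable, values, levels) {
  values <- factor(values, levels = levels)
  cnt <- table(values, useNA = "no")
  data.frame(variable = variable, category = names(cnt),
             count = as.integer(cnt),
             pct = round(100 * as.integer(cnt) / sum(cnt), 1),
             row.names = NULL)
}

#' Per-zone counts and summary tables
#'
#' Aggregates included records to the per-zone count dataset used by the
#' rate models (zones with no record get a zero count, not dropped) and
#' produces the demographic and intent summary tables with percentages to
#' one decimal. Ages below 2 (outside the youngest bin) go to a logged
#' `unbinned` category.
#'
#' @param included records that passed [filter_records()].
#' @param zones a `zone_layer`, or a data frame with columns `zone_id` and
#'   `population`.
#' @param scores a `score_table` (or data frame with `zone_id` and either
#'   `redlining_score` or `score`); optional, `NA` scores if omitted.
#' @param book the [codebook()] used for intent classification.
#' @return list with `counts` (data frame `zone_id, count, population,`
#'   `score`), `demographics`, `intents`.
#' @export
tabulate_injuries <- function(included, zones, scores = NULL,
                              book = codebook()) {
  if (inherits(zones, "zone_layer")) {
    zones <- data.frame(
      zone_id = vapply(zones, function(z) z$zone_id, ""),
      population = vapply(zones, function(z) as.numeric(z$population), 0))
  }
  bad <- setdiff(included$zone_id, zones$zone_id)
  if (length(bad))
    stop("included record(s) reference unknown zone(s): ",
         paste(bad, collapse = ", "), " (filter contract violated)")
  counts <- data.frame(zone_id = zones$zone_id,
                       count = as.integer(
                         table(factor(included$zone_id,
                                      levels = zones$zone_id))),
                       population = zones$population)
  if (!is.null(scores)) {
    sc <- if ("redlining_score" %in% names(scores)) scores$redlining_score
          else scores$score
    counts$score <- sc[match(counts$zone_id, scores$zone_id)]
  } else {
    counts$score <- NA_real_
  }
  # demographic summary (study-table layout)
  bins <- age_bin(included$age_years)
  unbinned <- sum(is.na(bins) & !is.na(included$age_years))
  if (unbinned > 0)
    message(unbinned, " record(s) with age outside the binned range ",
            "(counted as 'unbinned')")
  age_levels <- if (unbinned > 0) c(AGE_BINS, "unbinned") else AGE_BINS
  age_values <- as.character(bins)
  age_values[is.na(bins) & !is.na(included$age_years)] <- "unbinned"
  demographics <- rbind(
    one_way("gender", included$sex, c("male", "female")),
    one_way("age", age_values, age_levels),
    one_way("ethnicity", included$ethnicity,
            c("hispanic", "non_hispanic", "other")),
    one_way("race", included$race, c("white", "black", "other")),
    one_way("insurance", included$insured, c("insured", "uninsured")))
  # intent summary per code stem
  stems <- factor(icd_stem(included$icd10), levels = book$include_prefixes)
  cnt <- table(stems)
  intents <- data.frame(stem = names(cnt),
                        intent = unname(book$intent_map[names(cnt)]),
                        count = as.integer(cnt),
                        pct = round(100 * as.integer(cnt) /
                                      max(1L, length(stems)), 1),
                        row.names = NULL)
  list(counts = counts, demographics = demographics, intents = intents)
}

#' The published per-stem injury tabulation
#'
#' Counts of the 1055 study encounters by ICD-10 external-cause stem, as
#' printed in the source study's code-summary table (which lists the
#' self-harm handgun stem as W72; it has zero count either way).
#'
#' @return data frame with columns `stem`, `intent`, `count`.
#' @export
baltimore_table2 <- function() {
  data.frame(
    stem = c("W32", "W33", "W34", "W72", "X73", "X74", "X93", "X94",
             "X95", "Y22", "Y23", "Y24", "Y35"),
    intent = c(rep("accidental", 3), rep("self_harm", 3),
               rep("assault", 3), rep("undetermined", 3),
               "legal_intervention"),
    count = c(168L, 56L, 3L, 0L, 0L, 0L, 737L, 49L, 1L, 39L, 1L, 1L, 0L))
}

#' Pearson chi-square test on a two-way count table
#'
#' Plain Pearson chi-square (no continuity correction), as used for the
#' demographic comparisons.
#'
#' @param tab two-way table or matrix of counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected cell count not positive")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
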