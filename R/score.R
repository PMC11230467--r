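# Redlining exposure score: converts the zone x grade coverage matrix into
# per-zone grade percentages and the area-weighted mean grade on the 1-4
# scale (A = 1 "Best" ... D = 4 "Hazardous").

#' Scoring configuration
#'
#' @param grade_weights named numeric vector mapping grades to the linear
#'   scale; the defaults `A=1, B=2, C=3, D=4` put the most severely graded
#'   ("redlined") areas at the top of the scale. Weights must be strictly
#'   increasing in grade severity.
#' @param min_graded_fraction zones whose graded share of total area falls
#'   below this threshold are flagged as unscoreable (default 0: any graded
#'   overlap is scored).
#' @return object of class `score_config`.
#' @export
score_config <- function(grade_weights = c(A = 1, B = 2, C = 3, D = 4),
                         min_graded_fraction = 0) {
  stopifnot(identical(names(grade_weights), GRADES),
            all(diff(grade_weights) > 0),
            min_graded_fraction >= 0, min_graded_fraction <= 1)
  structure(list(grade_weights = grade_weights,
                 min_graded_fraction = min_graded_fraction),
            class = "score_config")
}

#' Redlining score from grade percentages
#'
#' `S = sum(w_g * p_g) / sum(p_g)` — the weighted mean grade over the graded
#' coverage only. The percentages need not sum to exactly 100 (printed
#' tables carry rounding).
#'
#' @param p numeric vector of four grade percentages (A, B, C, D order), or
#'   a matrix with four columns.
#' @param weights grade weights as in [score_config()].
#' @return numeric score(s) in `[min(weights), max(weights)]`; `NA` where
#'   all percentages are zero.
#' @export
score_from_percentages <- function(p, weights = c(A = 1, B = 2, C = 3, D = 4)) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  stopifnot(ncol(p) == 4, all(p >= 0 | is.na(p)))
  tot <- rowSums(p)
  s <- as.vector(p %*% weights) / tot
  s[tot == 0] <- NA_real_
  s
}

#' Compute per-zone grade percentages and redlining scores
#'
#' Percentages are normalised by the graded-only area of each zone (not the
#' total zone area): the historical maps cover only part of the modern city,
#' and the per-zone grade shares are shares *of what was graded*. Zones with
#' no graded overlap are emitted with an undefined score and flagged for
#' exclusion from downstream regression.
#'
#' @param cov a `coverage_matrix` from [compute_coverage()].
#' @param cfg a [score_config()].
#' @return data frame of class `score_table` with columns `zone_id`,
#'   `pct_A` .. `pct_D`, `redlining_score`, `graded_fraction`, `scoreable`.
#' @export
compute_scores <- function(cov, cfg = score_config()) {
  stopifnot(inherits(cov, "coverage_matrix"))
  if (any(cov$a < 0)) stop("negative intersection areas")
  tot <- rowSums(cov$a)
  pct <- 100 * cov$a / ifelse(tot > 0, tot, NA_real_)
  pct[tot == 0, ] <- NA_real_
  s <- as.vector(cov$a %*% cfg$grade_weights) / tot
  s[tot == 0] <- NA_real_
  graded_fraction <- tot / cov$zone_total_area
  scoreable <- tot > 0 & graded_fraction >= cfg$min_graded_fraction
  if (any(!scoreable))
    message("zones excluded from scoring (no/insufficient graded overlap): ",
            paste(cov$zone_ids[!scoreable], collapse = ", "))
  out <- data.frame(zone_id = cov$zone_ids,
                    pct_A = pct[, "A"], pct_B = pct[, "B"],
                    pct_C = pct[, "C"], pct_D = pct[, "D"],
                    redlining_score = s,
                    graded_fraction = unname(graded_fraction),
                    scoreable = scoreable,
                    row.names = NULL)
  class(out) <- c("score_table", class(out))
  out
}

#' Write a score table to CSV
#' @param scores a `score_table`.
#' @param path output CSV path.
#' @export
write_score_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}

#' The published 36-zone Baltimore dataset
#'
#' Per-zip firearm-injury counts, populations, grade-coverage percentages
#' and redlining scores for the 36 Baltimore zip codes, as printed in the
#' source study's descriptive table. Two score columns are provided:
#' `score_printed` is the table's 1-decimal score, and `score` is the
#' full-precision recomputation from the grade percentages, which is what
#' the regression analysis uses.
#'
#' One row (zip 21214) is internally inconsistent as printed: its grade
#' shares imply a score of 3.0 while the printed score is 2.0. For the
#' analysis `score`, the printed score is kept for such rows (the grade
#' shares are treated as the misprint) and the row is flagged via
#' `score_consistent = FALSE`; the printed range of scores (1.64-4) and the
#' published rate-ratio both support this reading.
#'
#' @return data frame with columns `zone_id`, `count`, `population`,
#'   `injury_pct`, `pct_A` .. `pct_D`, `score_printed`, `score`,
#'   `score_consistent`.
#' @export
baltimore_table3 <- function() {
  path <- system.file("extdata", "baltimore_table3.csv", package = "redscore")
  tbl <- utils::read.csv(path, colClasses = c(zone_id = "character"))
  recomputed <- score_from_percentages(
    as.matrix(tbl[, c("pct_A", "pct_B", "pct_C", "pct_D")]))
  consistent <- round(recomputed, 1) == tbl$score_printed
  tbl$score <- ifelse(consistent, recomputed, tbl$score_printed)
  tbl$score_consistent <- consistent
  tbl
}
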