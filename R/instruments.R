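#' Convert food-frequency questionnaire records to grams per day
#'
#' FFQ interviews record, for each food, how often it is eaten (per day,
#' week or month) and the portion in grams per occasion.  This converts a
#' record to an average daily intake: daily frequencies multiply directly,
#' weekly divide by 7, and monthly divide by the month length (30 days by
#' convention, configurable).
#'
#' @param frequency_unit Character vector, each `"daily"`, `"weekly"` or
#'   `"monthly"`.
#' @param times Consumption count per unit period (>= 0).
#' @param portion_g Grams per eating occasion (> 0).
#' @param month_days Days per month used for monthly records; default 30.
#' @return Numeric vector of grams per day.
#' @examples
#' ffq_to_daily_grams("daily", 2, 50)    # 100 g/day
#' ffq_to_daily_grams("weekly", 7, 70)   # 70 g/day
#' ffq_to_daily_grams("monthly", 30, 30) # 30 g/day
#' @export
ffq_to_daily_grams <- function(frequency_unit, times, portion_g,
                               month_days = 30) {
  known <- c(daily = 1, weekly = 7, monthly = month_days)
  bad <- setdiff(unique(frequency_unit), names(known))
  if (length(bad)) {
    stop_mhonet("unknown frequency unit(s): ", paste(bad, collapse = ", "))
  }
  if (any(times < 0)) stop_mhonet("`times` must be >= 0")
  if (any(portion_g <= 0)) stop_mhonet("`portion_g` must be > 0")
  times * portion_g / known[frequency_unit]
}

#' Total daily energy and nutrient intake from daily gram amounts
#'
#' Sums each nutrient across foods: every food contributes
#' `grams_per_day / 100` times its per-100 g nutrient density, and the
#' per-food contributions are added.  Energy (kcal) is treated exactly like
#' any other column of the composition table.
#'
#' @param daily_grams Either a named numeric vector (names are food ids,
#'   values grams/day) or a data frame with columns `food_id` and
#'   `grams_per_day`.
#' @param composition A food-composition data frame with a `food_id` column
#'   and one numeric column per nutrient, densities per 100 g of food.
#' @return Named numeric vector of daily totals, one entry per nutrient
#'   column of `composition` (all zero for an empty intake).
#' @examples
#' comp <- data.frame(food_id = c("a", "b"), protein_g = c(2, 10))
#' nutrient_totals(c(a = 150, b = 50), comp)  # 8 g protein/day
#' @export
nutrient_totals <- function(daily_grams, composition) {
  if (!"food_id" %in% names(composition)) {
    stop_mhonet("`composition` needs a `food_id` column")
  }
  nutrients <- setdiff(names(composition), "food_id")
  dens <- as.matrix(composition[, nutrients, drop = FALSE])
  if (any(dens < 0)) stop_mhonet("nutrient densities must be >= 0")
  rownames(dens) <- composition$food_id

  if (is.data.frame(daily_grams)) {
    grams <- stats::setNames(daily_grams$grams_per_day, daily_grams$food_id)
    grams <- tapply(grams, names(grams), sum)  # merge repeated foods
  } else {
    grams <- daily_grams
  }
  if (length(grams) == 0) {
    return(stats::setNames(numeric(length(nutrients)), nutrients))
  }
  if (is.null(names(grams))) {
    stop_mhonet("`daily_grams` must be named by food id")
  }
  if (any(grams < 0)) stop_mhonet("daily gram amounts must be >= 0")
  missing_ids <- setdiff(names(grams), rownames(dens))
  if (length(missing_ids)) {
    stop_mhonet("food id(s) absent from composition table: ",
                paste(missing_ids, collapse = ", "))
  }
  totals <- drop(crossprod(dens[names(grams), , drop = FALSE], grams / 100))
  stats::setNames(as.numeric(totals), nutrients)
}

#' Standard DASS-21 item-to-subscale allocation
#'
#' The 21 items split into three 7-item subscales.  This is the standard
#' published allocation; [score_dass()] takes the mapping as an argument so
#' a different allocation can be supplied.
#'
#' @return Named list with integer item indices for `depression`, `anxiety`
#'   and `stress`.
#' @export
dass21_mapping <- function() {
  list(depression = c(3L, 5L, 10L, 13L, 16L, 17L, 21L),
       anxiety    = c(2L, 4L, 7L, 9L, 15L, 19L, 20L),
       stress     = c(1L, 6L, 8L, 11L, 12L, 14L, 18L))
}

check_dass_mapping <- function(mapping) {
  if (!setequal(names(mapping), c("depression", "anxiety", "stress"))) {
    stop_mhonet("mapping must name depression, anxiety and stress subscales")
  }
  idx <- sort(unlist(mapping, use.names = FALSE))
  if (any(lengths(mapping) != 7L) || !identical(as.integer(idx), 1:21)) {
    stop_mhonet("mapping must partition items 1..21 into three sets of 7")
  }
  invisible(mapping)
}

#' Score DASS-21 responses into depression, anxiety and stress subscales
#'
#' Each of the 21 items is answered on a 0-3 scale; a subscale score is the
#' plain sum of its 7 items, so every subscale ranges 0-21.  Raw sums are
#' not doubled to the 42-item scale.
#'
#' @param items An n x 21 matrix/data frame of integer responses in 0-3, or
#'   a single length-21 vector.
#' @param mapping Item allocation, as from [dass21_mapping()].
#' @return Data frame with integer columns `depression`, `anxiety`,
#'   `stress` (one row per respondent).
#' @examples
#' score_dass(rep(3, 21))  # 21, 21, 21
#' @export
score_dass <- function(items, mapping = dass21_mapping()) {
  check_dass_mapping(mapping)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 21L) stop_mhonet("expected 21 item columns")
  if (nrow(items) > 0 &&
      (anyNA(items) || any(items != round(items)) ||
       any(items < 0) || any(items > 3))) {
    stop_mhonet("item responses must be integers in 0..3")
  }
  out <- lapply(mapping, function(ix) {
    as.integer(rowSums(items[, ix, drop = FALSE]))
  })
  data.frame(depression = out$depression, anxiety = out$anxiety,
             stress = out$stress)
}

#' Optional DASS severity labelling
#'
#' Severity categories need published cutoffs that vary by convention, so
#' this layer is off unless explicit breaks are supplied.
#'
#' @param score Numeric subscale scores.
#' @param breaks Increasing numeric cutpoints (lower bounds of the bands
#'   above the first), e.g. `c(5, 7, 10, 14)` yields five bands.
#' @param labels Character labels, one more than `length(breaks)`.
#' @return Factor of severity labels.
#' @export
dass_severity <- function(score, breaks, labels) {
  if (missing(breaks) || missing(labels)) {
    stop_mhonet("severity labelling requires explicit `breaks` and `labels`")
  }
  cut(score, breaks = c(-Inf, breaks, Inf), labels = labels, right = FALSE)
}

#' Classify IPAQ physical-activity scores
#'
#' Scores at or above 3 are `active`, scores in `[2, 3)` are `low_active`,
#' and scores below 2 are `sedentary`; the three bands partition the
#' non-negative axis with no gaps or overlaps.
#'
#' @param score Non-negative numeric activity scores.
#' @return Factor with levels `sedentary`, `low_active`, `active`.
#' @examples
#' classify_ipaq(c(3, 2.5, 1.9))
#' @export
classify_ipaq <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop_mhonet("IPAQ scores must be >= 0")
  cut(score, breaks = c(0, 2, 3, Inf), right = FALSE,
      labels = c("sedentary", "low_active", "active"),
      include.lowest = TRUE)
}
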