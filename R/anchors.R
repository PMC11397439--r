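# Default marginal anchors for an overweight/obese young-adult cohort:
# per-variable family, median/SD/min/max in natural units, measurement block,
# and the latent group-effect shift (in SD units) applied to the MUO
# subpopulation.  Families: right-skewed positive quantities (biomarkers,
# nutrient intakes) are lognormal; bounded physiological measurements are
# truncated normal; questionnaire subscale totals are discrete ordinal.
# Effect directions follow the usual MUO contrasts: cardiometabolic risk
# markers and a subset of intakes shift up, HDL/fiber/MUFA shift down.

anchor_row <- function(name, family, median, sd, min, max, block, unit,
                       effect = 0) {
  data.frame(name = name, family = family, median = median, sd = sd,
             min = min, max = max, block = block, unit = unit,
             group_effect = effect, stringsAsFactors = FALSE)
}

#' Reference marginal anchors for the default synthetic cohort
#'
#' One row per simulated variable: distribution family (`lognormal`,
#' `truncated-normal` or `discrete-ordinal`), the anchored median, SD and
#' observed range in natural units, the measurement block, and the latent
#' group-effect shift (SD units) applied to metabolically unhealthy
#' participants.  BMI and HOMA-IR are derived downstream, not simulated.
#'
#' @return Data frame with columns `name`, `family`, `median`, `sd`,
#'   `min`, `max`, `block`, `unit`, `group_effect`.
#' @export
cohort_anchors <- function() {
  rows <- list(
    anchor_row("age", "truncated-normal", 21, 2.51, 18, 28,
               "demographic", "years"),
    anchor_row("weight", "truncated-normal", 74.80, 11.14, 52.5, 113.5,
               "anthropometric", "kg", 0.4),
    anchor_row("height", "truncated-normal", 1.63, 0.09, 1.41, 1.88,
               "anthropometric", "m"),
    anchor_row("waist", "truncated-normal", 90, 7.53, 76, 112,
               "cardiometabolic", "cm", 0.6),
    anchor_row("sbp", "truncated-normal", 120, 8.54, 90, 139,
               "cardiometabolic", "mmHg", 0.7),
    anchor_row("dbp", "truncated-normal", 80, 6.45, 60, 100,
               "cardiometabolic", "mmHg", 0.5),
    anchor_row("glucose", "lognormal", 95.86, 10.77, 75.31, 130.10,
               "cardiometabolic", "mg/dL", 0.7),
    anchor_row("insulin", "lognormal", 10.41, 2.76, 2.4, 22.62,
               "cardiometabolic", "uIU/mL", 0.6),
    anchor_row("cholesterol", "lognormal", 195.73, 55.41, 93.87, 456.24,
               "cardiometabolic", "mg/dL", 1.0),
    anchor_row("triglycerides", "lognormal", 157.24, 50.72, 52, 385.44,
               "cardiometabolic", "mg/dL", 1.2),
    anchor_row("hdl", "truncated-normal", 44.25, 3.10, 40, 53.19,
               "cardiometabolic", "mg/dL", -0.8),
    anchor_row("kcal", "lognormal", 2249.94, 239.80, 1687, 2956.57,
               "intake", "kcal/day"),
    anchor_row("dietary_cholesterol", "lognormal", 355.99, 101.63, 139.62,
               733.81, "intake", "mg/day", 0.3),
    anchor_row("fiber", "lognormal", 21.24, 6.25, 7.58, 35.36,
               "intake", "g/day", -0.3),
    anchor_row("protein", "lognormal", 72.41, 19.48, 25, 139.20,
               "intake", "g/day", 0.2),
    anchor_row("carbohydrate", "lognormal", 297.75, 49.29, 165.51, 448.40,
               "intake", "g/day"),
    anchor_row("fat", "lognormal", 87.05, 12.53, 60.07, 131.64,
               "intake", "g/day"),
    anchor_row("mufa", "lognormal", 40.99, 12.01, 9.46, 78.38,
               "intake", "g/day", -0.25),
    anchor_row("pufa", "lognormal", 8.80, 4.12, 1.01, 49.69,
               "intake", "g/day"),
    anchor_row("sfa", "lognormal", 29.75, 9.57, 12.85, 54.61,
               "intake", "g/day", 0.15),
    anchor_row("water", "truncated-normal", 1493.89, 262.60, 857.88,
               1994.96, "intake", "mL/day"),
    anchor_row("vitamin_a", "lognormal", 633.29, 367.14, 222.56, 3961.87,
               "intake", "ug/day"),
    anchor_row("vitamin_d", "lognormal", 2.15, 0.73, 0.01, 529.50,
               "intake", "ug/day"),
    anchor_row("vitamin_e", "lognormal", 9.84, 0.80, 2.06, 53.33,
               "intake", "mg/day"),
    anchor_row("thiamine", "lognormal", 1.19, 0.90, 0.45, 6.01,
               "intake", "mg/day", 0.3),
    anchor_row("riboflavin", "lognormal", 1.87, 8.02, 0.64, 8.02,
               "intake", "mg/day"),
    anchor_row("niacin", "lognormal", 18.27, 94.89, 5.88, 39.61,
               "intake", "mg/day", 0.3),
    anchor_row("pantothenic_acid", "lognormal", 3.95, 34.85, 1.31, 9.51,
               "intake", "mg/day", 0.3),
    anchor_row("pyridoxine", "lognormal", 1.58, 5.98, 0.71, 8.41,
               "intake", "mg/day", 0.3),
    anchor_row("biotin", "lognormal", 3.57, 6.74, 0.05, 9.69,
               "intake", "ug/day"),
    anchor_row("folic_acid", "lognormal", 302.54, 1.69, 78.69, 670.29,
               "intake", "ug/day"),
    anchor_row("cobalamin", "lognormal", 13.08, 1.67, 1.73, 42.05,
               "intake", "ug/day"),
    anchor_row("vitamin_c", "lognormal", 151.04, 98.94, 12.45, 403.44,
               "intake", "mg/day"),
    anchor_row("sodium", "lognormal", 7099.66, 2332.11, 861.56, 14663.46,
               "intake", "mg/day", 0.4),
    anchor_row("potassium", "lognormal", 3362.47, 1132.61, 1285.65,
               8695.05, "intake", "mg/day"),
    anchor_row("calcium", "lognormal", 1234.77, 359.12, 550.51, 3872.18,
               "intake", "mg/day"),
    anchor_row("phosphorus", "lognormal", 1451.23, 376.28, 546.80,
               2918.23, "intake", "mg/day"),
    anchor_row("magnesium", "lognormal", 384.68, 119.86, 168.47, 1115.64,
               "intake", "mg/day"),
    anchor_row("iron", "lognormal", 15.40, 6.54, 4.45, 103.20,
               "intake", "mg/day"),
    anchor_row("zinc", "lognormal", 9.46, 3.09, 2.62, 20.17,
               "intake", "mg/day"),
    anchor_row("iodine", "lognormal", 144.19, 1093.68, 32.72, 16698,
               "intake", "ug/day", 0.3),
    anchor_row("copper", "lognormal", 1.02, 0.40, 0.18, 2.74,
               "intake", "mg/day", 0.3),
    anchor_row("chlorine", "lognormal", 1810.66, 1835.37, 408.88, 9127.22,
               "intake", "mg/day"),
    anchor_row("manganese", "lognormal", 2.76, 1.68, 0.33, 6.96,
               "intake", "mg/day", 0.3),
    anchor_row("selenium", "lognormal", 55.78, 517.56, 29.90, 5666,
               "intake", "ug/day"),
    anchor_row("depression", "discrete-ordinal", 5, 1.27, 5, 11,
               "psychological", "score"),
    anchor_row("stress", "discrete-ordinal", 11, 2.87, 8, 17,
               "psychological", "score"),
    anchor_row("anxiety", "discrete-ordinal", 5, 1.63, 4, 9,
               "psychological", "score")
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generic marginal anchors for benchmark cohorts
#'
#' A plain set of `p` identically specified variables, used for recovery
#' benchmarks where the variable identities do not matter.
#'
#' @param p Number of variables.
#' @param family Marginal family, default `"lognormal"`.
#' @param median,sd,min,max Anchor values shared by all variables.
#' @return Marginal data frame compatible with [cohort_spec()].
#' @export
generic_marginals <- function(p, family = "lognormal", median = 10, sd = 5,
                              min = 0.1, max = 1000) {
  do.call(rbind, lapply(seq_len(p), function(i) {
    anchor_row(sprintf("v%02d", i), family, median, sd, min, max,
               "generic", "unit")
  }))
}
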