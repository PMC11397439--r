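#' Body-mass index and WHO weight category
#'
#' BMI is weight (kg) divided by height (m) squared.  WHO cutoffs are
#' applied with inclusive lower bounds: below 25 is `normal`, 25 to below 30
#' is `overweight`, and 30 or more is `obese`.
#'
#' @param weight Weight in kilograms (> 0), vectorized.
#' @param height Height in metres (> 0), vectorized.
#' @return Data frame with numeric `bmi` and factor `category`
#'   (`normal`/`overweight`/`obese`).
#' @examples
#' compute_bmi(74.80, 1.63)
#' compute_bmi(c(25, 30), c(1, 1))$category  # both boundaries inclusive
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop_mhonet("weight and height must be positive")
  }
  bmi <- weight / height^2
  category <- cut(bmi, breaks = c(-Inf, 25, 30, Inf), right = FALSE,
                  labels = c("normal", "overweight", "obese"))
  data.frame(bmi = bmi, category = category)
}

#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = insulin (uIU/mL) x glucose (mg/dL) / 405`.
#'
#' @param insulin Fasting insulin in uIU/mL (>= 0), vectorized.
#' @param glucose Fasting glucose in mg/dL (>= 0), vectorized.
#' @return Numeric HOMA-IR values (unitless).
#' @examples
#' round(homa_ir(10.41, 95.86), 2)  # 2.46
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0) || any(glucose < 0)) {
    stop_mhonet("insulin and glucose must be >= 0")
  }
  insulin * glucose / 405
}

#' Count modified-IDF cardiometabolic risk factors
#'
#' Four criteria are checked with the inequality directions of the modified
#' International Diabetes Federation list used for young adults:
#' triglycerides >= 150 mg/dL, fasting glucose >= 126 mg/dL,
#' HDL cholesterol < 45 mg/dL, and elevated blood pressure at or above
#' 120/80 mmHg.  The blood-pressure criterion is disjunctive by default
#' (systolic >= 120 OR diastolic >= 80); set `bp_rule = "and"` for the
#' conjunctive reading.
#'
#' @param triglycerides,glucose,hdl mg/dL, vectorized.
#' @param sbp,dbp Systolic/diastolic blood pressure in mmHg, vectorized.
#' @param bp_rule `"or"` (default) or `"and"`.
#' @return Integer vector of risk-factor counts in 0..4.
#' @examples
#' idf_risk_factors(150, 126, 44.9, 120, 80)  # all four boundaries trigger
#' @export
idf_risk_factors <- function(triglycerides, glucose, hdl, sbp, dbp,
                             bp_rule = c("or", "and")) {
  bp_rule <- match.arg(bp_rule)
  if (any(c(triglycerides, glucose, hdl, sbp, dbp) <= 0)) {
    stop_mhonet("metabolic measurements must be positive")
  }
  bp <- if (bp_rule == "or") (sbp >= 120) | (dbp >= 80) else
    (sbp >= 120) & (dbp >= 80)
  as.integer((triglycerides >= 150) + (glucose >= 126) + (hdl < 45) + bp)
}

#' Classify metabolic health as MHO or MUO
#'
#' Two classification methods are supported.  Method `"idf"` labels a
#' participant MUO when two or more of the four risk factors are present.
#' Method `"idf_homa"` additionally requires insulin resistance: MUO needs
#' HOMA-IR >= 3 *and* two or more risk factors, while HOMA-IR < 3 is always
#' MHO.  The combination HOMA-IR >= 3 with fewer than two risk factors is
#' not covered by either stated rule; it defaults to MHO (both MUO
#' conditions are required) and can be switched with `ambiguous_homa`.
#'
#' @param risk_factor_count Integer counts in 0..4, vectorized.
#' @param homa HOMA-IR values; ignored for method `"idf"`.
#' @param method `"idf"` or `"idf_homa"`.
#' @param ambiguous_homa Label for the HOMA-IR >= 3, count <= 1 cell under
#'   `"idf_homa"`; `"MHO"` (default) or `"MUO"`.
#' @return Character vector of `"MHO"`/`"MUO"` labels.
#' @examples
#' classify_metabolic(2, method = "idf")                   # MUO
#' classify_metabolic(0, homa = 2.0, method = "idf_homa")  # MHO
#' classify_metabolic(3, homa = 3.5, method = "idf_homa")  # MUO
#' @export
classify_metabolic <- function(risk_factor_count, homa = NULL,
                               method = c("idf", "idf_homa"),
                               ambiguous_homa = c("MHO", "MUO")) {
  method <- match.arg(method)
  ambiguous_homa <- match.arg(ambiguous_homa)
  if (any(risk_factor_count < 0 | risk_factor_count > 4)) {
    stop_mhonet("risk_factor_count must be in 0..4")
  }
  if (method == "idf") {
    return(ifelse(risk_factor_count >= 2, "MUO", "MHO"))
  }
  if (is.null(homa)) stop_mhonet("method 'idf_homa' needs `homa`")
  if (any(homa < 0)) stop_mhonet("`homa` must be >= 0")
  ifelse(homa >= 3,
         ifelse(risk_factor_count >= 2, "MUO", ambiguous_homa),
         "MHO")
}

#' Classify a whole cohort table
#'
#' Adds the derived metabolic columns to a participant table: `bmi`,
#' `bmi_category`, `homa_ir`, `risk_factor_count`, and both classification
#' labels `label_idf` and `label_idf_homa`.  The table must carry columns
#' `weight`, `height`, `triglycerides`, `glucose`, `hdl`, `sbp`, `dbp` and
#' `insulin` in the units documented for the individual classifiers.
#'
#' @param table Participant data frame.
#' @param bp_rule,ambiguous_homa Passed through to [idf_risk_factors()] and
#'   [classify_metabolic()].
#' @return The table with the six derived columns appended.
#' @export
classify_cohort <- function(table, bp_rule = "or", ambiguous_homa = "MHO") {
  needed <- c("weight", "height", "triglycerides", "glucose", "hdl",
              "sbp", "dbp", "insulin")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop_mhonet("cohort table lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0) {
    table$bmi <- numeric(0); table$bmi_category <- character(0)
    table$homa_ir <- numeric(0); table$risk_factor_count <- integer(0)
    table$label_idf <- character(0); table$label_idf_homa <- character(0)
    return(table)
  }
  b <- compute_bmi(table$weight, table$height)
  table$bmi <- b$bmi
  table$bmi_category <- as.character(b$category)
  table$homa_ir <- homa_ir(table$insulin, table$glucose)
  table$risk_factor_count <- idf_risk_factors(
    table$triglycerides, table$glucose, table$hdl, table$sbp, table$dbp,
    bp_rule = bp_rule)
  table$label_idf <- classify_metabolic(table$risk_factor_count,
                                        method = "idf")
  table$label_idf_homa <- classify_metabolic(
    table$risk_factor_count, homa = table$homa_ir, method = "idf_homa",
    ambiguous_homa = ambiguous_homa)
  table
}
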