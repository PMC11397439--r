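#' Descriptive summary with a normality screen
#'
#' Median, sample standard deviation (n-1 denominator), minimum, maximum,
#' and a normality test.  Shapiro-Wilk is the primary screen; a
#' Kolmogorov-Smirnov test against a normal with the sample's moments is
#' available as an option.  Shapiro-Wilk accepts at most 5000 values, so
#' longer vectors are screened on a seeded subsample of 5000.  A constant
#' vector has no defined normality statistic and is reported as `NA` with a
#' warning.
#'
#' @param x Numeric vector, length >= 3, no missing values.
#' @param normality `"shapiro"` (default) or `"ks"`.
#' @return One-row data frame: `median`, `sd`, `min`, `max`,
#'   `normality_statistic`, `normality_p`.
#' @examples
#' describe_variable(c(1, 2, 3))
#' @export
describe_variable <- function(x, normality = c("shapiro", "ks")) {
  normality <- match.arg(normality)
  if (anyNA(x)) stop_mhonet("missing values are not supported")
  if (length(x) < 3) stop_mhonet("need at least 3 values")
  w <- p <- NA_real_
  if (diff(range(x)) == 0) {
    warning("constant vector: normality undefined", call. = FALSE)
  } else if (normality == "shapiro") {
    xs <- x
    if (length(xs) > 5000) {
      local_seed(0L)
      xs <- sample(xs, 5000)
    }
    t <- stats::shapiro.test(xs)
    w <- unname(t$statistic); p <- t$p.value
  } else {
    t <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
    w <- unname(t$statistic); p <- t$p.value
  }
  data.frame(median = stats::median(x), sd = stats::sd(x),
             min = min(x), max = max(x),
             normality_statistic = w, normality_p = p)
}

#' Describe every numeric variable of a cohort table
#'
#' @param table Data frame; non-numeric columns are skipped.
#' @param normality Passed to [describe_variable()].
#' @return Data frame with one row per numeric variable.
#' @export
describe_cohort <- function(table, normality = "shapiro") {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(num, function(v) {
    cbind(variable = v, describe_variable(table[[v]], normality = normality))
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums with average ranks for ties and reported
#' for the first sample.  When the combined size is at most 12 and there
#' are no ties, the two-sided p-value is exact (doubled tail of the exact
#' null distribution of U); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Nonempty numeric vectors.
#' @return List with `u` (U statistic of `x`), `p` (two-sided p-value), and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop_mhonet("both samples must be nonempty")
  }
  if (anyNA(x) || anyNA(y)) stop_mhonet("missing values are not supported")
  n1 <- length(x); n2 <- length(y)
  combined <- c(x, y)
  r <- rank(combined)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(combined) > 0

  if (n1 + n2 <= 12 && !ties) {
    p_lower <- stats::pwilcox(u, n1, n2)
    p_upper <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_lower, p_upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tab <- table(combined)
    tie_term <- sum(tab^3 - tab) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (u == mu) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(u = u, p = p, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1 and
#' mapped back to input order (the classic BH procedure, delegated to
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order; empty input gives an empty vector.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_mhonet("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Compare two groups variable by variable
#'
#' For every numeric variable, reports median and interquartile bounds per
#' group (linear-interpolation quantiles), the Mann-Whitney U statistic and
#' two-sided p-value, the Benjamini-Hochberg q-value computed across the
#' whole variable family, and a significance flag at p < 0.005.
#'
#' @param table Participant data frame including the label column.
#' @param label_column Name of the column holding exactly two group labels.
#' @param alpha Significance cutoff on the unadjusted p-value
#'   (default 0.005).
#' @return Data frame with one row per variable: group medians/quartiles,
#'   `u_statistic`, `p_value`, `q_value`, `significant`.  The `u_statistic`
#'   is reported for the first group in label sort order.
#' @export
compare_groups <- function(table, label_column, alpha = 0.005) {
  if (!label_column %in% names(table)) {
    stop_mhonet("label column '", label_column, "' not found")
  }
  labels <- as.character(table[[label_column]])
  groups <- sort(unique(labels))
  if (length(groups) != 2) {
    stop_mhonet("expected exactly 2 group labels, found ", length(groups))
  }
  if (any(tabulate(factor(labels, groups)) < 3)) {
    stop_mhonet("each group needs at least 3 members")
  }
  num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                 label_column)
  rows <- lapply(num, function(v) {
    a <- table[[v]][labels == groups[1]]
    b <- table[[v]][labels == groups[2]]
    qa <- stats::quantile(a, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    qb <- stats::quantile(b, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    mw <- mann_whitney_u(a, b)
    data.frame(variable = v,
               median_1 = qa[1], q1_1 = qa[2], q3_1 = qa[3],
               median_2 = qb[1], q1_2 = qb[2], q3_2 = qb[3],
               u_statistic = mw$u, p_value = mw$p)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_1$", paste0("_", tolower(groups[1])), names(out))
  names(out) <- sub("_2$", paste0("_", tolower(groups[2])), names(out))
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  attr(out, "groups") <- groups
  rownames(out) <- NULL
  out
}
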