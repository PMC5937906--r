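# Derived anthropometrics: BMI, LMS z-scores, IOTF-style weight category,
# circumference ratios, HOMA-IR, and the stratified descriptive summaries.

#' Body mass index
#'
#' `bmi = weight / (height/100)^2`. Heights below 50 are rejected as a unit
#' error (a height in metres supplied where centimetres are expected).
#'
#' @param weight weight in kg (positive).
#' @param height height in cm (positive, >= 50).
#' @return BMI in kg/m^2, vectorised.
#' @examples
#' compute_bmi(45.39, 141.3)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop_data("weight and height must be positive")
  }
  if (any(height < 50)) {
    stop_data("height < 50: expected centimetres, got what looks like metres")
  }
  weight / (height / 100)^2
}

#' LMS z-score
#'
#' Standardises a measurement against an LMS growth reference:
#' `z = ((X/M)^L - 1) / (L*S)` for `L != 0`, and the Box-Cox limit
#' `z = log(X/M) / S` as `L -> 0` (used when `|L| <= 1e-8`).
#'
#' @param x measured value (positive), vectorised.
#' @param L Box-Cox power (unitless).
#' @param M median of the reference distribution (same units as `x`).
#' @param S coefficient of variation (positive).
#' @return z-score in SD units.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(!is.finite(x)) || any(x <= 0)) stop_data("measured value must be positive")
  if (any(M <= 0) || any(S <= 0)) stop_data("LMS parameters require M > 0 and S > 0")
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) > 1e-8,
         ((x / M)^L - 1) / (L * S),
         log(x / M) / S)
}

#' Invert an LMS z-score
#'
#' Returns the measurement corresponding to a given z-score under an LMS
#' reference; the inverse of [lms_zscore()]. Used by the synthetic-cohort
#' generator to turn latent z values into BMI.
#'
#' @inheritParams lms_zscore
#' @param z z-score in SD units.
#' @return measurement in the reference's units.
#' @export
lms_inverse <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) > 1e-8,
         M * (1 + L * S * z)^(1 / L),
         M * exp(S * z))
}

.interp_rows <- function(tab, sex, at, age_col) {
  sub <- tab[tab$sex == sex, , drop = FALSE]
  if (!nrow(sub)) stop_data("no reference rows for sex '", sex, "'")
  sub <- sub[order(sub[[age_col]]), , drop = FALSE]
  ages <- sub[[age_col]]
  step <- if (nrow(sub) > 1) max(diff(ages)) else 0
  lo <- min(ages) - step; hi <- max(ages) + step
  if (any(at < lo | at > hi)) {
    stop_data("age ", format(at[at < lo | at > hi][1]),
              " outside reference range [", format(min(ages)), ", ",
              format(max(ages)), "] (plus one grid step)")
  }
  at_cl <- pmin(pmax(at, min(ages)), max(ages))
  vals <- setdiff(names(sub), c("sex", age_col))
  out <- lapply(vals, function(v) stats::approx(ages, sub[[v]], xout = at_cl,
                                                rule = 2)$y)
  names(out) <- vals
  as.data.frame(out)
}

#' Look up LMS parameters for a child
#'
#' Linearly interpolates L, M and S in age (each parameter independently)
#' between the bracketing reference rows for the child's sex. Ages at a grid
#' point return that row exactly; ages within one grid step outside the table
#' range use the boundary row; anything further out is an error.
#'
#' @param sex `"male"` or `"female"`, vectorised with `age_days`.
#' @param age_days chronological age in days; converted to months with the
#'   mean month length 30.4375 days.
#' @param table data frame with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @return data frame with columns `L`, `M`, `S`, one row per input.
#' @export
lms_lookup <- function(sex, age_days, table) {
  stopifnot(all(c("sex", "age_months", "L", "M", "S") %in% names(table)))
  n <- max(length(sex), length(age_days))
  sex <- rep_len(sex, n)
  age_months <- rep_len(age_days, n) / 30.4375
  out <- data.frame(L = numeric(n), M = NA_real_, S = NA_real_)
  for (sx in unique(sex)) {
    i <- sex == sx
    out[i, c("L", "M", "S")] <-
      .interp_rows(table, sx, age_months[i], "age_months")[, c("L", "M", "S")]
  }
  out
}

#' Classify weight category against age/sex BMI cutoffs
#'
#' Compares BMI with the sex- and age-interpolated overweight cutoff of an
#' IOTF-style table; children at or above the cutoff are the
#' `overweight_obese` case group (overweight and obese are merged), the rest
#' are `normal_weight` controls. The boundary is assigned to the case group.
#'
#' @param bmi BMI in kg/m^2.
#' @param sex `"male"`/`"female"`, vectorised.
#' @param age_years age in years.
#' @param cutoffs data frame with columns `sex`, `age_years`,
#'   `bmi_overweight`, `bmi_obese`.
#' @return character vector, `"normal_weight"` or `"overweight_obese"`.
#' @export
iotf_classify <- function(bmi, sex, age_years, cutoffs) {
  stopifnot(all(c("sex", "age_years", "bmi_overweight", "bmi_obese")
                %in% names(cutoffs)))
  n <- max(length(bmi), length(sex), length(age_years))
  bmi <- rep_len(bmi, n); sex <- rep_len(sex, n)
  age_years <- rep_len(age_years, n)
  ow <- numeric(n)
  for (sx in unique(sex)) {
    i <- sex == sx
    ow[i] <- .interp_rows(cutoffs, sx, age_years[i], "age_years")$bmi_overweight
  }
  ifelse(bmi >= ow, "overweight_obese", "normal_weight")
}

#' HOMA-IR insulin-resistance index
#'
#' `HOMA-IR = insulin (uU/ml) x glucose (mg/dl) / 405`.
#'
#' @param insulin fasting insulin in uU/ml (non-negative).
#' @param glucose fasting glucose in mg/dl (non-negative).
#' @return unitless index, vectorised; `NA` propagates.
#' @examples
#' homa_ir(6.88, 78.5)
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE)) {
    stop_data("insulin and glucose must be non-negative")
  }
  insulin * glucose / 405
}

#' Derive anthropometric columns on a cohort
#'
#' Adds `bmi`, `zbmi` (LMS z-score of BMI), `whr` (waist/hip), `whtr`
#' (waist/height), `homa_ir` and the IOTF `weight_category` to a cohort
#' table. Ratios and HOMA-IR are `NA` where their inputs are missing.
#'
#' @param cohort a `cohort_table` (or phenotype data frame).
#' @param lms LMS reference table (`sex`, `age_months`, `L`, `M`, `S`).
#' @param iotf cutoff table (`sex`, `age_years`, `bmi_overweight`,
#'   `bmi_obese`).
#' @return the cohort with derived columns added.
#' @export
derive_anthro <- function(cohort, lms, iotf) {
  cohort$bmi <- compute_bmi(cohort$weight, cohort$height)
  row <- lms_lookup(cohort$sex, cohort$age_days, lms)
  cohort$zbmi <- lms_zscore(cohort$bmi, row$L, row$M, row$S)
  cohort$whr <- if (all(c("waist", "hip") %in% names(cohort))) {
    cohort$waist / cohort$hip
  } else NA_real_
  cohort$whtr <- if ("waist" %in% names(cohort)) {
    cohort$waist / cohort$height
  } else NA_real_
  cohort$homa_ir <- if (all(c("insulin", "glucose") %in% names(cohort))) {
    homa_ir(cohort$insulin, cohort$glucose)
  } else NA_real_
  cohort$weight_category <- iotf_classify(cohort$bmi, cohort$sex,
                                          cohort$age_days / 365.25, iotf)
  cohort
}

# Dunn's rank-based pairwise comparisons on k groups: z statistics on mean
# ranks with the tie-corrected variance, Bonferroni-multiplied p values.
# Groups with < 2 non-missing observations are dropped from testing.
dunn_pairwise <- function(values, groups, adjust_m = NULL) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  cnt <- table(groups)
  usable <- names(cnt)[cnt >= 2]
  if (length(usable) < 2) {
    return(data.frame(group1 = character(), group2 = character(),
                      z = numeric(), p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  keep <- groups %in% usable
  v <- values[keep]; g <- groups[keep]
  N <- length(v)
  r <- rank(v)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  pairs <- utils::combn(sort(usable), 2)
  m <- adjust_m %||% ncol(pairs)
  res <- apply(pairs, 2, function(p) {
    se <- sqrt(s2 * (1 / n_g[[p[1]]] + 1 / n_g[[p[2]]]))
    z <- if (se > 0) (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se else 0
    p_raw <- 2 * stats::pnorm(-abs(z))
    c(z = z, p_raw = p_raw, p_adj = min(1, p_raw * m))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p_raw = res["p_raw", ], p_adj = res["p_adj", ],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Welch pairwise alternative with Bonferroni multiplication.
welch_pairwise <- function(values, groups, adjust_m = NULL) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  cnt <- table(groups)
  usable <- names(cnt)[cnt >= 2]
  if (length(usable) < 2) {
    return(data.frame(group1 = character(), group2 = character(),
                      z = numeric(), p_raw = numeric(), p_adj = numeric()))
  }
  pairs <- utils::combn(sort(usable), 2)
  m <- adjust_m %||% ncol(pairs)
  res <- apply(pairs, 2, function(p) {
    a <- values[groups == p[1]]; b <- values[groups == p[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p_raw <- if (mean(a) == mean(b)) 1 else 0
      return(c(z = if (p_raw == 1) 0 else Inf, p_raw = p_raw,
               p_adj = min(1, p_raw * m)))
    }
    tt <- stats::t.test(a, b)
    c(z = unname(tt$statistic), p_raw = tt$p.value,
      p_adj = min(1, tt$p.value * m))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p_raw = res["p_raw", ], p_adj = res["p_adj", ],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratified descriptive summary with pairwise comparisons
#'
#' Per-stratum n, mean and SD for each variable (non-missing values only),
#' with pairwise between-stratum comparisons. The default comparison is
#' Dunn's rank-based z test on mean ranks with Bonferroni multiplication
#' (matching the "distributions (mean ranks) vary between groups" footnote
#' convention); `method = "welch"` selects pairwise Welch t tests instead.
#' Pairs with adjusted p < 0.05 are flagged. A stratum with fewer than two
#' non-missing values for a variable is excluded from that variable's
#' comparisons (not an error).
#'
#' @param cohort a cohort table (after [derive_anthro()] if stratifying by
#'   weight category).
#' @param stratifier column name to stratify by, e.g. `"sex"` or
#'   `"weight_category"`.
#' @param variables character vector of numeric columns to summarise;
#'   defaults to all numeric columns except `age_days`.
#' @param method `"dunn"` (rank-based, default) or `"welch"`.
#' @param alpha flagging threshold on the adjusted p (default 0.05).
#' @return A list of class `"stratified_summary"`: `summary` (variable x
#'   stratum n/mean/sd) and `comparisons` (pairwise adjusted p with
#'   significance flags).
#' @export
stratified_summary <- function(cohort, stratifier,
                               variables = NULL,
                               method = c("dunn", "welch"),
                               alpha = 0.05) {
  method <- match.arg(method)
  if (!stratifier %in% names(cohort)) {
    stop_config("stratifier column '", stratifier, "' not in cohort")
  }
  strata <- cohort[[stratifier]]
  if (sum(table(strata) > 0) < 2) stop_data("need at least 2 non-empty strata")
  if (is.null(variables)) {
    num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    variables <- setdiff(num, "age_days")
  }
  pairfun <- if (method == "dunn") dunn_pairwise else welch_pairwise
  sum_rows <- list(); cmp_rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    for (s in sort(unique(strata))) {
      xi <- x[strata == s & !is.na(x)]
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        variable = v, stratum = s, n = length(xi),
        mean = if (length(xi)) mean(xi) else NA_real_,
        sd = if (length(xi) > 1) stats::sd(xi) else NA_real_,
        stringsAsFactors = FALSE)
    }
    cmp <- pairfun(x, strata)
    if (nrow(cmp)) {
      cmp <- cbind(variable = v, cmp,
                   significant = !is.na(cmp$p_adj) & cmp$p_adj < alpha)
      cmp_rows[[length(cmp_rows) + 1L]] <- cmp
    }
  }
  out <- list(summary = do.call(rbind, sum_rows),
              comparisons = if (length(cmp_rows)) do.call(rbind, cmp_rows)
                            else NULL,
              stratifier = stratifier, method = method, alpha = alpha)
  class(out) <- "stratified_summary"
  out
}

#' @export
print.stratified_summary <- function(x, ...) {
  cat("Stratified summary by", x$stratifier, "(", x$method, "pairwise )\n")
  s <- x$summary
  s$mean <- round(s$mean, 3); s$sd <- round(s$sd, 3)
  print(s, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons[x$comparisons$significant, , drop = FALSE]
    cat("Significant pairs (adjusted p <", x$alpha, "):", nrow(sig), "\n")
  }
  invisible(x)
}

#' Write a stratified descriptive summary as TSV
#'
#' One row per variable x stratum with n, mean, sd, plus a second block of
#' pairwise comparisons with adjusted p values and significance flags.
#'
#' @param x a `stratified_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stratified_summary <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  utils::write.table(x$summary, con, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  if (!is.null(x$comparisons)) {
    writeLines("", con)
    utils::write.table(x$comparisons, con, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
  }
  invisible(path)
}
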