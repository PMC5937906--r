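# The Falconer single-locus effect decomposition: additive and dominance
# effects, average effect of allele substitution, dominance-type
# classification and effect-size grading, exposed both as a low-level
# kernel on genotype means (falconer_decompose) and as a model fit on
# individual-level data (falconer).

#' Pool stratified means
#'
#' n-weighted pooling of per-stratum means, used to rebuild overall genotype
#' means from stratified descriptive tables.
#'
#' @param n integer vector of stratum sizes (all >= 1).
#' @param mean numeric vector of stratum means.
#' @return list with `n` (total) and `mean` (pooled).
#' @examples
#' pool_stratum_means(c(76, 107), c(2.11, 0.15))
#' @export
pool_stratum_means <- function(n, mean) {
  if (!length(n)) stop_data("no strata to pool")
  if (length(n) != length(mean)) stop_config("n and mean lengths differ")
  if (any(n < 1)) stop_data("every stratum must have n >= 1")
  list(n = sum(n), mean = sum(n * mean) / sum(n))
}

#' Effect-size grading cutoffs
#'
#' Thresholds on the absolute graded quantity (zBMI SD units when grading
#' zBMI effects): very weak below 0.05, weak up to 0.2, medium up to 0.8,
#' strong above. Boundary values are assigned upward.
#'
#' @param very_weak_max,weak_max,medium_max strictly increasing positive
#'   thresholds.
#' @return named numeric vector of class `"effect_grade_cutoffs"`.
#' @export
effect_grade_cutoffs <- function(very_weak_max = 0.05, weak_max = 0.2,
                                 medium_max = 0.8) {
  v <- c(very_weak_max = very_weak_max, weak_max = weak_max,
         medium_max = medium_max)
  if (any(diff(v) <= 0) || v[1] <= 0) {
    stop_config("grading cutoffs must be positive and strictly increasing")
  }
  class(v) <- "effect_grade_cutoffs"
  v
}

#' Classify the dominance type of a locus
#'
#' Classifies by the dominance ratio `r = |d/a|`: no dominance when `|d|` is
#' negligible relative to `|a|`, complete dominance when `r` is within a
#' relative tolerance band of 1, partial below the band, overdominance above
#' (including `a = 0, d != 0`, where `r` is infinite).
#'
#' @param a additive effect (half the homozygote divergence, minor-allele
#'   oriented).
#' @param d dominance deviation (heterozygote minus homozygote midpoint).
#' @param tol relative tolerance of the band (default 0.25: ratios in
#'   `[0.75, 1.25]` count as complete dominance, `|d| <= 0.25|a|` as none).
#' @return one of `"no_dominance"`, `"partial_dominance"`,
#'   `"complete_dominance"`, `"overdominance"`; `a = d = 0` returns
#'   `"no_dominance"` with attribute `degenerate = TRUE`.
#' @examples
#' classify_dominance(-0.15, 0.28)
#' @export
classify_dominance <- function(a, d, tol = 0.25) {
  if (a == 0 && d == 0) {
    return(structure("no_dominance", degenerate = TRUE))
  }
  if (abs(d) <= tol * abs(a)) return("no_dominance")
  r <- if (a == 0) Inf else abs(d / a)
  if (is.finite(r) && abs(r - 1) <= tol) return("complete_dominance")
  if (r < 1 - tol) "partial_dominance" else "overdominance"
}

#' Grade an effect size
#'
#' Grades `|x|` against the cutoffs (boundaries assigned to the higher
#' grade) and appends the direction of the effect: `"increase"` for
#' `x > 0`, `"decrease"` for `x < 0`. `x = 0` is graded `"very weak"` with
#' no direction.
#'
#' @param x the effect to grade (zBMI SD units by default usage).
#' @param cutoffs an [effect_grade_cutoffs()] vector.
#' @return a character label such as `"weak decrease"`, with attributes
#'   `magnitude` and `direction`.
#' @examples
#' grade_effect_size(-0.09)
#' grade_effect_size(0.03)
#' @export
grade_effect_size <- function(x, cutoffs = effect_grade_cutoffs()) {
  if (!is.finite(x)) stop_data("effect to grade must be finite")
  ax <- abs(x)
  mag <- if (ax < cutoffs[["very_weak_max"]]) "very weak"
         else if (ax < cutoffs[["weak_max"]]) "weak"
         else if (ax < cutoffs[["medium_max"]]) "medium"
         else "strong"
  dir <- if (x > 0) "increase" else if (x < 0) "decrease" else ""
  structure(trimws(paste(mag, dir)), magnitude = mag, direction = dir)
}

#' Falconer decomposition of genotype means
#'
#' Decomposes the three genotype means of a biallelic locus into the
#' homozygote midpoint `m`, the additive effect `a` (minor-homozygote mean
#' minus `m`; half the divergence between the homozygotes, oriented toward
#' the minor allele) and the dominance deviation `d` (heterozygote mean
#' minus `m`). The average effect of substituting a major for a minor
#' allele in a random-mating population is `alpha = a + d (p - q)` with `p`
#' the major- and `q` the minor-allele frequency; the minor-allele average
#' effect is `alpha1 = p * alpha`. The frequency-weighted population mean
#' `m + a (q - p) + 2 p q d` is reported as `pop_mean_hw`, alongside the
#' homozygote midpoint (`population_mean`, the value conventionally printed
#' in effect tables). The dominance type and the graded effect size (of
#' `alpha1` by default) are attached.
#'
#' @param means numeric length 3: phenotype means of (major homozygote,
#'   heterozygote, minor homozygote). Any `NA` yields a not-computable
#'   result carrying whichever quantities remain defined.
#' @param freqs major/minor allele frequencies: a list with `p` and `q`
#'   (e.g. from [allele_freqs()]) or a numeric `c(p, q)`.
#' @param n optional genotype class sizes (same order as `means`).
#' @param tol dominance-classification tolerance, see
#'   [classify_dominance()].
#' @param cutoffs grading cutoffs, see [effect_grade_cutoffs()].
#' @param grade_on which quantity the effect grade is computed from:
#'   `"minor_avg_effect"` (default), `"alpha"` or `"additive"`.
#' @return An object of class `"falconer_effects"`.
#' @examples
#' falconer_decompose(c(0.9640, 1.0933, 0.6614), c(p = 653/1234, q = 581/1234))
#' @export
falconer_decompose <- function(means, freqs, n = NULL, tol = 0.25,
                               cutoffs = effect_grade_cutoffs(),
                               grade_on = c("minor_avg_effect", "alpha",
                                            "additive")) {
  grade_on <- match.arg(grade_on)
  if (length(means) != 3) stop_config("means must have length 3")
  if (is.list(freqs)) freqs <- c(p = freqs$p, q = freqs$q)
  p <- unname(freqs[1]); q <- unname(freqs[2])
  if (abs(p + q - 1) > 1e-8) stop_data("allele frequencies must sum to 1")
  if (!is.null(n) && any(n[!is.na(means)] == 0)) {
    stop_data("a present genotype mean cannot have n = 0")
  }
  out <- list(means = means, n = n, p = p, q = q,
              midpoint = NA_real_, additive = NA_real_, dominance = NA_real_,
              alpha = NA_real_, minor_avg_effect = NA_real_,
              aecme = NA_real_, population_mean = NA_real_,
              pop_mean_hw = NA_real_, dominance_ratio = NA_real_,
              dominance_type = NA_character_, effect_grade = NA_character_,
              grade_on = grade_on, tol = tol, cutoffs = cutoffs,
              computable = !anyNA(means))
  if (!anyNA(means[c(1, 3)])) {
    out$midpoint <- (means[1] + means[3]) / 2
    out$population_mean <- out$midpoint
    out$additive <- means[3] - out$midpoint
  }
  if (!anyNA(means) ) {
    out$dominance <- means[2] - out$midpoint
    out$alpha <- out$additive + out$dominance * (p - q)
    out$minor_avg_effect <- p * out$alpha
    # the per-substitution effect, reported under the table heading
    # "average effect of changing to minor allele"
    out$aecme <- out$alpha
    out$pop_mean_hw <- out$midpoint + out$additive * (q - p) +
      2 * p * q * out$dominance
    out$dominance_ratio <- if (out$additive == 0) {
      if (out$dominance == 0) 0 else Inf
    } else abs(out$dominance / out$additive)
    out$dominance_type <- as.character(
      classify_dominance(out$additive, out$dominance, tol))
    graded <- switch(grade_on,
                     minor_avg_effect = out$minor_avg_effect,
                     alpha = out$alpha,
                     additive = out$additive)
    out$effect_grade <- as.character(grade_effect_size(graded, cutoffs))
  }
  class(out) <- "falconer_effects"
  out
}

#' Reconstruct genotype means from a Falconer decomposition
#'
#' Inverse of [falconer_decompose()]: returns `c(m - a, m + d, m + a)`,
#' recovering the (major homozygote, heterozygote, minor homozygote) means
#' exactly.
#'
#' @param effects a `"falconer_effects"` object.
#' @return numeric length 3.
#' @export
reconstruct_means <- function(effects) {
  c(effects$midpoint - effects$additive,
    effects$midpoint + effects$dominance,
    effects$midpoint + effects$additive)
}

#' @export
print.falconer_effects <- function(x, digits = 4, ...) {
  cat("Falconer single-locus decomposition\n")
  if (!x$computable) cat("  (not fully computable: missing genotype class)\n")
  fmt <- function(v) if (is.na(v)) "NA" else format(round(v, digits))
  cat("  homozygote midpoint m :", fmt(x$midpoint), "\n")
  cat("  additive effect a     :", fmt(x$additive), "\n")
  cat("  dominance deviation d :", fmt(x$dominance), "\n")
  cat("  alpha (substitution)  :", fmt(x$alpha), "\n")
  cat("  minor-allele avg eff  :", fmt(x$minor_avg_effect), "\n")
  cat("  HW population mean    :", fmt(x$pop_mean_hw), "\n")
  if (!is.na(x$dominance_type)) {
    cat("  dominance type        :", x$dominance_type,
        sprintf("(|d/a| = %s)", fmt(x$dominance_ratio)), "\n")
  }
  if (!is.na(x$effect_grade)) {
    cat("  effect grade (", x$grade_on, ") :", x$effect_grade, "\n")
  }
  invisible(x)
}

.genotype_levels <- function(cnt) {
  c(major_homo = paste(cnt$major_allele, cnt$major_allele, sep = "/"),
    het = .norm_call(cnt$major_allele, cnt$minor_allele),
    minor_homo = paste(cnt$minor_allele, cnt$minor_allele, sep = "/"))
}

#' Fit a single-locus Falconer model
#'
#' Fits the classical single-locus quantitative-genetics model to
#' individual-level data: the phenotype is decomposed over the three
#' genotype classes of one biallelic SNP into the homozygote midpoint,
#' additive effect and dominance deviation, with allele frequencies
#' estimated from the same calls (or supplied). The fit is by genotype-class
#' means, the maximum-likelihood estimate under homoscedastic Gaussian
#' noise.
#'
#' @param formula `phenotype ~ snp`, where the SNP column holds genotype
#'   call strings (`"A/G"`).
#' @param data a `cohort_table` (or any data frame; major/minor orientation
#'   is then inferred from observed allele frequency).
#' @param group optional weight-category filter (requires derived
#'   `weight_category`).
#' @param freqs optional allele frequencies (list with `p`, `q`) overriding
#'   the estimate from the data.
#' @param tol,cutoffs,grade_on passed to [falconer_decompose()].
#' @return An object of class `"falconer"`: the decomposition plus genotype
#'   class sizes, standard errors of `a` and `d`, the residual SD and the
#'   model frame.
#' @examples
#' fix <- make_study_fixture(seed = 1)
#' fit <- falconer(zbmi ~ rs1137101, data = fix$cohort)
#' fit
#' coef(fit)
#' @export
falconer <- function(formula, data, group = NULL, freqs = NULL,
                     tol = 0.25, cutoffs = effect_grade_cutoffs(),
                     grade_on = "minor_avg_effect") {
  vars <- all.vars(formula)
  if (length(vars) != 2) stop_config("formula must be phenotype ~ snp")
  phenotype <- vars[1]; snp_id <- vars[2]
  cnt <- count_genotypes(data, snp_id, group)
  if (is.na(cnt$minor_allele)) {
    stop_data("SNP ", snp_id, " is monomorphic in the fitting data; ",
              "the decomposition needs all three genotype classes")
  }
  dat <- data
  if (!is.null(group)) {
    dat <- dat[!is.na(dat$weight_category) & dat$weight_category == group, ]
  }
  y <- dat[[phenotype]]; g <- dat[[snp_id]]
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  lv <- .genotype_levels(cnt)
  n_g <- vapply(lv, function(x) sum(g == x), integer(1))
  mean_g <- vapply(lv, function(x) if (sum(g == x)) mean(y[g == x]) else NA_real_,
                   numeric(1))
  sd_g <- vapply(lv, function(x) if (sum(g == x) > 1) stats::sd(y[g == x])
                 else NA_real_, numeric(1))
  if (is.null(freqs)) {
    freqs <- allele_freqs(genotype_counts(n_g[1], n_g[2], n_g[3]))
  }
  eff <- falconer_decompose(unname(mean_g), freqs, n = unname(n_g),
                            tol = tol, cutoffs = cutoffs,
                            grade_on = grade_on)
  se_mean <- sd_g / sqrt(n_g)
  resid_df <- sum(pmax(n_g - 1L, 0L))
  sigma <- if (resid_df > 0) {
    sqrt(sum((n_g - 1L) * sd_g^2, na.rm = TRUE) / resid_df)
  } else NA_real_
  out <- c(eff[setdiff(names(eff), "n")], list(
    phenotype = phenotype, snp_id = snp_id, group = group,
    genotype_levels = lv, n_class = n_g, mean_class = mean_g,
    sd_class = sd_g,
    se_additive = 0.5 * sqrt(se_mean[[1]]^2 + se_mean[[3]]^2),
    se_dominance = sqrt(se_mean[[2]]^2 +
                          0.25 * (se_mean[[1]]^2 + se_mean[[3]]^2)),
    sigma = sigma, n = length(y),
    model = data.frame(y = y, genotype = g)
  ))
  class(out) <- c("falconer", "falconer_effects")
  out
}

#' @export
print.falconer <- function(x, digits = 4, ...) {
  cat("Single-locus Falconer model:", x$phenotype, "~", x$snp_id,
      if (!is.null(x$group)) paste0("[", x$group, "]"), "\n")
  cat(sprintf("  n = %d (%s)\n", x$n,
              paste(sprintf("%s: %d", x$genotype_levels, x$n_class),
                    collapse = ", ")))
  cat(sprintf("  allele freqs: p(major) = %.3f, q(minor) = %.3f\n", x$p, x$q))
  NextMethod()
}

#' @export
summary.falconer <- function(object, ...) {
  x <- object
  tab <- data.frame(
    genotype = x$genotype_levels, n = x$n_class,
    mean = x$mean_class, sd = x$sd_class, row.names = names(x$genotype_levels))
  est <- data.frame(
    estimate = c(additive = x$additive, dominance = x$dominance,
                 alpha = x$alpha, minor_avg_effect = x$minor_avg_effect),
    se = c(x$se_additive, x$se_dominance, NA, NA))
  out <- list(fit = x, genotype_table = tab, estimates = est)
  class(out) <- "summary.falconer"
  out
}

#' @export
print.summary.falconer <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nGenotype classes:\n")
  print(format(x$genotype_table, digits = digits), ...)
  cat("\nEffect estimates:\n")
  print(format(x$estimates, digits = digits), ...)
  invisible(x)
}

#' @export
coef.falconer <- function(object, ...) {
  c(midpoint = object$midpoint, additive = object$additive,
    dominance = object$dominance, alpha = object$alpha,
    minor_avg_effect = object$minor_avg_effect,
    pop_mean_hw = object$pop_mean_hw)
}

#' @export
predict.falconer <- function(object, newdata = NULL, ...) {
  g <- if (is.null(newdata)) object$model$genotype
       else if (is.data.frame(newdata)) newdata[[object$snp_id]]
       else newdata
  fitted_g <- stats::setNames(object$mean_class, object$genotype_levels)
  unname(fitted_g[g])
}

#' @export
residuals.falconer <- function(object, ...) {
  object$model$y - predict(object)
}

#' @export
fitted.falconer <- function(object, ...) predict(object)

#' Simulate cohorts from a fitted single-locus model
#'
#' Draws genotypes from Hardy-Weinberg proportions at the fitted allele
#' frequencies and phenotypes from the fitted genotype means plus Gaussian
#' noise at the fitted residual SD, giving `nsim` replicate data frames the
#' same size as the fitting data.
#'
#' @param object a `"falconer"` fit.
#' @param nsim number of replicates.
#' @param seed optional seed, applied once before drawing.
#' @param ... ignored.
#' @return list of `nsim` data frames with columns `y` and `genotype`.
#' @export
simulate.falconer <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  probs <- c(object$p^2, 2 * object$p * object$q, object$q^2)
  lapply(seq_len(nsim), function(i) {
    idx <- sample.int(3, n, replace = TRUE, prob = probs)
    g <- object$genotype_levels[idx]
    y <- object$mean_class[idx] + stats::rnorm(n, 0, object$sigma)
    data.frame(y = unname(y), genotype = unname(g))
  })
}

#' @export
plot.falconer <- function(x, ...) {
  m <- x$mean_class; se <- x$sd_class / sqrt(x$n_class)
  bp <- graphics::barplot(
    m, names.arg = paste0(x$genotype_levels, "\n(n=", x$n_class, ")"),
    ylab = x$phenotype, main = paste(x$phenotype, "by", x$snp_id),
    ylim = range(0, m + 2 * se, m - 2 * se, na.rm = TRUE), ...)
  graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3, length = 0.05)
  graphics::abline(h = x$midpoint, lty = 2)
  invisible(x)
}

#' Falconer effects table across a SNP panel
#'
#' Computes the full Falconer decomposition for every SNP x phenotype
#' combination from individual-level cohort data (genotype-class means
#' computed directly). SNPs whose minor-homozygote class has fewer than
#' five observations are flagged: their estimates rest on too few
#' individuals to be stable.
#'
#' @param cohort a `cohort_table` with derived anthropometrics.
#' @param phenotypes phenotype columns, default `c("bmi", "zbmi")`.
#' @param snp_ids SNPs to include, default the whole attached panel.
#' @param ... passed to [falconer()].
#' @return data frame, one row per SNP x phenotype, with the effect
#'   estimates, dominance type, effect grade and `flag_small_minor_homo`.
#' @export
effects_table <- function(cohort, phenotypes = c("bmi", "zbmi"),
                          snp_ids = NULL, ...) {
  panel <- attr(cohort, "snp_panel")
  snp_ids <- snp_ids %||% panel$snp_id
  rows <- list()
  for (s in snp_ids) {
    for (ph in phenotypes) {
      fit <- tryCatch(
        falconer(stats::as.formula(paste(ph, "~", s)), cohort, ...),
        falconer_data_error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s, phenotype = ph, n = fit$n,
        n_major_homo = fit$n_class[[1]], n_het = fit$n_class[[2]],
        n_minor_homo = fit$n_class[[3]],
        p_major = fit$p, q_minor = fit$q,
        dominant_effect = fit$dominance, additive_effect = fit$additive,
        population_mean = fit$population_mean,
        pop_mean_hw = fit$pop_mean_hw,
        alpha = fit$alpha, minor_avg_effect = fit$minor_avg_effect,
        aecme = fit$aecme,
        se_additive = fit$se_additive, se_dominance = fit$se_dominance,
        dominance_type = fit$dominance_type %||% NA_character_,
        effect_grade = fit$effect_grade %||% NA_character_,
        flag_small_minor_homo = fit$n_class[[3]] < 5,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
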