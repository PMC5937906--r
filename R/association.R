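# Allele/genotype frequencies, Hardy-Weinberg testing, case-control
# association, and genotype-stratified phenotype contrasts.

#' Genotype counts for one SNP
#'
#' Constructs or extracts (major-homozygote, heterozygote, minor-homozygote)
#' counts. Major/minor orientation comes from the declared panel; when
#' undeclared it is inferred from observed allele frequency, ties broken
#' lexicographically (the alphabetically first symbol becomes major).
#'
#' @param n_major_homo,n_het,n_minor_homo non-negative integer counts.
#' @param snp_id,major_allele,minor_allele optional labels.
#' @return An object of class `"genotype_counts"`.
#' @export
genotype_counts <- function(n_major_homo, n_het, n_minor_homo,
                            snp_id = NA_character_,
                            major_allele = NA_character_,
                            minor_allele = NA_character_) {
  cnt <- c(n_major_homo, n_het, n_minor_homo)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_data("genotype counts must be non-negative integers")
  }
  out <- list(n_major_homo = as.integer(n_major_homo),
              n_het = as.integer(n_het),
              n_minor_homo = as.integer(n_minor_homo),
              snp_id = snp_id, major_allele = major_allele,
              minor_allele = minor_allele)
  class(out) <- "genotype_counts"
  out
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts", if (!is.na(x$snp_id)) paste0("(", x$snp_id, ")"),
      ":", x$n_major_homo, "/", x$n_het, "/", x$n_minor_homo,
      " (major hom / het / minor hom)\n")
  f <- allele_freqs(x)
  cat(sprintf("  alleles %s=%d (%.3f), %s=%d (%.3f)\n",
              x$major_allele %||% "major", f$count_major, f$p,
              x$minor_allele %||% "minor", f$count_minor, f$q))
  invisible(x)
}

#' Count genotypes in a cohort
#'
#' Tallies non-missing genotype calls for one SNP, optionally restricted to
#' one weight-category group. Allele conservation (allele counts equal twice
#' the genotype total) holds by construction.
#'
#' @param cohort a `cohort_table`.
#' @param snp_id SNP column to count.
#' @param group optional `"normal_weight"` or `"overweight_obese"` filter
#'   (requires derived `weight_category`).
#' @return A `"genotype_counts"` object.
#' @export
count_genotypes <- function(cohort, snp_id, group = NULL) {
  panel <- attr(cohort, "snp_panel")
  if (!snp_id %in% names(cohort)) stop_config("SNP '", snp_id, "' not in cohort")
  g <- cohort[[snp_id]]
  if (!is.null(group)) {
    if (!"weight_category" %in% names(cohort)) {
      stop_config("cohort has no weight_category; run derive_anthro() first")
    }
    g <- g[!is.na(cohort$weight_category) & cohort$weight_category == group]
  }
  g <- g[!is.na(g)]
  if (!length(g)) stop_data("zero non-missing calls for SNP ", snp_id,
                            if (!is.null(group)) paste0(" in group ", group))
  al <- c(substr(g, 1, 1), substr(g, 3, 3))
  pr <- if (!is.null(panel)) panel[panel$snp_id == snp_id, ] else NULL
  if (!is.null(pr) && nrow(pr) == 1 && !is.na(pr$major_allele) &&
      !is.na(pr$minor_allele)) {
    major <- pr$major_allele; minor <- pr$minor_allele
  } else {
    tab <- sort(table(al), decreasing = TRUE)
    syms <- names(tab)
    if (length(syms) == 1) syms <- c(syms, NA_character_)
    # frequency orientation; lexicographic tie-break
    if (length(tab) == 2 && tab[1] == tab[2]) syms <- sort(syms)
    major <- syms[1]; minor <- syms[2]
  }
  hom_major <- paste(major, major, sep = "/")
  hom_minor <- if (!is.na(minor)) paste(minor, minor, sep = "/") else ""
  het <- if (!is.na(minor)) .norm_call(major, minor) else ""
  genotype_counts(sum(g == hom_major), sum(g == het), sum(g == hom_minor),
                  snp_id = snp_id, major_allele = major, minor_allele = minor)
}

#' Allele counts and frequencies from genotype counts
#'
#' @param counts a `"genotype_counts"` object.
#' @return list with `count_major`, `count_minor`, `p` (major-allele
#'   frequency) and `q = 1 - p`.
#' @export
allele_freqs <- function(counts) {
  cm <- 2L * counts$n_major_homo + counts$n_het
  cn <- 2L * counts$n_minor_homo + counts$n_het
  tot <- cm + cn
  if (tot == 0) stop_data("no alleles to count")
  list(count_major = cm, count_minor = cn, p = cm / tot, q = cn / tot)
}

# Exact conditional HWE probabilities for all heterozygote counts compatible
# with the observed allele counts (fixed parity), via the standard
# log-probability recurrence P(h+2)/P(h) = 4*AA_h*aa_h / ((h+1)(h+2)) with
# AA_h = (nA - h)/2, aa_h = (na - h)/2. Numerically safe for the cohort
# sizes involved here (hundreds).
.hwe_exact_dist <- function(n_major, n_minor) {
  parity <- n_minor %% 2L
  hets <- seq.int(parity, min(n_major, n_minor), by = 2L)
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1L]
    aa_h <- (n_major - h) / 2
    bb_h <- (n_minor - h) / 2
    logp[i] <- logp[i - 1L] + log(4 * aa_h * bb_h) - log((h + 1) * (h + 2))
  }
  p <- exp(logp - max(logp))
  list(hets = hets, prob = p / sum(p))
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts against Hardy-Weinberg proportions two
#' ways, reported side by side: the Pearson chi-square against expected
#' counts `(p^2, 2pq, q^2) * n` with 1 degree of freedom and no continuity
#' correction, and the exact conditional test (the probability, given the
#' allele counts, of all heterozygote configurations no more probable than
#' the one observed). A monomorphic sample is in equilibrium by convention
#' (`p_exact = 1`).
#'
#' @param counts a `"genotype_counts"` object (or three counts via
#'   [genotype_counts()]).
#' @return An object of class `"hwe_result"` with `chi2`, `df = 1`,
#'   `p_chisq`, `p_exact`.
#' @examples
#' hwe_test(genotype_counts(115, 165, 105))
#' @export
hwe_test <- function(counts) {
  n <- counts$n_major_homo + counts$n_het + counts$n_minor_homo
  if (n < 1) stop_data("need at least one genotyped sample")
  f <- allele_freqs(counts)
  obs <- c(counts$n_major_homo, counts$n_het, counts$n_minor_homo)
  if (f$count_minor == 0L || f$count_major == 0L) {
    out <- list(chi2 = 0, df = 1L, p_chisq = 1, p_exact = 1,
                snp_id = counts$snp_id)
    class(out) <- "hwe_result"
    return(out)
  }
  expc <- n * c(f$p^2, 2 * f$p * f$q, f$q^2)
  chi2 <- sum((obs - expc)^2 / expc)
  p_chisq <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  dist <- .hwe_exact_dist(f$count_major, f$count_minor)
  p_obs <- dist$prob[dist$hets == counts$n_het]
  p_exact <- sum(dist$prob[dist$prob <= p_obs * (1 + 1e-12)])
  out <- list(chi2 = chi2, df = 1L, p_chisq = p_chisq,
              p_exact = min(1, p_exact), snp_id = counts$snp_id)
  class(out) <- "hwe_result"
  out
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("Hardy-Weinberg test",
      if (!is.na(x$snp_id %||% NA)) paste0("(", x$snp_id, ")"), "\n")
  cat(sprintf("  exact p = %.4g; chi2 = %.3f (df = 1), p = %.4g\n",
              x$p_exact, x$chi2, x$p_chisq))
  invisible(x)
}

#' Case-control association test
#'
#' Pearson chi-square (no continuity correction) on the case-vs-control
#' contingency table of allele counts (2x2) or genotype counts (2x3).
#' Genotype columns with zero total across both groups are dropped with the
#' degrees of freedom reduced accordingly; if fewer than two non-empty
#' columns remain the result is flagged not-computable rather than erroring.
#'
#' @param case,control `"genotype_counts"` for the two groups; in allele
#'   mode a bare numeric `c(count_major, count_minor)` is also accepted,
#'   for published tables that print allele counts directly.
#' @param mode `"allele"` or `"genotype"`.
#' @return An object of class `"case_control_result"` with `chi2`, `df`,
#'   `p`, `mode`, `computable`.
#' @export
case_control_test <- function(case, control, mode = c("allele", "genotype")) {
  mode <- match.arg(mode)
  acounts <- function(x) {
    if (is.numeric(x) && length(x) == 2) return(unname(x))
    f <- allele_freqs(x)
    c(f$count_major, f$count_minor)
  }
  tab <- if (mode == "allele") {
    rbind(case = acounts(case), control = acounts(control))
  } else {
    rbind(case = c(case$n_major_homo, case$n_het, case$n_minor_homo),
          control = c(control$n_major_homo, control$n_het,
                      control$n_minor_homo))
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
    out <- list(mode = mode, chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                computable = FALSE, table = tab)
    class(out) <- "case_control_result"
    return(out)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- list(mode = mode, chi2 = unname(ct$statistic),
              df = unname(ct$parameter), p = ct$p.value,
              computable = TRUE, table = tab)
  class(out) <- "case_control_result"
  out
}

#' @export
print.case_control_result <- function(x, ...) {
  if (!x$computable) {
    cat("Case-control test (", x$mode, "): not computable (degenerate table)\n")
  } else {
    cat(sprintf("Case-control test (%s): chi2 = %.3f (df = %d), p = %.4g\n",
                x$mode, x$chi2, x$df, x$p))
  }
  invisible(x)
}

#' Phenotype contrasts of each genotype against the wild-type homozygote
#'
#' For the heterozygote and the minor homozygote, computes the difference in
#' phenotype means against the major (wild-type) homozygote with a Welch 95%
#' confidence interval, and a rank-based pairwise p (Dunn's z over the three
#' genotype groups) Bonferroni-adjusted across the per-SNP comparisons.
#' A comparison group with fewer than two non-missing values is marked
#' not-computable.
#'
#' @param cohort a `cohort_table` with derived anthropometrics.
#' @param snp_id SNP column name.
#' @param phenotype phenotype column name.
#' @param group optional weight-category filter.
#' @param conf_level confidence level for the Welch interval.
#' @return data frame with one row per non-reference genotype: `genotype`,
#'   `n`, `difference`, `ci_low`, `ci_high`, `p_adj`, `computable`.
#' @export
genotype_contrasts <- function(cohort, snp_id, phenotype, group = NULL,
                               conf_level = 0.95) {
  cnt <- count_genotypes(cohort, snp_id, group)
  if (is.na(cnt$minor_allele)) {
    stop_data("SNP ", snp_id, " is monomorphic; no contrasts to compute")
  }
  dat <- cohort
  if (!is.null(group)) {
    dat <- dat[!is.na(dat$weight_category) & dat$weight_category == group, ]
  }
  g <- dat[[snp_id]]; y <- dat[[phenotype]]
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  ref <- paste(cnt$major_allele, cnt$major_allele, sep = "/")
  others <- c(het = .norm_call(cnt$major_allele, cnt$minor_allele),
              minor_homo = paste(cnt$minor_allele, cnt$minor_allele, sep = "/"))
  if (sum(g == ref) < 2) {
    stop_data("wild-type homozygote group has fewer than 2 observations")
  }
  dunn <- dunn_pairwise(y, g, adjust_m = length(others))
  rows <- lapply(others, function(gt) {
    yi <- y[g == gt]; yr <- y[g == ref]
    if (length(yi) < 2) {
      return(data.frame(genotype = gt, n = length(yi), difference = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_adj = NA_real_, computable = FALSE))
    }
    if (stats::sd(yi) == 0 && stats::sd(yr) == 0) {
      d <- mean(yi) - mean(yr)
      ci <- c(d, d)
    } else {
      tt <- stats::t.test(yi, yr, conf.level = conf_level)
      d <- unname(tt$estimate[1] - tt$estimate[2])
      ci <- unname(tt$conf.int)
    }
    hit <- (dunn$group1 == gt & dunn$group2 == ref) |
           (dunn$group1 == ref & dunn$group2 == gt)
    data.frame(genotype = gt, n = length(yi), difference = d,
               ci_low = ci[1], ci_high = ci[2],
               p_adj = if (any(hit)) dunn$p_adj[hit][1] else NA_real_,
               computable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$phenotype <- phenotype
  out$snp_id <- snp_id
  out
}

# Compact letter display: groups not significantly different share a letter.
# Letters are the maximal cliques of the "not significantly different" graph
# (brute-force over subsets; genotype classes are at most 3).
.letter_display <- function(groups, pairs_sig) {
  k <- length(groups)
  if (k == 1) return(stats::setNames("a", groups))
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs_sig))) {
    if (pairs_sig$significant[i]) {
      nsd[pairs_sig$group1[i], pairs_sig$group2[i]] <- FALSE
      nsd[pairs_sig$group2[i], pairs_sig$group1[i]] <- FALSE
    }
  }
  subsets <- lapply(seq_len(2^k - 1), function(m) groups[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  is_clique <- vapply(subsets, function(s) all(nsd[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques[-i], function(o) all(cliques[[i]] %in% o), logical(1)))
  }, logical(1))]
  maximal <- maximal[order(vapply(maximal, function(s) min(match(s, groups)), numeric(1)))]
  lab <- stats::setNames(rep("", k), groups)
  for (i in seq_along(maximal)) {
    for (gp in maximal[[i]]) lab[gp] <- paste0(lab[gp], letters[i])
  }
  lab
}

#' Genotype-stratified phenotype table
#'
#' For one SNP, per genotype within each stratum (weight category by
#' default): n, mean and SD of each variable, a three-way rank test
#' (Kruskal-Wallis) and Dunn-Bonferroni pairwise letters. Genotype classes
#' with fewer than two observations for a variable are excluded from the
#' comparisons but their summary is still printed (letter `"-"`).
#'
#' @param cohort a `cohort_table` with derived anthropometrics.
#' @param snp_id SNP column name.
#' @param variables numeric columns to summarise.
#' @param stratifier stratum column, default `"weight_category"`.
#' @param alpha significance level for the pairwise letters.
#' @return data frame: one row per stratum x genotype x variable with `n`,
#'   `mean`, `sd`, `letters`, `kw_p` (Kruskal-Wallis p across genotypes).
#' @export
genotype_stratified_table <- function(cohort, snp_id, variables,
                                      stratifier = "weight_category",
                                      alpha = 0.05) {
  cnt <- count_genotypes(cohort, snp_id)
  gts <- paste(cnt$major_allele, cnt$major_allele, sep = "/")
  if (!is.na(cnt$minor_allele)) {
    gts <- c(gts, .norm_call(cnt$major_allele, cnt$minor_allele),
             paste(cnt$minor_allele, cnt$minor_allele, sep = "/"))
  }
  strata <- sort(unique(cohort[[stratifier]][!is.na(cohort[[stratifier]])]))
  rows <- list()
  for (s in strata) {
    dat <- cohort[!is.na(cohort[[stratifier]]) & cohort[[stratifier]] == s, ]
    for (v in variables) {
      y <- dat[[v]]; g <- dat[[snp_id]]
      ok <- !is.na(y) & !is.na(g)
      y <- y[ok]; g <- g[ok]
      n_g <- vapply(gts, function(gt) sum(g == gt), integer(1))
      usable <- gts[n_g >= 2]
      kw_p <- NA_real_
      letts <- stats::setNames(rep("-", length(gts)), gts)
      if (length(usable) >= 2) {
        keep <- g %in% usable
        kw_p <- stats::kruskal.test(y[keep], factor(g[keep]))$p.value
        dn <- dunn_pairwise(y[keep], g[keep])
        dn$significant <- !is.na(dn$p_adj) & dn$p_adj < alpha
        letts[usable] <- .letter_display(usable, dn)
      } else if (length(usable) == 1) {
        letts[usable] <- "a"
      }
      for (gt in gts) {
        yi <- y[g == gt]
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, genotype = gt, variable = v, n = length(yi),
          mean = if (length(yi)) mean(yi) else NA_real_,
          sd = if (length(yi) > 1) stats::sd(yi) else NA_real_,
          letters = letts[[gt]], kw_p = kw_p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "snp_id") <- snp_id
  out
}
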