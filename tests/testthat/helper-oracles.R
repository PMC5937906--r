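# Independent oracles used to cross-check the package's implementations.

# Exact conditional HWE p by direct evaluation of each configuration's
# log-probability from factorials (independent of the package's recurrence).
hwe_exact_oracle <- function(n_major_homo, n_het, n_minor_homo) {
  n <- n_major_homo + n_het + n_minor_homo
  nA <- 2 * n_major_homo + n_het
  na <- 2 * n_minor_homo + n_het
  hets <- seq(na %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    AA <- (nA - h) / 2; aa <- (na - h) / 2
    lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n) +
      lfactorial(n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Closed-form 2x2 Pearson chi-square: N (ad - bc)^2 / (r1 r2 c1 c2).
chi2_2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  N <- sum(tab)
  N * (a * d - b * c2)^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
}

# Build a cohort_table directly from per-genotype counts of one SNP, with a
# constant phenotype unless per-class values are supplied.
cohort_from_counts <- function(n_major_homo, n_het, n_minor_homo,
                               major = "A", minor = "G",
                               snp_id = "rs_test", values = NULL) {
  g <- c(rep(paste(major, major, sep = "/"), n_major_homo),
         rep(paste(min(major, minor), max(major, minor), sep = "/"), n_het),
         rep(paste(minor, minor, sep = "/"), n_minor_homo))
  n <- length(g)
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age_days = 3600, weight = 32, height = 138,
    stringsAsFactors = FALSE)
  out[[snp_id]] <- g
  if (!is.null(values)) out$y <- values
  attr(out, "snp_panel") <- snp_panel(snp_id, "GENE", major, minor)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Simulate genotype counts of n individuals under exact HWE at minor-allele
# frequency q (multinomial), as a genotype_counts object.
random_hwe_counts <- function(n, q) {
  p <- 1 - q
  x <- stats::rmultinom(1, n, c(p^2, 2 * p * q, q^2))
  genotype_counts(x[1], x[2], x[3])
}
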