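# Seeded synthetic-cohort generator: Hardy-Weinberg genotypes, a
# single-locus genotype -> phenotype model with planted additive and
# dominance effects, and ancillary anthropometry/biochemistry so that every
# downstream stage has realistic inputs. All randomness flows from one seed.

#' Simulation parameters
#'
#' Bundles the knobs of the synthetic cohort generator. Defaults emulate a
#' prepubertal school cohort: 773 children (381 boys, 392 girls) around age
#' 9.8 years, latent zBMI Normal(0.65, 1.11), and five biallelic SNPs in
#' Hardy-Weinberg equilibrium at minor-allele frequencies 0.47, 0.46, 0.01,
#' 0.21 and 0.09, with per-SNP call rates matching a partially genotyped
#' panel. Planted per-SNP additive/dominance effects act on the latent zBMI.
#'
#' @param n cohort size.
#' @param n_male number of boys (the rest are girls).
#' @param snps data frame with columns `snp_id`, `gene`, `major_allele`,
#'   `minor_allele`, `maf` (in (0, 0.5]), `a`, `d` (planted additive and
#'   dominance effects, zBMI units) and `call_rate` (fraction genotyped).
#' @param zbmi_mean,zbmi_sd latent zBMI distribution.
#' @param noise_sd extra phenotype noise SD on the latent zBMI.
#' @param missing_rate independent missingness rate applied to optional
#'   phenotype fields, in [0, 1).
#' @param case_z latent-z threshold used to place the overweight cutoff.
#'   Defaults to the 70th percentile of the full generative latent
#'   distribution (baseline plus the planted genotype effects' mean shift
#'   and variance plus noise, Gaussian approximation), giving a ~30% case
#'   fraction by construction.
#' @param seed integer seed; mandatory so cohorts are reproducible.
#' @return list of class `"simulation_params"`.
#' @export
simulation_params <- function(n = 773, n_male = 381,
                              snps = default_snp_specs(),
                              zbmi_mean = 0.65, zbmi_sd = 1.11,
                              noise_sd = 0.25, missing_rate = 0.15,
                              case_z = NULL, seed) {
  if (missing(seed)) stop_config("a seed is mandatory for reproducibility")
  stopifnot(n >= 1, n_male <= n, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  if (any(snps$maf <= 0 | snps$maf > 0.5)) {
    stop_config("minor-allele frequencies must lie in (0, 0.5]")
  }
  if (is.null(case_z)) {
    gm <- .genotype_effect_moments(snps)
    case_z <- (zbmi_mean + gm$mean) +
      sqrt(zbmi_sd^2 + noise_sd^2 + gm$var) * stats::qnorm(0.70)
  }
  out <- list(n = as.integer(n), n_male = as.integer(n_male), snps = snps,
              zbmi_mean = zbmi_mean, zbmi_sd = zbmi_sd, noise_sd = noise_sd,
              missing_rate = missing_rate, case_z = case_z,
              seed = as.integer(seed))
  class(out) <- "simulation_params"
  out
}

#' Default SNP specifications for the synthetic cohort
#'
#' Five biallelic loci mirroring a typical obesity candidate-gene panel:
#' minor-allele frequencies 0.47, 0.46, 0.01, 0.21, 0.09 and per-SNP call
#' rates 617/773, 530/773, 437/773, 352/773 and 272/773. The 0.01-frequency
#' locus intentionally produces zero minor homozygotes in most cohorts of
#' this size, exercising the degenerate-class code paths. Planted effects
#' are modest zBMI shifts.
#'
#' @return data frame of SNP specifications.
#' @export
default_snp_specs <- function() {
  data.frame(
    snp_id = c("rs1137101", "rs9939609", "rs2229616", "rs17782313",
               "rs1801282"),
    gene = c("LEPR", "FTO", "MC4R", "MC4R", "PPARG"),
    major_allele = c("A", "T", "G", "T", "C"),
    minor_allele = c("G", "A", "A", "C", "G"),
    maf = c(0.47, 0.46, 0.01, 0.21, 0.09),
    a = c(-0.15, 0.06, 0.00, 0.17, -0.10),
    d = c(0.28, -0.07, 0.00, -0.16, 0.10),
    call_rate = c(617, 530, 437, 352, 272) / 773,
    stringsAsFactors = FALSE
  )
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws `n` independent genotypes at a biallelic locus with genotype
#' probabilities `(p^2, 2pq, q^2)`, `p = 1 - maf`.
#'
#' @param n number of individuals.
#' @param maf minor-allele frequency in [0, 0.5].
#' @param seed optional seed (set once before drawing); omit to use the
#'   current RNG stream.
#' @return integer vector of minor-allele dosages (0, 1, 2).
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (maf < 0 || maf > 0.5) stop_config("maf must lie in [0, 0.5]")
  p <- 1 - maf
  sample.int(3, n, replace = TRUE,
             prob = c(p^2, 2 * p * maf, maf^2)) - 1L
}

# mean and variance of the summed planted genotype effects under HWE:
# per SNP the effect takes -a, d, a with probabilities (p^2, 2pq, q^2).
.genotype_effect_moments <- function(snps) {
  m <- 0; v <- 0
  for (j in seq_len(nrow(snps))) {
    q <- snps$maf[j]; p <- 1 - q
    pr <- c(p^2, 2 * p * q, q^2)
    x <- c(-snps$a[j], snps$d[j], snps$a[j])
    mj <- sum(pr * x)
    m <- m + mj
    v <- v + sum(pr * x^2) - mj^2
  }
  list(mean = m, var = v)
}

# toy LMS reference: Box-Cox power -1.6, coefficient of variation 0.11,
# median BMI rising gently with age; girls 0.2 units above boys.
toy_lms_table <- function() {
  ages <- seq(90, 150, by = 5)
  do.call(rbind, lapply(c("male", "female"), function(sx) {
    data.frame(sex = sx, age_months = ages, L = -1.6,
               M = 15.8 + 0.045 * (ages - 100) + if (sx == "female") 0.2 else 0,
               S = 0.11, stringsAsFactors = FALSE)
  }))
}

# IOTF-style cutoffs consistent with the toy LMS: the overweight cutoff is
# the BMI at latent z = case_z, the obese cutoff at z = case_z + 0.8.
toy_iotf_table <- function(case_z) {
  ages_y <- seq(7.5, 12.5, by = 0.5)
  lms <- toy_lms_table()
  do.call(rbind, lapply(c("male", "female"), function(sx) {
    row <- .interp_rows(lms, sx, ages_y * 12, "age_months")
    data.frame(sex = sx, age_years = ages_y,
               bmi_overweight = lms_inverse(case_z, row$L, row$M, row$S),
               bmi_obese = lms_inverse(case_z + 0.8, row$L, row$M, row$S),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate phenotypes conditional on genotypes
#'
#' Implements the single-locus model the Falconer decomposition assumes:
#' the latent zBMI of an individual is the baseline draw plus, for each SNP,
#' the planted genotype effect (`-a` for the major homozygote, `+d` for the
#' heterozygote, `+a` for the minor homozygote) plus Gaussian noise.
#' Anthropometry is built backwards from the latent z through the toy LMS
#' reference (BMI, then weight from height), and ancillary circumference
#' and biochemistry variables are generated from documented correlated
#' normals so the descriptive-table code has full inputs; no physiological
#' realism is claimed for them. Missingness is applied independently at
#' `missing_rate` to the optional fields.
#'
#' @param genotypes matrix of minor-allele dosages (`n` rows, one column per
#'   SNP in `params$snps` order).
#' @param params a [simulation_params()] object.
#' @return data frame of phenotype records (one per child) with attribute
#'   `"latent_z"`.
#' @export
simulate_phenotypes <- function(genotypes, params) {
  n <- params$n
  sex <- c(rep("male", params$n_male), rep("female", n - params$n_male))
  age_days <- round(stats::runif(n, 9.0 * 365.25, 10.6 * 365.25))
  z <- stats::rnorm(n, params$zbmi_mean, params$zbmi_sd)
  for (j in seq_len(nrow(params$snps))) {
    eff <- c(-params$snps$a[j], params$snps$d[j], params$snps$a[j])
    z <- z + eff[genotypes[, j] + 1L]
  }
  z <- z + stats::rnorm(n, 0, params$noise_sd)
  z <- pmin(pmax(z, -4), 4)   # keep the Box-Cox transform in range
  lms <- toy_lms_table()
  row <- lms_lookup(sex, age_days, lms)
  bmi <- lms_inverse(z, row$L, row$M, row$S)
  height <- stats::rnorm(n, ifelse(sex == "male", 138.7, 137.7),
                         ifelse(sex == "male", 6.8, 7.4))
  height <- pmax(height, 110)
  weight <- bmi * (height / 100)^2
  zdev <- (z - params$zbmi_mean) / params$zbmi_sd
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)), sex = sex,
    age_days = age_days, weight = round(weight, 2),
    height = round(height, 1), stringsAsFactors = FALSE)
  # ancillary variables: linear in the standardized latent z plus noise
  out$waist <- round(0.43 * height + 3.2 + 6.5 * zdev + stats::rnorm(n, 0, 3), 1)
  out$hip <- round(0.46 * height + 4.5 + 5.5 * zdev + stats::rnorm(n, 0, 3), 1)
  out$mid_upper_arm <- round(21.3 + 2.2 * zdev + stats::rnorm(n, 0, 1.4), 1)
  out$calf <- round(29.3 + 2.4 * zdev + stats::rnorm(n, 0, 1.6), 1)
  out$body_fat_pct <- round(pmax(21.9 + 6.0 * zdev + stats::rnorm(n, 0, 3.5), 5), 2)
  out$skeletal_muscle_pct <- round(31.9 - 0.5 * zdev + stats::rnorm(n, 0, 2.6), 2)
  out$rmr <- round(1209 + 60 * zdev + stats::rnorm(n, 0, 80))
  out$glucose <- round(78.5 + 1.0 * zdev + stats::rnorm(n, 0, 10.2), 1)
  out$insulin <- round(pmax(exp(stats::rnorm(n, log(5.3), 0.55) + 0.35 * zdev),
                            0.5), 2)
  out$leptin <- round(pmax(exp(stats::rnorm(n, log(6.5), 0.8) + 0.7 * zdev),
                           0.2), 2)
  out$tc <- round(170.1 + 1.0 * zdev + stats::rnorm(n, 0, 30.5), 1)
  out$hdl <- round(55.5 - 2.5 * zdev + stats::rnorm(n, 0, 10.5), 1)
  out$ldl <- round(90.1 + 3.0 * zdev + stats::rnorm(n, 0, 23.5), 1)
  out$tg <- round(pmax(61.2 + 8.0 * zdev + stats::rnorm(n, 0, 24), 15), 1)
  out$apo_a1 <- round(1.35 - 0.03 * zdev + stats::rnorm(n, 0, 0.17), 2)
  out$apo_b <- round(0.73 + 0.03 * zdev + stats::rnorm(n, 0, 0.17), 2)
  out$creatinine <- round(stats::rnorm(n, 0.60, 0.10), 2)
  out$total_protein <- round(stats::rnorm(n, 7.43, 0.75), 2)
  out$ferritin <- round(pmax(stats::rnorm(n, 37.9, 21), 2), 1)
  if (params$missing_rate > 0) {
    for (col in setdiff(names(out), c("sample_id", "sex", "age_days",
                                      "weight", "height"))) {
      drop <- stats::runif(n) < params$missing_rate
      out[[col]][drop] <- NA
    }
  }
  attr(out, "latent_z") <- z
  out
}

#' Simulate a complete cohort
#'
#' Runs the full generator under one seed: Hardy-Weinberg genotypes for
#' every SNP in the panel, phenotypes from the planted single-locus model,
#' per-SNP call-rate thinning, the join into a `cohort_table`, and the toy
#' LMS/IOTF reference tables.
#'
#' @param params a [simulation_params()] object.
#' @return list with `cohort` (a derived `cohort_table`), `phenotypes`,
#'   `calls`, `panel`, `lms`, `iotf` and `params`.
#' @export
simulate_cohort <- function(params) {
  set.seed(params$seed)
  n <- params$n
  geno <- vapply(seq_len(nrow(params$snps)),
                 function(j) simulate_genotypes(n, params$snps$maf[j]),
                 integer(n))
  phen <- simulate_phenotypes(geno, params)
  panel <- snp_panel(params$snps$snp_id, params$snps$gene,
                     params$snps$major_allele, params$snps$minor_allele)
  calls <- do.call(rbind, lapply(seq_len(nrow(params$snps)), function(j) {
    called <- stats::runif(n) <= params$snps$call_rate[j]
    dose <- geno[called, j]
    M <- params$snps$major_allele[j]; m <- params$snps$minor_allele[j]
    a1 <- ifelse(dose == 2L, m, M)
    a2 <- ifelse(dose >= 1L, m, M)
    data.frame(sample_id = phen$sample_id[called],
               snp_id = params$snps$snp_id[j],
               allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
               stringsAsFactors = FALSE)
  }))
  lms <- toy_lms_table()
  iotf <- toy_iotf_table(params$case_z)
  cohort <- join_cohort(phen, calls, panel, policy = "strict")
  cohort <- derive_anthro(cohort, lms, iotf)
  list(cohort = cohort, phenotypes = phen, calls = calls, panel = panel,
       lms = lms, iotf = iotf, params = params)
}

#' Study-scale synthetic fixture
#'
#' A seeded cohort with the headline structure of a prepubertal candidate-SNP
#' study: n = 773 (381 boys / 392 girls), five SNPs at minor-allele
#' frequencies 0.47, 0.46, 0.01, 0.21, 0.09, partially genotyped, and a
#' case fraction of about 0.30 by construction of the toy IOTF cutoffs.
#' When `dir` is given, the standard input files are also written
#' (phenotypes CSV, wide genotype TSV, VCF, LMS and IOTF CSVs, plus a JSON
#' manifest of seed and parameters), so end-to-end file-based runs can be
#' exercised.
#'
#' @param seed integer seed (default 20090101 %% 1e6).
#' @param dir optional directory to write input files into.
#' @return the [simulate_cohort()] list, plus `files` when `dir` is given.
#' @export
make_study_fixture <- function(seed = 90101, dir = NULL) {
  params <- simulation_params(seed = seed)
  sim <- simulate_cohort(params)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    f <- list(
      phenotypes = file.path(dir, "phenotypes.csv"),
      genotypes = file.path(dir, "genotypes.tsv"),
      vcf = file.path(dir, "genotypes.vcf"),
      lms = file.path(dir, "lms_reference.csv"),
      iotf = file.path(dir, "iotf_cutoffs.csv"),
      manifest = file.path(dir, "manifest.json")
    )
    write_phenotypes(sim$phenotypes, f$phenotypes)
    wide <- data.frame(sample_id = sim$phenotypes$sample_id,
                       stringsAsFactors = FALSE)
    for (s in sim$panel$snp_id) {
      sub <- sim$calls[sim$calls$snp_id == s, ]
      g <- .norm_call(sub$allele1, sub$allele2)
      wide[[s]] <- g[match(wide$sample_id, sub$sample_id)]
    }
    utils::write.table(wide, f$genotypes, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
    .write_fixture_vcf(wide, sim$panel, f$vcf)
    utils::write.table(sim$lms, f$lms, sep = ",", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(sim$iotf, f$iotf, sep = ",", row.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(
      list(seed = params$seed, n = params$n, n_male = params$n_male,
           snps = params$snps, zbmi_mean = params$zbmi_mean,
           zbmi_sd = params$zbmi_sd, noise_sd = params$noise_sd,
           missing_rate = params$missing_rate, case_z = params$case_z),
      f$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sim$files <- f
  }
  sim
}

.write_fixture_vcf <- function(wide, panel, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", wide$sample_id), collapse = "\t")),
             con)
  for (i in seq_len(nrow(panel))) {
    s <- panel$snp_id[i]
    M <- panel$major_allele[i]; m <- panel$minor_allele[i]
    g <- wide[[s]]
    gt <- ifelse(is.na(g), "./.",
          ifelse(g == paste(M, M, sep = "/"), "0/0",
          ifelse(g == paste(m, m, sep = "/"), "1/1", "0/1")))
    writeLines(paste(c("1", as.character(1000 + i), s, M, m, ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
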