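# The Falconer decomposition kernel, its classifications, and the model fit.

test_that("stratum pooling is the exact n-weighted mean", {
  p <- pool_stratum_means(c(76, 107), c(2.11, 0.15))
  expect_equal(p$n, 183)
  expect_equal(round(p$mean, 4), 0.9640)
  expect_equal(pool_stratum_means(5, 1.7)$mean, 1.7)
  expect_equal(pool_stratum_means(c(3, 97), c(2.5, 2.5))$mean, 2.5)
  expect_error(pool_stratum_means(integer(), numeric()),
               class = "falconer_data_error")
})

test_that("decomposition reproduces published reference effects at 2 dp", {
  # leptin-receptor locus: pooled zBMI genotype means and allele counts
  lepr <- falconer_decompose(c(0.9640, 1.0933, 0.6614),
                             c(p = 653 / 1234, q = 581 / 1234))
  expect_equal(round(lepr$additive, 2), -0.15)
  expect_equal(round(lepr$dominance, 2), 0.28)
  expect_equal(round(lepr$population_mean, 2), 0.81)
  expect_identical(lepr$dominance_type, "overdominance")

  # melanocortin-4-receptor locus
  mc4r <- falconer_decompose(c(1.4600, 1.4663, 1.7926),
                             c(p = 554 / 704, q = 150 / 704))
  expect_equal(round(mc4r$additive, 2), 0.17)
  expect_equal(round(mc4r$dominance, 2), -0.16)
  expect_equal(round(mc4r$population_mean, 2), 1.63)
  expect_equal(round(mc4r$minor_avg_effect, 2), 0.06)
  expect_identical(mc4r$dominance_type, "complete_dominance")
})

test_that("additive and overdominant toys decompose as constructed", {
  add <- falconer_decompose(c(-1, 0, 1), c(p = 0.7, q = 0.3))
  expect_equal(add$midpoint, 0)
  expect_equal(add$additive, 1)
  expect_equal(add$dominance, 0)
  expect_equal(add$alpha, 1)   # alpha = a when d = 0, any frequency
  od <- falconer_decompose(c(0, 1, 0), c(p = 0.5, q = 0.5))
  expect_equal(od$additive, 0)
  expect_equal(od$dominance, 1)
  expect_identical(od$dominance_type, "overdominance")
})

test_that("alpha equals a for all frequencies in the additive limit", {
  for (q in c(0.05, 0.2, 0.5)) {
    fe <- falconer_decompose(c(2, 3, 4), c(p = 1 - q, q = q))
    expect_equal(fe$alpha, fe$additive)
  }
})

test_that("dominance classification follows the |d/a| ratio bands", {
  expect_identical(classify_dominance(-0.15, 0.28), "overdominance")
  expect_identical(classify_dominance(0.17, -0.16), "complete_dominance")
  expect_identical(classify_dominance(1, 0), "no_dominance")
  expect_identical(classify_dominance(1, 0.5), "partial_dominance")
  expect_identical(classify_dominance(0, 0.3), "overdominance")
  expect_identical(classify_dominance(-1.12, 0.68), "partial_dominance")
  deg <- classify_dominance(0, 0)
  expect_identical(as.character(deg), "no_dominance")
  expect_true(attr(deg, "degenerate"))
  # band edges at the default 0.25 tolerance
  expect_identical(classify_dominance(1, 0.75), "complete_dominance")
  expect_identical(classify_dominance(1, 1.25), "complete_dominance")
  expect_identical(classify_dominance(1, 1.26), "overdominance")
})

test_that("effect grading assigns boundaries upward with signed direction", {
  expect_identical(as.character(grade_effect_size(0.03)), "very weak increase")
  expect_identical(as.character(grade_effect_size(-0.09)), "weak decrease")
  expect_identical(as.character(grade_effect_size(0.05)), "weak increase")
  expect_identical(as.character(grade_effect_size(0.2)), "medium increase")
  expect_identical(as.character(grade_effect_size(-0.8)), "strong decrease")
  expect_identical(as.character(grade_effect_size(0)), "very weak")
})

test_that("decompose and reconstruct are inverse on random instances", {
  set.seed(43)
  for (i in 1:1000) {
    means <- rnorm(3, 18, 3)
    q <- runif(1, 0.01, 0.5)
    fe <- falconer_decompose(means, c(p = 1 - q, q = q))
    expect_equal(reconstruct_means(fe), means, tolerance = 1e-12)
  }
})

test_that("negating the phenotype negates effects and flips grade direction", {
  set.seed(47)
  for (i in 1:50) {
    means <- rnorm(3); q <- runif(1, 0.05, 0.5)
    f1 <- falconer_decompose(means, c(p = 1 - q, q = q))
    f2 <- falconer_decompose(-means, c(p = 1 - q, q = q))
    expect_equal(f2$additive, -f1$additive)
    expect_equal(f2$dominance, -f1$dominance)
    expect_equal(f2$alpha, -f1$alpha)
    expect_identical(f2$dominance_type, f1$dominance_type)
    d1 <- attr(grade_effect_size(f1$minor_avg_effect), "direction")
    d2 <- attr(grade_effect_size(f2$minor_avg_effect), "direction")
    if (f1$minor_avg_effect != 0) expect_false(d1 == d2)
  }
})

test_that("swapping major/minor labels negates a and alpha, preserving the means", {
  set.seed(53)
  for (i in 1:1000) {
    means <- rnorm(3, 1, 0.8)
    q <- runif(1, 0.01, 0.5)
    f1 <- falconer_decompose(means, c(p = 1 - q, q = q))
    f2 <- falconer_decompose(means[c(3, 2, 1)], c(p = q, q = 1 - q))
    expect_equal(f2$additive, -f1$additive, tolerance = 1e-12)
    expect_equal(f2$alpha, -f1$alpha, tolerance = 1e-12)
    expect_equal(f2$midpoint, f1$midpoint, tolerance = 1e-12)
    expect_equal(reconstruct_means(f2), means[c(3, 2, 1)], tolerance = 1e-12)
    expect_equal(f2$pop_mean_hw, f1$pop_mean_hw, tolerance = 1e-10)
  }
})

test_that("a missing genotype class yields a partial, flagged result", {
  fe <- falconer_decompose(c(1.2, NA, 1.8), c(p = 0.8, q = 0.2))
  expect_false(fe$computable)
  expect_equal(fe$midpoint, 1.5)
  expect_equal(fe$additive, 0.3)
  expect_true(is.na(fe$dominance))
  expect_true(is.na(fe$alpha))
  expect_error(
    falconer_decompose(c(1, 1.1, 1.2), c(p = 0.8, q = 0.2), n = c(10, 5, 0)),
    class = "falconer_data_error")
})

test_that("the model fit recovers planted effects on a large cohort", {
  snps <- data.frame(snp_id = "rs1", gene = "G", major_allele = "A",
                     minor_allele = "G", maf = 0.4, a = 0.30, d = 0.10,
                     call_rate = 1)
  sim <- simulate_cohort(simulation_params(n = 10000, n_male = 5000,
                                           snps = snps, seed = 59))
  fit <- falconer(zbmi ~ rs1, data = sim$cohort)
  expect_lt(abs(fit$additive - 0.30), 3 * fit$se_additive)
  expect_lt(abs(fit$dominance - 0.10), 3 * fit$se_dominance)
})

test_that("null cohorts rarely show spurious additive effects", {
  snps <- data.frame(snp_id = "rs1", gene = "G", major_allele = "A",
                     minor_allele = "G", maf = 0.4, a = 0, d = 0,
                     call_rate = 1)
  set.seed(61)
  ok <- replicate(100, {
    p <- simulation_params(n = 1000, n_male = 500, snps = snps,
                           seed = sample.int(1e6, 1))
    fit <- falconer(zbmi ~ rs1, data = simulate_cohort(p)$cohort)
    abs(fit$additive) < 3 * fit$se_additive
  })
  expect_gte(mean(ok), 0.95)
})

test_that("estimates tighten as the cohort grows", {
  snps <- data.frame(snp_id = "rs1", gene = "G", major_allele = "A",
                     minor_allele = "G", maf = 0.3, a = 0.25, d = 0.10,
                     call_rate = 1)
  err <- vapply(c(1e3, 1e4), function(n) {
    devs <- vapply(c(67, 68, 69), function(s) {
      fit <- falconer(zbmi ~ rs1, data = simulate_cohort(
        simulation_params(n = n, n_male = n / 2, snps = snps,
                          seed = s))$cohort)
      abs(fit$additive - 0.25)
    }, numeric(1))
    mean(devs)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("model methods are mutually consistent", {
  fix <- make_study_fixture(seed = 71)
  fit <- falconer(zbmi ~ rs1137101, data = fix$cohort)
  co <- coef(fit)
  expect_named(co, c("midpoint", "additive", "dominance", "alpha",
                     "minor_avg_effect", "pop_mean_hw"))
  # fitted + residuals reassemble the data
  expect_equal(fitted(fit) + residuals(fit), fit$model$y)
  # predictions are the class means
  expect_equal(unique(predict(fit)[fit$model$genotype == "A/G"]),
               unname(fit$mean_class[[2]]))
  # simulate is deterministic under a seed and preserves structure
  s1 <- simulate(fit, nsim = 2, seed = 99)
  s2 <- simulate(fit, nsim = 2, seed = 99)
  expect_identical(s1, s2)
  expect_equal(nrow(s1[[1]]), fit$n)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.falconer")
  expect_output(print(fit), "Falconer")
})

test_that("effects_table flags sparse minor-homozygote classes", {
  fix <- make_study_fixture(seed = 73)
  et <- effects_table(fix$cohort)
  expect_true(all(c("bmi", "zbmi") %in% et$phenotype))
  expect_true(all(et$flag_small_minor_homo[et$n_minor_homo < 5]))
  expect_false(any(et$flag_small_minor_homo[et$n_minor_homo >= 5]))
  # reconstruction holds on fitted decompositions too
  row <- et[et$snp_id == "rs1137101" & et$phenotype == "zbmi", ]
  fit <- falconer(zbmi ~ rs1137101, data = fix$cohort)
  expect_equal(row$additive_effect, fit$additive)
})
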