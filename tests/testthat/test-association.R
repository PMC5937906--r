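# Genotype counting, case-control association and genotype-stratified
# phenotype comparisons.

test_that("genotype counting reproduces allele bookkeeping and conservation", {
  co <- cohort_from_counts(190, 273, 154)
  cnt <- count_genotypes(co, "rs_test")
  f <- allele_freqs(cnt)
  expect_equal(c(f$count_major, f$count_minor), c(653, 581))
  expect_equal(round(c(f$p, f$q), 2), c(0.53, 0.47))
  # conservation: allele counts are twice the genotype total
  expect_equal(f$count_major + f$count_minor,
               2 * (cnt$n_major_homo + cnt$n_het + cnt$n_minor_homo))
})

test_that("declared orientation flip swaps the homozygote counts exactly", {
  co <- cohort_from_counts(190, 273, 154)
  attr(co, "snp_panel") <- snp_panel("rs_test", "GENE", "G", "A")
  cnt <- count_genotypes(co, "rs_test")
  expect_equal(cnt$n_major_homo, 154L)
  expect_equal(cnt$n_minor_homo, 190L)
  expect_equal(cnt$n_het, 273L)
})

test_that("undeclared orientation is inferred by frequency with lexicographic ties", {
  co <- cohort_from_counts(10, 0, 4)
  attr(co, "snp_panel") <- snp_panel("rs_test", "GENE", NA, NA)
  cnt <- count_genotypes(co, "rs_test")
  expect_equal(cnt$major_allele, "A")
  tie <- cohort_from_counts(5, 0, 5, major = "T", minor = "C")
  attr(tie, "snp_panel") <- snp_panel("rs_test", "GENE", NA, NA)
  cnt2 <- count_genotypes(tie, "rs_test")
  expect_equal(cnt2$major_allele, "C")  # tie broken alphabetically
})

test_that("counting an all-missing group errors", {
  co <- cohort_from_counts(3, 3, 3)
  co$rs_test <- NA_character_
  expect_error(count_genotypes(co, "rs_test"), class = "falconer_data_error")
})

test_that("allele-mode chi-square matches the 2x2 closed form and label swap", {
  case <- genotype_counts(52, 86, 33)
  ctrl <- genotype_counts(115, 165, 105)
  r <- case_control_test(case, ctrl, "allele")
  tab <- rbind(c(190, 152), c(395, 375))
  expect_equal(r$chi2, chi2_2x2_oracle(tab), tolerance = 1e-10)
  expect_equal(round(r$p, 3), 0.190)
  swapped <- case_control_test(ctrl, case, "allele")
  expect_equal(r$p, swapped$p)
  expect_equal(r$chi2, swapped$chi2)
})

test_that("identical case/control proportions give chi2 = 0 and p = 1", {
  a <- genotype_counts(40, 40, 20)
  b <- genotype_counts(80, 80, 40)
  r <- case_control_test(a, b, "allele")
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
})

test_that("genotype-mode test drops empty columns with reduced df", {
  case <- genotype_counts(120, 2, 0)
  ctrl <- genotype_counts(275, 7, 0)
  r <- case_control_test(case, ctrl, "genotype")
  expect_true(r$computable)
  expect_equal(r$df, 1L)       # minor-homozygote column dropped
  deg <- case_control_test(genotype_counts(10, 0, 0),
                           genotype_counts(20, 0, 0), "genotype")
  expect_false(deg$computable)
  expect_true(is.na(deg$p))
})

test_that("null case-control simulation is calibrated near the nominal level", {
  set.seed(29)
  rej <- replicate(400, {
    case_control_test(random_hwe_counts(300, 0.3),
                      random_hwe_counts(300, 0.3), "allele")$p < 0.05
  })
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.075)
})

test_that("contrast of a group against itself is exactly zero", {
  y <- rnorm(60)
  co <- cohort_from_counts(20, 20, 20, values = rep(y[1:20], 3))
  ct <- genotype_contrasts(co, "rs_test", "y")
  expect_equal(ct$difference, c(0, 0))
  expect_true(all(ct$ci_low <= ct$difference & ct$difference <= ct$ci_high))
})

test_that("planted genotype shift is estimated without bias", {
  set.seed(31)
  est <- replicate(500, {
    co <- cohort_from_counts(100, 100, 0,
                             values = c(rnorm(100, 0), rnorm(100, 1)))
    genotype_contrasts(co, "rs_test", "y")$difference[1]
  })
  expect_lt(abs(mean(est) - 1.0), 0.03)
})

test_that("contrast groups with fewer than two values are marked not computable", {
  co <- cohort_from_counts(10, 1, 0, values = c(rnorm(10), 5))
  ct <- genotype_contrasts(co, "rs_test", "y")
  expect_false(ct$computable[ct$genotype == "A/G"])
  expect_true(is.na(ct$difference[ct$genotype == "A/G"]))
})

test_that("stratified genotype table letters: identical distributions share one letter", {
  set.seed(37)
  y <- rnorm(20)
  co <- cohort_from_counts(20, 20, 20, values = rep(y, 3))
  co$weight_category <- "normal_weight"
  tab <- genotype_stratified_table(co, "rs_test", "y")
  expect_true(all(tab$letters == "a"))
})

test_that("a genotype with n = 1 keeps its mean but is excluded from letters", {
  co <- cohort_from_counts(10, 10, 1, values = c(rnorm(20), 3.3))
  co$weight_category <- "normal_weight"
  tab <- genotype_stratified_table(co, "rs_test", "y")
  row <- tab[tab$genotype == "G/G", ]
  expect_equal(row$mean, 3.3)
  expect_identical(row$letters, "-")
})

test_that("a planted one-sd minor-homozygote shift earns its own letter", {
  set.seed(41)
  hits <- replicate(200, {
    co <- cohort_from_counts(150, 150, 150,
                             values = c(rnorm(300), rnorm(150, 1)))
    co$weight_category <- "normal_weight"
    tab <- genotype_stratified_table(co, "rs_test", "y")
    mh <- tab$letters[tab$genotype == "G/G"]
    !grepl(strsplit(tab$letters[tab$genotype == "A/A"], "")[[1]][1], mh)
  })
  expect_gte(mean(hits), 0.80)
})
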