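# Readers, writers and the joined cohort data model.

write_lines <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("phenotype reader parses required fields and keeps missing distinct from zero", {
  f <- write_lines(c(
    "sample_id,sex,age_days,weight,height,ferritin,insulin",
    "S1,male,3600,32.5,138.2,37.1,0",
    "S2,female,3500,28.0,131.0,,5.2",
    "S3,male,3700,45.39,141.3,12.0,"
  ))
  ph <- read_phenotypes(f)
  expect_equal(nrow(ph), 3L)
  expect_true(is.na(ph$ferritin[2]))
  expect_false(is.na(ph$insulin[1]))
  expect_identical(ph$insulin[1], 0)          # a true zero survives
  expect_true(is.na(ph$insulin[3]))           # an empty cell does not become 0

  out <- tempfile(fileext = ".csv")
  write_phenotypes(ph, out)
  back <- read_phenotypes(out)
  expect_equal(back, ph, tolerance = 1e-12)
  expect_identical(is.na(back$ferritin), is.na(ph$ferritin))
})

test_that("age is computed by calendar-day subtraction of dates", {
  f <- write_lines(c(
    "sample_id,sex,birth_date,exam_date,weight,height",
    "S1,female,2000-01-01,2009-11-01,31.2,136.5"
  ))
  expect_equal(read_phenotypes(f)$age_days, 3592)
})

test_that("phenotype reader rejects bad inputs loudly", {
  f1 <- write_lines(c("sample_id,sex,age_days,weight",
                      "S1,male,3600,32"))
  expect_error(read_phenotypes(f1), "height", class = "falconer_config_error")
  f2 <- write_lines(c("sample_id,sex,age_days,weight,height",
                      "S1,male,3600,32,138", "S1,female,3500,30,131"))
  expect_error(read_phenotypes(f2), "duplicate", class = "falconer_data_error")
})

test_that("genotype calls are unordered allele pairs", {
  f <- write_lines(c("sample_id\trs1",
                     "S1\tAA", "S2\tAG", "S3\tGA", "S4\tGG"), ext = ".tsv")
  g <- read_genotypes(f)
  calls <- g$calls
  expect_identical(calls$allele1[calls$sample_id == "S2"],
                   calls$allele1[calls$sample_id == "S3"])
  expect_identical(calls$allele2[calls$sample_id == "S2"],
                   calls$allele2[calls$sample_id == "S3"])
})

test_that("wide genotype table missingness is counted per call", {
  set.seed(42)
  hdr <- paste(c("sample_id", paste0("rs", 1:5)), collapse = "\t")
  rows <- vapply(1:10, function(i) {
    paste(c(sprintf("S%02d", i), rep("A/G", 5)), collapse = "\t")
  }, character(1))
  # blank out 3 specific calls
  rows[2] <- sub("A/G", "NA", rows[2])
  rows[5] <- sub("A/G", "NA", rows[5])
  rows[9] <- sub("A/G", "NA", rows[9])
  g <- read_genotypes(write_lines(c(hdr, rows), ext = ".tsv"))
  expect_equal(sum(!is.na(g$calls$allele1)), 47L)
  expect_equal(nrow(g$calls), 50L)
})

test_that("VCF reader decodes GT against REF/ALT and rejects multiallelic rows", {
  v <- write_lines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs10\tT\tC\t.\tPASS\t.\tGT\t0/1\t1/1\t./."
  ), ext = ".vcf")
  g <- read_genotypes(v)
  s1 <- g$calls[g$calls$sample_id == "S1", ]
  expect_setequal(c(s1$allele1, s1$allele2), c("T", "C"))
  s2 <- g$calls[g$calls$sample_id == "S2", ]
  expect_identical(c(s2$allele1, s2$allele2), c("C", "C"))
  expect_true(is.na(g$calls$allele1[g$calls$sample_id == "S3"]))

  bad <- write_lines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs11\tT\tC,G\t.\tPASS\t.\tGT\t0/1"
  ), ext = ".vcf")
  expect_error(read_genotypes(bad), "biallelic",
               class = "falconer_data_error")
})

test_that("join respects policy and keeps per-SNP n at the call level", {
  phen <- data.frame(sample_id = paste0("S", 1:5),
                     sex = "male", age_days = 3600, weight = 32, height = 138,
                     stringsAsFactors = FALSE)
  calls <- data.frame(sample_id = paste0("S", 1:5), snp_id = "rs1",
                      allele1 = "A", allele2 = c("A", "G", "G", NA, "A"),
                      stringsAsFactors = FALSE)
  calls$allele1[4] <- NA
  co <- join_cohort(phen, calls, snp_panel("rs1", "G1", "A", "G"))
  expect_equal(nrow(co), 5L)
  expect_equal(sum(!is.na(co$rs1)), 4L)

  co2 <- join_cohort(phen, calls[calls$sample_id %in% paste0("S", 1:3), ],
                     snp_panel("rs1", "G1", "A", "G"), policy = "intersect")
  expect_equal(nrow(co2), 3L)

  expect_error(
    join_cohort(phen[0, ], calls, snp_panel("rs1", "G1", "A", "G")),
    class = "falconer_data_error")
  expect_error(
    join_cohort(phen, data.frame(sample_id = "S1", snp_id = "rs1",
                                 allele1 = "A", allele2 = "T"),
                snp_panel("rs1", "G1", "A", "G")),
    "outside declared pair", class = "falconer_data_error")
})

test_that("study-scale fixture keeps per-SNP analysis n below cohort size", {
  fix <- make_study_fixture(seed = 5)
  co <- fix$cohort
  n_per <- vapply(fix$panel$snp_id, function(s) sum(!is.na(co[[s]])),
                  integer(1))
  expect_equal(nrow(co), 773L)
  expect_true(all(n_per < 773L))
  # per-SNP analysis n equals non-missing calls, never the cohort size
  cnt <- count_genotypes(co, "rs1137101")
  expect_equal(cnt$n_major_homo + cnt$n_het + cnt$n_minor_homo,
               unname(n_per[["rs1137101"]]))
})

test_that("cohort write/read round-trips values and missingness", {
  fix <- make_study_fixture(seed = 8)
  co <- fix$cohort
  f <- tempfile(fileext = ".tsv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_identical(names(back), names(co))
  for (nm in names(co)) {
    if (is.numeric(co[[nm]])) {
      expect_equal(back[[nm]], co[[nm]], tolerance = 1e-12)
    } else {
      expect_identical(back[[nm]], co[[nm]])
    }
    expect_identical(is.na(back[[nm]]), is.na(co[[nm]]))
  }
  expect_identical(attr(back, "snp_panel")$minor_allele,
                   attr(co, "snp_panel")$minor_allele)
})

test_that("swapping the two allele symbols of every call changes no count", {
  fix <- make_study_fixture(seed = 9)
  co <- fix$cohort
  flip <- function(g) {
    a <- substr(g, 1, 1); b <- substr(g, 3, 3)
    paste(b, a, sep = "/")
  }
  co2 <- co
  for (s in fix$panel$snp_id) {
    g <- co2[[s]]
    co2[[s]][!is.na(g)] <- flip(g[!is.na(g)])
    # re-normalise through the same path the reader uses
    a1 <- substr(co2[[s]], 1, 1); a2 <- substr(co2[[s]], 3, 3)
    co2[[s]] <- ifelse(is.na(co2[[s]]), NA,
                       paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
  }
  for (s in fix$panel$snp_id) {
    c1 <- count_genotypes(co, s); c2 <- count_genotypes(co2, s)
    expect_identical(c1[c("n_major_homo", "n_het", "n_minor_homo")],
                     c2[c("n_major_homo", "n_het", "n_minor_homo")])
  }
})
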