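# Cohort I/O: phenotype/genotype readers and the joined cohort table that
# every downstream stage consumes.

# Optional per-child measurements recognised by the readers. Biochemistry
# units follow clinical convention: mg/dl for glucose/lipids/creatinine,
# g/L for apolipoproteins, ng/ml for leptin/ferritin, uU/ml for insulin.
.pheno_optional_cols <- c(
  "waist", "hip", "mid_upper_arm", "calf",
  "body_fat_pct", "skeletal_muscle_pct", "rmr",
  "glucose", "insulin", "leptin",
  "tc", "ldl", "hdl", "tg", "apo_a1", "apo_b",
  "creatinine", "total_protein", "ferritin"
)

#' Define a panel of biallelic SNPs
#'
#' A SNP panel declares, for each locus, its identifier, gene label and the
#' major (wild-type) and minor (polymorphic) allele symbols. The declared
#' orientation fixes which homozygote is the reference class in counting and
#' in the Falconer decomposition.
#'
#' @param snp_id character vector of rsIDs (unique, non-empty).
#' @param gene character vector of gene labels.
#' @param major_allele,minor_allele one-character allele symbols; normalised
#'   to upper case. `NA` minor/major alleles are allowed, in which case the
#'   orientation is inferred from observed frequencies when counting.
#' @return A data frame of class `"snp_panel"`.
#' @examples
#' snp_panel("rs1137101", "LEPR", "A", "G")
#' @export
snp_panel <- function(snp_id, gene, major_allele, minor_allele) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id) || any(!nzchar(snp_id))) {
    stop_config("snp_id must be non-empty and unique within a panel")
  }
  major_allele <- toupper(as.character(major_allele))
  minor_allele <- toupper(as.character(minor_allele))
  both <- !is.na(major_allele) & !is.na(minor_allele)
  if (any(both & major_allele == minor_allele)) {
    stop_config("major_allele and minor_allele must differ for every SNP")
  }
  ok <- function(a) is.na(a) | nchar(a) == 1L
  if (!all(ok(major_allele)) || !all(ok(minor_allele))) {
    stop_config("allele symbols must be single characters")
  }
  out <- data.frame(
    snp_id = snp_id, gene = as.character(gene),
    major_allele = major_allele, minor_allele = minor_allele,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

.delim_for <- function(path, dialect) {
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  switch(dialect, csv = ",", tsv = "\t",
         stop_config("unknown dialect: ", dialect))
}

.read_table <- function(path, dialect) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = .delim_for(path, dialect),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", colClasses = "character")
}

.num <- function(x) suppressWarnings(as.numeric(x))

#' Read a phenotype table
#'
#' Reads a per-child phenotype table. Required columns: `sample_id`, `sex`
#' (`male`/`female`), `weight` (kg), `height` (cm), and either `age_days` or
#' both `birth_date` and `exam_date` (ISO dates; age is the calendar-day
#' difference). All other recognised columns are optional; unparseable or
#' empty optional cells become missing (`NA`), never zero.
#'
#' @param path path to a CSV or TSV file with a header row.
#' @param dialect `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return A data frame of phenotype records, one row per child.
#' @export
read_phenotypes <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- .read_table(path, dialect)
  for (col in c("sample_id", "sex", "weight", "height")) {
    if (!col %in% names(raw)) {
      stop_config("phenotype table is missing required column '", col, "'")
    }
  }
  has_age <- "age_days" %in% names(raw)
  has_dates <- all(c("birth_date", "exam_date") %in% names(raw))
  if (!has_age && !has_dates) {
    stop_config("phenotype table is missing required column 'age_days' ",
                "(or both 'birth_date' and 'exam_date')")
  }
  if (anyDuplicated(raw$sample_id)) {
    stop_data("duplicate sample_id in phenotype table: ",
              paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
                    collapse = ", "))
  }
  sex <- tolower(raw$sex)
  if (!all(sex %in% c("male", "female"))) {
    stop_data("sex must be 'male' or 'female'")
  }
  if (has_age) {
    age_days <- .num(raw$age_days)
  } else {
    age_days <- as.numeric(as.Date(raw$exam_date) - as.Date(raw$birth_date))
  }
  weight <- .num(raw$weight)
  height <- .num(raw$height)
  if (anyNA(age_days) || anyNA(weight) || anyNA(height)) {
    stop_data("required cells (age, weight, height) must all parse as numbers")
  }
  if (any(weight <= 0) || any(height <= 0) || any(age_days <= 0)) {
    stop_data("weight, height and age must be positive")
  }
  out <- data.frame(sample_id = raw$sample_id, sex = sex,
                    age_days = age_days, weight = weight, height = height,
                    stringsAsFactors = FALSE)
  for (col in .pheno_optional_cols) {
    if (col %in% names(raw)) out[[col]] <- .num(raw[[col]])
  }
  out
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]. Missing values are written as the literal
#' sentinel `NA`, distinct from `0` and from the empty string, so that
#' biochemistry values legitimately near zero survive a round trip.
#'
#' @param x a phenotype data frame.
#' @param path output path.
#' @param dialect `"auto"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  utils::write.table(x, path, sep = .delim_for(path, dialect),
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

.norm_call <- function(a1, a2) {
  # unordered allele pair, canonicalised by sorting so "A/G" == "G/A"
  ifelse(is.na(a1) | is.na(a2), NA_character_,
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
}

.parse_wide_genotypes <- function(raw) {
  snp_cols <- setdiff(names(raw), "sample_id")
  if (!"sample_id" %in% names(raw)) {
    stop_config("genotype table is missing required column 'sample_id'")
  }
  if (anyDuplicated(raw$sample_id)) {
    stop_data("duplicate sample_id in genotype table")
  }
  calls <- do.call(rbind, lapply(snp_cols, function(s) {
    cell <- toupper(trimws(raw[[s]]))
    cell[cell %in% c("", "NA", "./.", ".")] <- NA_character_
    ok <- is.na(cell) | grepl("^[A-Z]/?[A-Z]$", cell)
    if (!all(ok)) {
      stop_data("unparseable genotype cell for SNP ", s, ", sample ",
                raw$sample_id[which(!ok)[1]])
    }
    a1 <- substr(sub("/", "", cell), 1, 1)
    a2 <- substr(sub("/", "", cell), 2, 2)
    data.frame(sample_id = raw$sample_id, snp_id = s,
               allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  }))
  calls
}

.parse_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop_data("multiallelic VCF record(s) at ID ",
              paste(fix[grepl(",", alt), "ID"], collapse = ", "),
              "; only biallelic SNPs are supported")
  }
  ref <- toupper(fix[, "REF"]); alt <- toupper(alt)
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L)) {
    stop_data("non-SNP VCF record(s); REF and ALT must be single bases")
  }
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(ids, names(gt)))
  samples <- colnames(gt)
  calls <- do.call(rbind, lapply(seq_along(ids), function(i) {
    g <- gt[i, ]
    g[is.na(g)] <- "./."
    parts <- strsplit(g, "[/|]")
    dec <- function(p) {
      if (length(p) != 2L || any(p == ".")) return(c(NA_character_, NA_character_))
      idx <- as.integer(p)
      if (any(is.na(idx)) || any(idx > 1L)) {
        stop_data("GT allele index outside {0,1} for SNP ", ids[i])
      }
      c(ref[i], alt[i])[idx + 1L]
    }
    al <- unname(t(vapply(parts, dec, character(2))))
    data.frame(sample_id = samples, snp_id = ids[i],
               allele1 = al[, 1], allele2 = al[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  calls
}

#' Read genotype calls
#'
#' Reads genotype calls either from a wide table (one row per sample, one
#' column per SNP, cells like `"A/G"` or `"AG"`) or from a VCF v4.2 subset
#' (biallelic SNP records with a GT field; `./.` means missing). Allele pairs
#' are unordered: `"A/G"` and `"G/A"` compare equal. Major/minor orientation
#' is not assigned here; declare it in a [snp_panel()] or let the counting
#' stage infer it from observed frequencies.
#'
#' @param path input file.
#' @param format `"auto"` (`.vcf` extension selects VCF), `"wide_table"` or
#'   `"vcf"`.
#' @return A list with `calls` (long data frame: `sample_id`, `snp_id`,
#'   `allele1`, `allele2`) and `panel`, the inferred [snp_panel()] with
#'   observed allele symbols and undeclared orientation.
#' @export
read_genotypes <- function(path, format = c("auto", "wide_table", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "wide_table"
  }
  calls <- if (format == "vcf") {
    if (!file.exists(path)) stop_config("file not found: ", path)
    .parse_vcf_genotypes(path)
  } else {
    .parse_wide_genotypes(.read_table(path, "auto"))
  }
  tmp <- .norm_call(calls$allele1, calls$allele2)
  calls$allele1 <- substr(tmp, 1, 1)
  calls$allele2 <- substr(tmp, 3, 3)
  snps <- unique(calls$snp_id)
  observed <- lapply(snps, function(s) {
    a <- c(calls$allele1[calls$snp_id == s], calls$allele2[calls$snp_id == s])
    sort(unique(a[!is.na(a)]))
  })
  if (any(lengths(observed) > 2L)) {
    bad <- snps[lengths(observed) > 2L][1]
    stop_data("more than two allele symbols observed for SNP ", bad)
  }
  panel <- snp_panel(
    snp_id = snps, gene = NA_character_,
    major_allele = vapply(observed, function(a) a[1] %||% NA_character_,
                          character(1)),
    minor_allele = vapply(observed, function(a) if (length(a) > 1) a[2] else NA_character_,
                          character(1))
  )
  list(calls = calls, panel = panel)
}

#' Join phenotypes and genotypes into a cohort table
#'
#' Joins a phenotype table and long genotype calls on `sample_id` into the
#' wide cohort table all analysis stages consume: one row per child, one
#' genotype-call column (named by `snp_id`, `"X/Y"` strings) per SNP.
#' Children missing a given SNP call stay in the table with that call `NA`,
#' so per-SNP analysis n varies with genotyping coverage.
#'
#' @param phenotypes data frame from [read_phenotypes()].
#' @param genotypes either the list returned by [read_genotypes()] or a long
#'   calls data frame.
#' @param panel optional [snp_panel()] declaring major/minor alleles; when
#'   supplied, every observed allele must belong to the declared pair.
#' @param policy `"strict"` requires every genotyped sample to have a
#'   phenotype record; `"intersect"` keeps the common samples.
#' @return A data frame of class `"cohort_table"` with the panel attached as
#'   attribute `"snp_panel"`.
#' @export
join_cohort <- function(phenotypes, genotypes, panel = NULL,
                        policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  calls <- if (is.list(genotypes) && !is.data.frame(genotypes)) genotypes$calls else genotypes
  inferred <- if (is.list(genotypes) && !is.data.frame(genotypes)) genotypes$panel else NULL
  if (is.null(panel)) panel <- inferred
  if (is.null(panel)) {
    panel <- snp_panel(unique(calls$snp_id), NA_character_,
                       NA_character_, NA_character_)
  }
  extra <- setdiff(unique(calls$snp_id), panel$snp_id)
  if (length(extra)) stop_config("calls reference SNPs not in panel: ",
                                 paste(extra, collapse = ", "))
  gsamp <- unique(calls$sample_id)
  keep <- intersect(gsamp, phenotypes$sample_id)
  if (!length(keep)) stop_data("no sample_id in common between phenotypes and genotypes")
  if (policy == "strict" && length(setdiff(gsamp, phenotypes$sample_id))) {
    stop_data("genotyped samples missing from phenotype table: ",
              paste(utils::head(setdiff(gsamp, phenotypes$sample_id), 5),
                    collapse = ", "))
  }
  # strict keeps every phenotyped child (per-SNP n then varies with
  # genotyping coverage); intersect restricts to children with a genotype row
  out <- if (policy == "intersect") {
    phenotypes[phenotypes$sample_id %in% keep, , drop = FALSE]
  } else {
    phenotypes
  }
  for (s in panel$snp_id) {
    sub <- calls[calls$snp_id == s, , drop = FALSE]
    pr <- panel[panel$snp_id == s, ]
    declared <- c(pr$major_allele, pr$minor_allele)
    if (!anyNA(declared)) {
      obs <- c(sub$allele1, sub$allele2)
      bad <- !is.na(obs) & !obs %in% declared
      if (any(bad)) {
        i <- ((which(bad)[1] - 1L) %% nrow(sub)) + 1L
        stop_data("allele '", obs[bad][1], "' outside declared pair for SNP ",
                  s, " in sample ", sub$sample_id[i])
      }
    }
    g <- .norm_call(sub$allele1, sub$allele2)
    out[[s]] <- g[match(out$sample_id, sub$sample_id)]
  }
  attr(out, "snp_panel") <- panel
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  panel <- attr(x, "snp_panel")
  cat("Cohort table:", nrow(x), "children,",
      if (is.null(panel)) 0L else nrow(panel), "SNPs\n")
  if (!is.null(panel)) {
    n_per <- vapply(panel$snp_id, function(s) sum(!is.na(x[[s]])), integer(1))
    cat("  per-SNP genotyped n:",
        paste(sprintf("%s=%d", panel$snp_id, n_per), collapse = ", "), "\n")
  }
  if ("weight_category" %in% names(x)) {
    cat("  weight category:",
        sum(x$weight_category == "overweight_obese", na.rm = TRUE), "case /",
        sum(x$weight_category == "normal_weight", na.rm = TRUE), "control\n")
  }
  invisible(x)
}

#' Write / read a cohort table
#'
#' Serialises the joined cohort (including any derived columns) to TSV with
#' full double precision (17 significant digits) and the explicit `NA`
#' sentinel, so a write/read round trip preserves values and missingness.
#' The SNP panel is stored in a `#` header comment line.
#'
#' @param x a `cohort_table`.
#' @param path output path.
#' @return `path` invisibly (writer); a `cohort_table` (reader).
#' @export
write_cohort <- function(x, path) {
  panel <- attr(x, "snp_panel")
  hdr <- paste0("#snp_panel\t", paste(
    sprintf("%s:%s:%s:%s", panel$snp_id, panel$gene,
            panel$major_allele, panel$minor_allele), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) sprintf("%.17g", v))
  for (nm in names(y)) y[[nm]][is.na(x[[nm]])] <- NA
  utils::write.table(y, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#snp_panel")) stop_data("not a cohort table file")
  spec <- strsplit(sub("^#snp_panel\t?", "", first), "\t")[[1]]
  parts <- strsplit(spec, ":")
  na_if <- function(x) ifelse(x == "NA", NA_character_, x)
  panel <- snp_panel(
    vapply(parts, `[`, character(1), 1),
    na_if(vapply(parts, `[`, character(1), 2)),
    na_if(vapply(parts, `[`, character(1), 3)),
    na_if(vapply(parts, `[`, character(1), 4))
  )
  raw <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA", colClasses = "character")
  out <- raw
  for (nm in names(out)) {
    if (nm %in% c("sample_id", "sex", "weight_category", panel$snp_id)) next
    out[[nm]] <- .num(raw[[nm]])
  }
  attr(out, "snp_panel") <- panel
  class(out) <- c("cohort_table", "data.frame")
  out
}
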