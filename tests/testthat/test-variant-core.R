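test_that("variant call tables enforce their invariants", {
  expect_error(variant_call("chr1", 0L, "A", "T", 100L, 10L), "pos")
  expect_error(variant_call("chr1", 5L, "A", "A", 100L, 10L), "ref == alt")
  expect_error(variant_call("chr1", 5L, "A", "T", 100L, 150L), "depth_alt")
  expect_error(variant_call("chr1", 5L, "A", "T", 100L, 10L, quality = -1),
               "quality")
  expect_error(variant_call("chr1", 5L, "A", "T", 100L, 10L, vaf = 0.5),
               "inconsistent")
  calls <- variant_call("chr1", c(10L, 20L), "A", "T", 200L, c(10L, 50L))
  expect_equal(calls$vaf, c(0.05, 0.25))
  expect_equal(variant_key(calls), c("chr1:10:A>T", "chr1:20:A>T"))
})

test_that("VCF write/read round-trips every field the pipeline uses", {
  set.seed(42)
  n <- 12
  dp <- sample(100:2000, n)
  calls <- variant_call(
    chrom = sample(paste0("chr", c(1, 2, 10, "X")), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = "A",
    alt = sample(c("T", "G", "TT"), n, replace = TRUE),
    depth_total = dp, depth_alt = round(dp * runif(n, 0.01, 0.6)),
    quality = round(runif(n, 0, 200), 3),
    caller_filter = sample(c("PASS", "q22"), n, replace = TRUE),
    consequence = sample(protein_affecting_classes(), n, replace = TRUE),
    af_gnomad = ifelse(runif(n) < 0.5, NA, runif(n)),
    af_kg_eas = ifelse(runif(n) < 0.5, NA, runif(n) / 3)
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  back <- read_vcf(path)
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
  sorted <- calls[ord, ]
  rownames(sorted) <- NULL
  attr(back, "fraction") <- NULL
  expect_identical(back, sorted)
})

test_that("VCF records are written sorted by chromosome then position", {
  calls <- variant_call(c("chr2", "chr1", "chr1"), c(5L, 900L, 30L), "A", "T",
                        500L, 50L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  recs <- grep("^[^#]", readLines(path), value = TRUE)
  fields <- do.call(rbind, strsplit(recs, "\t"))
  expect_equal(fields[, 1], c("chr1", "chr1", "chr2"))
  expect_equal(as.integer(fields[, 2]), c(30L, 900L, 5L))
})

test_that("writing duplicate keys is refused and empty sets give a valid header-only VCF", {
  dup <- variant_call("chr1", c(10L, 10L), "A", "T", 500L, 50L)
  path <- withr::local_tempfile(fileext = ".vcf")
  expect_error(write_vcf(dup, path), "duplicate")
  empty <- variant_call(character(), integer(), character(), character(),
                        integer(), integer())
  write_vcf(empty, path)
  expect_true(all(grepl("^#", readLines(path))))
  back <- read_vcf(path)
  expect_equal(nrow(back), 0L)
})

test_that("VAF falls back to AD/DP when AF is absent and bad records error with their index", {
  path <- withr::local_tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "S"), collapse = "\t"))
  writeLines(c(header,
               "chr1\t100\t.\tA\tT\t60\tPASS\tCSQ_CLASS=missense_variant\tDP:AD\t200:190,10"),
             path)
  calls <- read_vcf(path)
  expect_equal(calls$vaf, 0.05)
  expect_true(is.na(calls$af_gnomad))

  writeLines(c(header, "chr1\t0\t.\tA\tT\t60\tPASS\t.\tDP:AD\t200:190,10"),
             path)
  expect_error(read_vcf(path), "pos")
  writeLines(c(header, "chr1\t50\t.\tA\tT\t60\tPASS\t.\tDP:AD\t200:150,300"),
             path)
  expect_error(read_vcf(path), "record 1")
})

test_that("multi-allelic records split into one call per alternate allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S"), collapse = "\t"),
               "chr3\t77\t.\tA\tT,G\t60\tPASS\tCSQ_CLASS=missense_variant\tDP:AD:AF\t400:360,30,10:0.075,0.025"),
             path)
  calls <- read_vcf(path)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$alt, c("T", "G"))
  expect_equal(calls$depth_alt, c(30L, 10L))
  expect_equal(calls$vaf, c(0.075, 0.025))
})

test_that("reports are tab-separated, percent-converted for VAF columns, and reject ragged rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(data.frame(x = 1), path)
  expect_length(readLines(path), 2L)

  write_report(data.frame(gene = "AXL", vaf = 0.0242), path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[2], "\t")[[1]], c("AXL", "2.42"))

  # fold/ratio columns stay on their own scale
  write_report(data.frame(vaf_tumor = 0.5, fold = 2.4, log_ratio = 1), path)
  expect_equal(strsplit(readLines(path)[2], "\t")[[1]], c("50", "2.4", "1"))

  write_report(data.frame(a = numeric(), b = character()), path)
  expect_length(readLines(path), 1L)

  expect_error(write_report(list(list(a = 1), list(b = 2)), path), "ragged")
})

test_that("fraction trios validate their member call sets", {
  good <- clean_call()
  expect_s3_class(fraction_trio("P1", good, good, good), "fraction_trio")
  dup <- variant_call("chr1", c(1L, 1L), "A", "T", 500L, 50L)
  expect_error(fraction_trio("P1", dup, good, good), "duplicate")
  expect_error(fraction_trio("P1", good, good, good,
                             blood_keys = data.frame(x = 1)), "blood_keys")
})
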