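test_that("the packaged frequency table carries the printed per-population values", {
  ft <- brs_frequencies()
  expect_equal(sort(populations(ft)),
               sort(c("NFE", "FIN", "AMR", "AFR", "JEW", "EAS", "SAS",
                      "JPN3K", "TWB")))
  e <- ft$entries
  a226v <- e[e$variant == "SCN5A|NM_198056|677C>T", ]
  expect_equal(a226v$frequency[a226v$population == "EAS"], 0.001357)
  expect_equal(a226v$frequency[a226v$population == "TWB"], 0.001508)
  expect_equal(a226v$frequency[a226v$population == "NFE"], 0.000008)
})

test_that("blank cells are absent, zeros are zero, out-of-range cells error", {
  df <- data.frame(variant = c("v1", "v2"), EAS = c("", "0"),
                   NFE = c("0.5", "0.1"), stringsAsFactors = FALSE)
  ft <- read_frequency_tsv(write_temp_tsv(df))
  e <- ft$entries
  expect_equal(nrow(e[e$variant == "v1", ]), 1L)  # blank EAS absent
  expect_equal(e$frequency[e$variant == "v2" & e$population == "EAS"], 0)

  df$EAS[1] <- "1.5"
  err <- tryCatch(read_frequency_tsv(write_temp_tsv(df)),
                  af_validation_error = identity)
  expect_s3_class(err, "af_validation_error")
  expect_match(conditionMessage(err), "row 1")
  expect_match(conditionMessage(err), "EAS")
})

test_that("frequency tables round-trip through write/read", {
  ft <- brs_frequencies()
  path <- tempfile(fileext = ".tsv")
  write_frequency_tsv(ft, path)
  back <- read_frequency_tsv(path)
  ord <- function(e) e[order(e$variant, e$population), ]
  expect_equal(ord(back$entries), ord(ft$entries), ignore_attr = TRUE)
})

write_temp_vcf <- function(body_lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF_eas,Number=A,Type=Float,Description=\"EAS allele frequency\">",
    "##INFO=<ID=AF_nfe,Number=A,Type=Float,Description=\"NFE allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body_lines), path)
  path
}

test_that("VCF INFO AF fields become per-population entries keyed CHROM-POS-REF-ALT", {
  path <- write_temp_vcf(c(
    "3\t38603929\trs1\tG\tA\t.\tPASS\tAF_eas=0.001357;AF_nfe=0.000008",
    "3\t38650000\trs2\tC\tT\t.\tPASS\tDP=100;AF_eas=0.5"
  ))
  ft <- read_frequency_vcf(path, "AF_")
  e <- ft$entries
  expect_equal(nrow(e), 3L)
  expect_equal(e$frequency[e$variant == "3-38603929-G-A" & e$population == "EAS"],
               0.001357)
  expect_equal(e$frequency[e$variant == "3-38603929-G-A" & e$population == "NFE"],
               0.000008)
  expect_equal(e$frequency[e$variant == "3-38650000-C-T" & e$population == "EAS"],
               0.5)
})

test_that("multi-allelic records yield one entry per alternate allele", {
  path <- write_temp_vcf(
    "3\t100\t.\tC\tT,G\t.\tPASS\tAF_eas=0.002,0.003;AF_nfe=0.1,0.2")
  e <- read_frequency_vcf(path, "AF_")$entries
  expect_equal(nrow(e), 4L)
  expect_equal(e$frequency[e$variant == "3-100-C-T" & e$population == "EAS"], 0.002)
  expect_equal(e$frequency[e$variant == "3-100-C-G" & e$population == "EAS"], 0.003)
  expect_equal(e$frequency[e$variant == "3-100-C-G" & e$population == "NFE"], 0.2)
})

test_that("a VCF without matching INFO fields gives an empty table with a warning", {
  path <- write_temp_vcf("3\t100\t.\tC\tT\t.\tPASS\tDP=5")
  expect_warning(ft <- read_frequency_vcf(path, "AF_"),
                 class = "af_empty_input")
  expect_equal(nrow(ft$entries), 0L)
})

test_that("annotate merges tables, keeps the maximum on collisions, and invents no populations", {
  reg <- brs_registry()
  ann <- annotate(reg, brs_frequencies())
  expect_equal(nrow(ann), 18L)
  expect_setequal(attr(ann, "populations"), populations(brs_frequencies()))

  # registry entry in no table -> all-absent frequency map
  extra <- toy_registry(1, prefix = "zz")
  ann2 <- annotate(rbind(reg, extra[, names(reg)]), brs_frequencies())
  pops <- attr(ann2, "populations")
  expect_true(all(is.na(ann2[ann2$key == extra$key, pops])))

  # same (variant, population) in two tables -> maximum retained
  t1 <- frequency_table(data.frame(variant = reg$key[1], population = "EAS",
                                   frequency = 0.0001))
  t2 <- frequency_table(data.frame(variant = reg$key[1], population = "EAS",
                                   frequency = 0.0002))
  expect_message(ann3 <- annotate(reg[1, ], list(t1, t2)), "maximum")
  expect_equal(ann3$EAS, 0.0002)
})

test_that("annotate also matches tabular resources by dbSNP identifier", {
  reg <- brs_registry()
  t <- frequency_table(data.frame(variant = "rs199473561", population = "EAS",
                                  frequency = 0.2))
  ann <- annotate(reg, t)
  expect_equal(ann$EAS[ann$dbsnp_id == "rs199473561"], 0.2)
})
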