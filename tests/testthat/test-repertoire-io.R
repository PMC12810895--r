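test_that("normalizeTrbvFamily maps both dialects onto IMGT families", {
  expect_identical(normalizeTrbvFamily("TRBV9*01"), "TRBV9")
  expect_identical(normalizeTrbvFamily("TCRBV09-01"), "TRBV9")
  expect_identical(normalizeTrbvFamily("TRBV12-3/12-4*01"), "TRBV12")
  expect_identical(normalizeTrbvFamily("TRBV12-3*01"), "TRBV12")
  expect_error(normalizeTrbvFamily("TRBV12-3/13-1"), "multiple")
  expect_identical(normalizeTrbvFamily("TRBV12-3/13-1", onAmbiguous = "na"),
                   NA_character_)
  expect_identical(normalizeTrbvFamily(c("", NA), onAmbiguous = "na"),
                   c(NA_character_, NA_character_))
})

airrRows <- data.frame(
  v_call = c("TRBV9*01", "TRBV12-3*01", "TRBV5-1*01"),
  junction_aa = c("CASSLGETQYF", "CASSPGQGYEQYF", "CASSLLGNTEAFF"),
  duplicate_count = c(6L, 3L, 1L),
  productive = c("T", "T", "T"),
  stringsAsFactors = FALSE)

test_that("parseRepertoire normalizes frequencies over retained rows", {
  p <- writeAirrFixture(airrRows)
  rep1 <- parseRepertoire(p, "airr")
  cl <- clonotypes(rep1)
  expect_identical(nrow(cl), 3L)
  expect_equal(sort(cl$productive_frequency), c(0.1, 0.3, 0.6))

  rep2 <- parseRepertoire(p, "airr", minTemplates = 2L)
  cl2 <- clonotypes(rep2)
  expect_identical(nrow(cl2), 2L)
  expect_equal(sort(cl2$productive_frequency), c(3 / 9, 6 / 9))
})

test_that("parseRepertoire drops non-standard CDR3 rows, keeps the rest", {
  rows <- airrRows
  rows$junction_aa[2] <- "CASS*GQGYEQYF"
  p <- writeAirrFixture(rows)
  rep1 <- parseRepertoire(p, "airr")
  expect_identical(nrow(clonotypes(rep1)), 2L)
  expect_identical(rep1@metadata$dropped, 1L)
  expect_equal(sum(clonotypes(rep1)$productive_frequency), 1)
})

test_that("parseRepertoire errors name the dialect and missing column", {
  p <- writeAirrFixture(airrRows[, -1])
  expect_error(parseRepertoire(p, "airr"), "airr dialect.*v_call")

  rows <- airrRows
  rows$productive <- "F"
  expect_error(parseRepertoire(writeAirrFixture(rows), "airr"),
               "empty repertoire")
  expect_error(parseRepertoire(tempfile(), "airr"), "not found")
})

test_that("parseRepertoire reads the immunoSEQ dialect", {
  rows <- data.frame(
    aminoAcid = c("CASSLGETQYF", "CASSPGQGYEQYF"),
    vGeneName = c("TCRBV09-01", "TCRBV12-03"),
    count = c(4L, 1L),
    sequenceStatus = c("In", "In"),
    stringsAsFactors = FALSE)
  rep1 <- parseRepertoire(writeAirrFixture(rows), "immunoseq")
  cl <- clonotypes(rep1)
  expect_setequal(cl$trbv_family, c("TRBV9", "TRBV12"))
  expect_equal(sort(cl$productive_frequency), c(0.2, 0.8))
})

test_that("airr round trip preserves the clonotype multiset and frequencies", {
  p <- writeAirrFixture(airrRows)
  orig <- parseRepertoire(p, "airr")
  out <- tempfile(fileext = ".tsv")
  writeRepertoire(orig, out, dialect = "airr")
  back <- parseRepertoire(out, "airr", sampleId = sampleId(orig))
  a <- clonotypes(orig); b <- clonotypes(back)
  key <- function(d) order(d$trbv_family, d$cdr3_aa)
  a <- a[key(a), ]; b <- b[key(b), ]
  expect_identical(a$cdr3_aa, b$cdr3_aa)
  expect_identical(a$templates, b$templates)
  expect_equal(a$productive_frequency, b$productive_frequency,
               tolerance = 1e-12)
})

test_that("detection threshold is strictly greater-than 2e-6", {
  r <- freqRepertoire("s1", c("TRBV9", "TRBV9", "TRBV12"),
                      c("CASSAAAAAAF", "CASSCCCCCCF", "CASSDDDDDDF"),
                      c(3e-6, 2e-6, 1e-5))
  det <- detectionSet(r)
  expect_true("CASSAAAAAAF" %in% det$cdr3_aa)   # 3e-6 > 2e-6
  expect_false("CASSCCCCCCF" %in% det$cdr3_aa)  # exactly 2e-6 excluded
  expect_true("CASSDDDDDDF" %in% det$cdr3_aa)
})

test_that("detectionSet is monotone in the threshold and collapses duplicates", {
  r <- TcrRepertoire("s1", "s1", data.frame(
    trbv_gene = c("TRBV9*01", "TRBV9*02"),
    trbv_family = c("TRBV9", "TRBV9"),
    cdr3_aa = c("CASSLGETQYF", "CASSLGETQYF"),
    templates = c(2L, 1L),
    productive_frequency = c(2 / 3, 1 / 3)))
  expect_identical(nrow(detectionSet(r)), 1L)  # same pair, one element
  lo <- detectionSet(r, 1e-6); hi <- detectionSet(r, 0.5)
  expect_true(nrow(hi) <= nrow(lo))
})

test_that("uniqueClones counts clonotypes above the threshold", {
  r <- freqRepertoire("s1", c("TRBV9", "TRBV9"),
                      c("CASSAAAAAAF", "CASSCCCCCCF"), c(3e-6, 2e-6))
  expect_identical(uniqueClones(r), 2L)  # 3e-6 clone + the filler clone
  expect_identical(uniqueClones(r, freqThreshold = 0.5), 1L)
})

test_that("repertoire validity rejects broken clonotype tables", {
  bad <- data.frame(trbv_family = "TRBV9", cdr3_aa = "CASSLGETQYF",
                    templates = 0L, productive_frequency = 1)
  expect_error(TcrRepertoire("s1", "s1", bad), "templates")
  bad2 <- data.frame(trbv_family = "TRBV9", cdr3_aa = "CASSLGETQYF",
                     templates = 1L, productive_frequency = 0.5)
  expect_error(TcrRepertoire("s1", "s1", bad2), "sum to 1")
})

test_that("cohort labels parse and heterodimer labels require both alleles", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(subject_id = c("u1", "u2", "u3"),
                         check.names = FALSE,
                         `A*02:01` = c(1L, 0L, NA),
                         `DQA1*05:01` = c(1L, 1L, 0L),
                         `DQB1*03:01` = c(1L, 0L, 1L)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- readCohortLabels(p)
  expect_identical(rownames(lab), c("u1", "u2", "u3"))
  expect_identical(lab[["A*02:01"]], c(1L, 0L, NA))

  hd <- deriveHeterodimerLabels(lab)
  expect_true("DQA1*05:01/DQB1*03:01" %in% names(hd))
  expect_identical(hd[["DQA1*05:01/DQB1*03:01"]], c(1L, 0L, 0L))

  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(subject_id = "u1", allele = 2), bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readCohortLabels(bad), "non-binary")
})
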