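test_that("excludeReferenceLike removes same-family edit-<=1 candidates only", {
  ref <- data.frame(trbv_family = "TRBV9", cdr3_aa = "CASSLGETQYF",
                    stringsAsFactors = FALSE)
  cand <- data.frame(
    trbv_family = c("TRBV9", "TRBV9", "TRBV12", "TRBV9"),
    cdr3_aa = c("CASSLGETQYF",   # identical -> excluded
                "CASSLGETPYF",   # one substitution -> excluded
                "CASSLGETPYF",   # same variant, other family -> kept
                "CASSDDDDDDF"),  # unrelated -> kept
    stringsAsFactors = FALSE)
  out <- excludeReferenceLike(cand, ref)
  expect_identical(out$cdr3_aa, c("CASSLGETPYF", "CASSDDDDDDF"))
  expect_identical(out$trbv_family, c("TRBV12", "TRBV9"))
  # idempotent
  expect_identical(excludeReferenceLike(out, ref), out)
})

test_that("excludeReferenceLike equals the brute-force rule on random input", {
  set.seed(47)
  base <- rndCdr3(10, 9, 13, "CASS")
  vary <- vapply(base, function(b) {
    v <- strsplit(b, "")[[1]]; v[6] <- sample(AA20, 1)
    paste(v, collapse = "")
  }, "")
  cand <- data.frame(trbv_family = sample(c("TRBV9", "TRBV12"), 40, TRUE),
                     cdr3_aa = sample(c(base, vary, rndCdr3(20, 9, 13, "CASS")),
                                      40, TRUE), stringsAsFactors = FALSE)
  ref <- data.frame(trbv_family = rep(c("TRBV9", "TRBV12"), 5),
                    cdr3_aa = base, stringsAsFactors = FALSE)
  out <- excludeReferenceLike(cand, ref)
  dropBrute <- vapply(seq_len(nrow(cand)), function(i) {
    r <- ref[ref$trbv_family == cand$trbv_family[i], "cdr3_aa"]
    length(r) > 0 && any(adist(cand$cdr3_aa[i], r) <= 1)
  }, TRUE)
  expect_identical(out, cand[!dropBrute, , drop = FALSE])
})

test_that("discoverNovel masks gated samples and guards low support", {
  occ <- matrix(0, 30, 1, dimnames = list(sprintf("s%02d", 1:30), "TRBV9|CASSAAAAAAF"))
  occ[1:12, 1] <- 1
  y <- c(rep(1L, 12), rep(0L, 18))
  expect_warning(r0 <- discoverNovel(occ, rep(NA_integer_, 30)), "fewer than 5")
  expect_identical(nrow(r0), 0L)
  # masked samples drop out of the table entirely
  y2 <- y; y2[13:20] <- NA
  res <- discoverNovel(occ, y2, screenConfig(pThreshold = 1e-4))
  expect_equal(res$a + res$b + res$c + res$d, sum(!is.na(y2)))
})

test_that("clusterRegex builds anchored motifs per the alignment rules", {
  expect_identical(clusterRegex("CASSLAPGATNEKLFF", "CASSVAPGATNEKLFF"),
                   "^CASS[LV]APGATNEKLFF$")
  expect_identical(clusterRegex("CASSLAPGATNEKLFF"), "^CASSLAPGATNEKLFF$")
  # shorter member: optional position token, both strings match
  r <- clusterRegex("CASSLAPGF", "CASSAPGF")
  expect_true(grepl(".\\{0,1\\}", r))
  expect_true(grepl(r, "CASSLAPGF"))
  expect_true(grepl(r, "CASSAPGF"))
  # longer member: optional insertion group
  r2 <- clusterRegex("CASSLAPGF", "CASSLLAPGF")
  expect_true(grepl(r2, "CASSLAPGF"))
  expect_true(grepl(r2, "CASSLLAPGF"))
})

test_that("metaclonotype members always full-match their regex", {
  for (s in 1:5) {
    cl <- syntheticClusterFeatures(nMembers = 5L, seed = s)
    # add one deletion and one insertion variant of the anchor
    a <- cl$cdr3_aa[1]
    extra <- c(paste0(substr(a, 1, 5), substr(a, 7, nchar(a))),
               paste0(substr(a, 1, 5), "W", substr(a, 6, nchar(a))))
    feats <- rbind(cl, data.frame(allele = cl$allele[1],
                                  trbv_family = cl$trbv_family[1],
                                  cdr3_aa = extra, type = "exact_public"))
    mc <- buildMetaclonotypes(feats)$metaclonotypes
    expect_gte(nrow(mc), 1L)
    for (i in seq_len(nrow(mc))) {
      expect_true(grepl(mc$regex[i], mc$anchor_cdr3[i]))
      expect_true(all(grepl(mc$regex[i], mc$members[[i]])))
    }
    # >= 99% of unrelated random background CDR3s do not match
    bg <- rndCdr3(300, 8, 18, "CASS")
    expect_lt(mean(grepl(mc$regex[1], bg)), 0.01)
  }
})

test_that("buildMetaclonotypes honors the greedy structure", {
  # 3-node path (anchor at the middle by degree): one cluster of 2 members
  an <- "CASSLAPGATNEF"                 # L5V costs 9, G8A costs 12, both <= 14
  m1 <- "CASSVAPGATNEF"
  m2 <- "CASSVAPAATNEF"                 # an -> m2 needs both subs: 21 > 14
  feats <- data.frame(trbv_family = "TRBV9", cdr3_aa = c(an, m1, m2),
                      stringsAsFactors = FALSE)
  D <- tcrdistMatrix(feats)
  expect_true(D[1, 2] <= 14 && D[2, 3] <= 14 && D[1, 3] > 14)
  out <- buildMetaclonotypes(feats)
  expect_identical(nrow(out$metaclonotypes), 1L)
  expect_identical(out$metaclonotypes$anchor_cdr3, m1)
  expect_identical(out$metaclonotypes$n_members, 2L)
  # isolated feature: no metaclonotype, kept as singleton
  iso <- data.frame(trbv_family = "TRBV9", cdr3_aa = "CASSWWWWWWWWF",
                    stringsAsFactors = FALSE)
  out2 <- buildMetaclonotypes(rbind(feats[1, ], iso))
  expect_identical(nrow(out2$metaclonotypes), 0L)
  expect_identical(length(out2$singletons), 2L)
})

test_that("screenPrevalence applies regex, family gate and strata", {
  reps <- list(
    freqRepertoire("e1", "TRBV9", "CASSLAPGATNEF", 0.01),
    freqRepertoire("e2", "TRBV12", "CASSLAPGATNEF", 0.01),  # wrong family
    freqRepertoire("e3", "TRBV9", "CASSDDDDDDDDF", 0.01))
  mc <- data.frame(id = "mc_001", allele = "A*02:01", trbv_family = "TRBV9",
                   anchor_cdr3 = "CASSLAPGATNEF", n_members = 1L,
                   regex = "^CASS[LV]APGATNEF$", stringsAsFactors = FALSE)
  strata <- data.frame(sample_id = c("e1", "e2", "e3"),
                       exposed = c(TRUE, TRUE, FALSE),
                       allele_pos = c(1L, 1L, NA))
  pv <- screenPrevalence(mc, reps, strata)
  expect_identical(nrow(pv), 4L)
  expect_identical(pv$fraction[pv$stratum == "+Ex/+HLA"], 0.5)  # e1 yes, e2 no
  expect_true(all(pv$flagged[pv$n_samples == 0]))
  expect_true(all(is.na(pv$fraction[pv$n_samples == 0])))
  # a regex that can never match yields all-zero detected counts
  mc0 <- mc; mc0$regex <- "^ZZZ$"
  pv0 <- screenPrevalence(mc0, reps, strata)
  expect_identical(sum(pv0$n_detected), 0L)
})
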