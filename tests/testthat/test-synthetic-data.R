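test_that("generateCohort is deterministic in the seed", {
  cfg <- simulationConfig(nSubjects = 8L, nBackground = 40L, seed = 9L)
  a <- generateCohort(cfg); b <- generateCohort(cfg)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  expect_identical(clonotypes(a$repertoires[[3]]),
                   clonotypes(b$repertoires[[3]]))
  c2 <- generateCohort(simulationConfig(nSubjects = 8L, nBackground = 40L,
                                        seed = 10L))
  expect_false(identical(clonotypes(a$repertoires[[1]]),
                         clonotypes(c2$repertoires[[1]])))
})

test_that("deterministic limit: penetrance 1 / leak 0 reproduces the labels", {
  cfg <- simulationConfig(nSubjects = 20L, nExactPublic = 3L,
                          nQuasiPublic = 0L, penetrancePos = 1,
                          leakNeg = 1e-12, nBackground = 30L, seed = 4L)
  co <- generateCohort(cfg)
  det <- cohortDetections(co$repertoires)
  occ <- buildOccurrence(det, co$truth, "exact",
                         sampleIds = vapply(co$repertoires, sampleId, ""))
  y <- co$labels[vapply(co$repertoires, subjectId, ""), 1]
  for (j in seq_len(ncol(occ)))
    expect_identical(as.integer(occ[, j]), as.integer(y))
})

test_that("quasi-public planting: neighborhood detection dominates exact", {
  cfg <- simulationConfig(nSubjects = 40L, nExactPublic = 0L,
                          nQuasiPublic = 5L, nBackground = 50L, seed = 12L)
  co <- generateCohort(cfg)
  det <- cohortDetections(co$repertoires)
  ids <- vapply(co$repertoires, sampleId, "")
  exact <- buildOccurrence(det, co$truth, "exact", sampleIds = ids)
  edit1 <- buildOccurrence(det, co$truth, "edit1", sampleIds = ids)
  expect_true(all(edit1 - exact >= 0))
  expect_true(sum(edit1) > sum(exact))  # variants make the neighborhood public
})

test_that("simulationConfig validates its probabilities", {
  expect_error(simulationConfig(penetrancePos = 0.1, leakNeg = 0.5), "exceed")
  expect_error(simulationConfig(alleles = data.frame(name = "A", prevalence = 2)),
               "prevalence")
  expect_warning(simulationConfig(alleles = data.frame(name = "A",
                                                       prevalence = 1)),
                 "degenerate")
})

test_that("downsampleRepertoire degenerate cases", {
  one <- TcrRepertoire("s1", "s1", data.frame(
    trbv_gene = "TRBV9", trbv_family = "TRBV9", cdr3_aa = "CASSLGETQYF",
    templates = 5L, productive_frequency = 1))
  ds <- downsampleRepertoire(one, 37L, seed = 1L)
  expect_identical(nrow(clonotypes(ds)), 1L)
  expect_equal(clonotypes(ds)$productive_frequency, 1)
  expect_identical(clonotypes(ds)$templates, 37L)

  many <- TcrRepertoire("s2", "s2", data.frame(
    trbv_gene = "TRBV9", trbv_family = "TRBV9",
    cdr3_aa = c("CASSLGETQYF", "CASSPGQGYEQYF"),
    templates = c(3L, 3L), productive_frequency = c(0.5, 0.5)))
  d1 <- downsampleRepertoire(many, 1L, seed = 2L)
  expect_identical(nrow(clonotypes(d1)), 1L)
  expect_identical(d1@metadata$n_draws, 1L)
  expect_identical(d1@metadata$source_sample, "s2")
  expect_error(downsampleRepertoire(many, 0L), ">= 1")
})

test_that("expected unique clones after 1000 draws from 10k equal clones", {
  # closed-form occupancy: E[unique] = 10000 * (1 - (1 - 1/10000)^1000)
  set.seed(99)
  cdr3s <- character(0)
  while (length(cdr3s) < 10000)
    cdr3s <- unique(c(cdr3s, apply(matrix(sample(AA20, 12000 * 8,
                                                 replace = TRUE), 12000), 1,
                                   paste, collapse = "")))
  cdr3s <- cdr3s[1:10000]
  flat <- TcrRepertoire("flat", "flat", data.frame(
    trbv_gene = "TRBV9", trbv_family = "TRBV9", cdr3_aa = cdr3s,
    templates = rep(1L, 10000), productive_frequency = rep(1e-4, 10000)))
  uniq <- vapply(1:200, function(s)
    nrow(clonotypes(downsampleRepertoire(flat, 1000L, seed = s))), 0L)
  expected <- 10000 * (1 - (1 - 1 / 10000) ^ 1000)
  expect_lt(abs(mean(uniq) - expected) / expected, 0.02)
})

test_that("buildCalibrationSet enumerates (source, draws) pairs with labels", {
  cfg <- simulationConfig(nSubjects = 2L, nBackground = 60L, seed = 3L)
  co <- generateCohort(cfg)
  cal <- buildCalibrationSet(co$repertoires, drawsList = c(10, 100), seed = 5L)
  expect_identical(length(cal$repertoires), 4L)   # 2 sources x 2 draw counts
  expect_identical(nrow(cal$info), 4L)
  expect_setequal(cal$info$subject_id,
                  vapply(co$repertoires, subjectId, ""))
  expect_setequal(cal$info$n_draws, c(10L, 100L))
  # the quoted protocol's arithmetic: 650 sources x 7 draw counts
  expect_identical(650L * 7L, 4550L)
})

test_that("replicate richness is monotone in draw count (Spearman > 0.9)", {
  cfg <- simulationConfig(nSubjects = 3L, nBackground = 400L, seed = 8L)
  co <- generateCohort(cfg)
  draws <- c(1, 5, 10, 25, 50, 100, 500)
  rho <- vapply(1:50, function(s) {
    cal <- buildCalibrationSet(co$repertoires, drawsList = draws, seed = s)
    U <- vapply(cal$repertoires, uniqueClones, 0L)
    cor(U, cal$info$n_draws, method = "spearman")
  }, 0)
  expect_gt(mean(rho), 0.9)
})

test_that("simulateFeatureMatrix has the declared shape and determinism", {
  sim <- simulateFeatureMatrix(nSamples = 50L, nInformative = 5L,
                               nDecoy = 10L, seed = 2L)
  expect_identical(dim(sim$X), c(50L, 15L))
  expect_true(all(sim$X %in% 0:1))
  expect_identical(sim$informative, 1:5)
  sim2 <- simulateFeatureMatrix(nSamples = 50L, nInformative = 5L,
                                nDecoy = 10L, seed = 2L)
  expect_identical(sim$X, sim2$X)
  expect_identical(sim$y, sim2$y)
})

test_that("syntheticClusterFeatures plants a same-family substitution star", {
  cl <- syntheticClusterFeatures(nMembers = 6L, family = "TRBV9", seed = 3L)
  expect_identical(nrow(cl), 6L)
  expect_identical(unique(cl$trbv_family), "TRBV9")
  expect_identical(anyDuplicated(cl$cdr3_aa), 0L)
  anchor <- cl$cdr3_aa[1]
  expect_true(all(levenshtein(anchor, cl$cdr3_aa[-1]) == 1L))
  expect_true(all(nchar(cl$cdr3_aa) == nchar(anchor)))  # substitutions only
})
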