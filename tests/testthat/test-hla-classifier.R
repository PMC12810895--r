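test_that("auroc matches hand-enumerated and reference values", {
  expect_identical(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_identical(auroc(c(1, 1), c(0, 1)), 0.5)  # ties count one half
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(13)
  sc <- rnorm(200); y <- rbinom(200, 1, plogis(sc))
  ref <- as.numeric(suppressMessages(pROC::auc(y, sc)))
  expect_equal(auroc(sc, y), ref, tolerance = 1e-12)
})

test_that("balancedAccuracy matches the (TPR + TNR) / 2 formula", {
  expect_identical(balancedAccuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_identical(balancedAccuracy(rep(1, 4), c(1, 1, 0, 0)), 0.5)
  # TP=9, FN=1, TN=8, FP=2 -> (0.9 + 0.8) / 2
  calls <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  labs <- c(rep(1, 10), rep(0, 10))
  expect_equal(balancedAccuracy(calls, labs), 0.85, tolerance = 1e-12)
})

test_that("IPW weights give each class total weight exactly 1", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  w <- ipwWeights(y)
  expect_equal(sum(w[y == 1]), 1, tolerance = 1e-14)
  expect_equal(sum(w[y == 0]), 1, tolerance = 1e-14)
  expect_error(ipwWeights(rep(1, 5)), "both classes")
})

test_that("weightedObjective equals -2 log 2 at the origin", {
  set.seed(3)
  X <- matrix(rbinom(60, 1, 0.3), 20, 3)
  y <- rbinom(20, 1, 0.5); y[1] <- 1; y[2] <- 0
  w <- ipwWeights(y)
  expect_equal(weightedObjective(rep(0, 3), 0, X, y, w, lambda = 1),
               -2 * log(2), tolerance = 1e-12)
  # the penalty enters linearly in ||beta||_1
  b <- c(0.5, -1, 0)
  expect_equal(weightedObjective(b, 0.2, X, y, w, 2) -
                 weightedObjective(b, 0.2, X, y, w, 1),
               -sum(abs(b)), tolerance = 1e-12)
})

test_that("featurize sets exact and edit1 bits by mode semantics", {
  det <- data.frame(sample_id = c("s1", "s2"),
                    trbv_family = c("TRBV9", "TRBV9"),
                    cdr3_aa = c("CASSLGETPYF", "CASSDDDDDDF"),
                    stringsAsFactors = FALSE)
  feats <- data.frame(trbv_family = c("TRBV9", "TRBV9"),
                      cdr3_aa = c("CASSLGETQYF", "CASSLGETQYF"),
                      mode = c("exact", "edit1"), stringsAsFactors = FALSE)
  X <- featurize(det, feats, sampleIds = c("s1", "s2", "s3"))
  # s1 carries a 1-substitution variant: edit1 bit on, exact bit off
  expect_identical(unname(X["s1", ]), c(0, 1))
  expect_identical(unname(X["s2", ]), c(0, 0))
  expect_identical(unname(X["s3", ]), c(0, 0))   # absent sample: all zero
  expect_identical(colnames(X),
                   c("TRBV9|CASSLGETQYF|exact", "TRBV9|CASSLGETQYF|edit1"))
  expect_identical(X, featurize(det, feats, sampleIds = c("s1", "s2", "s3")))
})

test_that("makeFolds groups by subject and stratifies by label", {
  subjects <- rep(sprintf("u%02d", 1:20), each = 2)
  y <- rep(c(1L, 0L), c(12, 28))
  fold <- tcrHLA:::makeFolds(y, subjects, nFolds = 5L, seed = 7L)
  split <- tapply(fold, subjects, function(f) length(unique(f)))
  expect_true(all(split == 1))                # never splits a subject
  perFold <- table(fold[y == 1][!duplicated(subjects[y == 1])])
  expect_lte(max(perFold) - min(perFold), 1L) # positives spread evenly
})

test_that("fitAlleleModel recovers a separating feature and drops decoys", {
  set.seed(29)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  X <- cbind(signal = y,
             matrix(rbinom(n * 6, 1, 0.2), n,
                    dimnames = list(NULL, paste0("decoy", 1:6))))
  m <- fitAlleleModel(X, y, seed = 1L)
  w <- setNames(m@beta, m@features$cdr3_aa)
  expect_true("signal" %in% names(w) && w[["signal"]] > 0)
  expect_false(any(grepl("decoy", names(w))))
  expect_identical(unname(m@ipw), c(sum(y == 1), sum(y == 0)))
  expect_identical(length(m@beta), nrow(m@features))
  # decision scores separate the classes on the training data
  f <- decisionScore(m, X)
  expect_gt(auroc(f, y), 0.99)
})

test_that("fitAlleleModel validates its inputs", {
  X <- matrix(c(0, 1, 2, 1), 2, 2)
  expect_error(fitAlleleModel(X, c(0, 1)), "binary")
  Xb <- matrix(rbinom(20, 1, 0.5), 10, 2)
  expect_error(fitAlleleModel(Xb, rep(1L, 10)), "both classes")
})

test_that("nonzero count is non-increasing along the penalty path", {
  sim <- simulateFeatureMatrix(nSamples = 150, nInformative = 10,
                               nDecoy = 30, seed = 6L)
  glmLam <- rev(exp(seq(log(1e-3), log(1e2), length.out = 25))) / 2
  fit <- tcrHLA:::glmnetBinary(sim$X, sim$y, glmLam)
  nz <- fit$df          # glmLam descending: support can only grow, modulo
  expect_true(all(diff(nz) >= -1))  # a 1-feature solver-noise slack
})

test_that("decisionScore honors the affine form and column matching", {
  feats <- data.frame(trbv_family = c("TRBV9", "TRBV12"),
                      cdr3_aa = c("CASSAAAAAAF", "CASSCCCCCCF"),
                      mode = c("exact", "edit1"), stringsAsFactors = FALSE)
  m <- new("AlleleModel", allele = "A*02:01", features = feats,
           beta = c(2, -1), intercept = 0.5, lambda = 0.1,
           ipw = c(n1 = 3, n0 = 7))
  expect_identical(decisionScore(m, c(0, 0)), 0.5)   # all-zero -> intercept
  expect_identical(decisionScore(m, c(1, 1)), 1.5)
  # named columns are re-ordered to the model's feature order
  X <- matrix(c(1, 1), 1, 2,
              dimnames = list(NULL, c("TRBV12|CASSCCCCCCF|edit1",
                                      "TRBV9|CASSAAAAAAF|exact")))
  expect_identical(decisionScore(m, X), 1.5)
  expect_error(decisionScore(m, matrix(0, 1, 3)), "dimension")
})

test_that("model JSON serialization round-trips bit-exactly", {
  sim <- simulateFeatureMatrix(nSamples = 100, nInformative = 5, nDecoy = 10,
                               seed = 11L)
  m <- fitAlleleModel(sim$X, sim$y, seed = 2L, allele = "B*07:02")
  m <- calibrateModel(m, decisionScore(m, sim$X), sim$y)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  writeAlleleModel(m, p1)
  back <- readAlleleModel(p1)
  expect_identical(back@beta, m@beta)
  expect_identical(back@intercept, m@intercept)
  expect_identical(back@lambda, m@lambda)
  expect_identical(back@calibration$standard, m@calibration$standard)
  writeAlleleModel(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1) + 10),
                   readBin(p2, "raw", file.size(p2) + 10))
})
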