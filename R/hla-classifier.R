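#' Build binary feature vectors for samples
#'
#' Maps each sample's detection set to the model's binary representation:
#' an exact-feature bit is set iff the `(family, cdr3)` pair is detected at
#' productive frequency above 2e-6; an edit-1 anchor bit is set iff any
#' same-family clonotype within one substitution, insertion or deletion of
#' the anchor is detected. Both subvectors are concatenated in the order of
#' `features`.
#'
#' @param detections data.table with `sample_id`, `trbv_family`, `cdr3_aa`
#'   (rbind of [detectionSet] outputs with a `sample_id` column).
#' @param features data.frame with `trbv_family`, `cdr3_aa`,
#'   `mode` (`"exact"`/`"edit1"`).
#' @param sampleIds row universe (defaults to samples present).
#' @return dense binary matrix, samples x features; column names are
#'   `"<family>|<cdr3>|<mode>"`.
#' @export
featurize <- function(detections, features, sampleIds = NULL) {
  stopIfNot(all(features$mode %in% c("exact", "edit1")),
            "feature mode must be 'exact' or 'edit1'")
  det <- as.data.table(detections)
  if (is.null(sampleIds)) sampleIds <- sortC(unique(det$sample_id))
  cols <- paste(features$trbv_family, features$cdr3_aa, features$mode,
                sep = "|")
  X <- matrix(0, length(sampleIds), nrow(features),
              dimnames = list(sampleIds, cols))
  for (md in c("exact", "edit1")) {
    sel <- which(features$mode == md)
    if (!length(sel)) next
    occ <- buildOccurrence(det, features[sel, , drop = FALSE], mode = md,
                           sampleIds = sampleIds)
    X[, sel] <- as.matrix(occ)
  }
  X
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a uniformly random positive outranks a uniformly
#' random negative, ties counted one half.
#'
#' @param scores numeric decision scores.
#' @param labels binary labels (0/1), both classes present.
#' @return value in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopIfNot(n1 > 0 && n0 > 0, "auroc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity.
#'
#' @param calls binary predicted classes.
#' @param labels binary true labels, both classes present.
#' @return value in \[0, 1\].
#' @export
balancedAccuracy <- function(calls, labels) {
  labels <- as.integer(labels); calls <- as.integer(calls)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopIfNot(n1 > 0 && n0 > 0, "balancedAccuracy needs both classes")
  (sum(calls == 1 & labels == 1) / n1 + sum(calls == 0 & labels == 0) / n0) / 2
}

#' Inverse-probability class weights
#'
#' `1/n1` for positives and `1/n0` for negatives, so each class carries
#' total weight exactly 1 in the fitting objective regardless of
#' imbalance.
#'
#' @param y binary labels.
#' @return numeric weight vector.
#' @export
ipwWeights <- function(y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopIfNot(n1 > 0 && n0 > 0, "both classes required for IPW")
  ifelse(y == 1, 1 / n1, 1 / n0)
}

#' Inverse-probability-weighted L1 logistic objective
#'
#' `sum_i w_i [y_i log s_i + (1 - y_i) log(1 - s_i)] - lambda * ||beta||_1`
#' with `s_i = sigmoid(a0 + x_i' beta)`; the intercept is unpenalized. At
#' `beta = 0, a0 = 0` this equals `-2 log 2` for any label vector (each
#' class contributes total weight 1 times `log 2`).
#'
#' @param beta weight vector; `intercept` scalar.
#' @param X binary design matrix; `y` binary labels; `w` IPW weights.
#' @param lambda L1 penalty.
#' @param intercept unpenalized intercept.
#' @return scalar objective value (to be maximized).
#' @export
weightedObjective <- function(beta, intercept, X, y, w, lambda) {
  eta <- as.numeric(intercept + X %*% beta)
  # numerically safe log-likelihood terms
  ll <- y * plogis(eta, log.p = TRUE) +
    (1 - y) * plogis(-eta, log.p = TRUE)
  sum(w * ll) - lambda * sum(abs(beta))
}

# subject-grouped, label-stratified fold assignment
makeFolds <- function(y, subjects, nFolds, seed) {
  df <- data.table(subject = subjects, y = y)
  sub <- df[, list(y = max(y)), by = "subject"]
  withSeed(seed, {
    fold <- integer(nrow(sub))
    for (cls in c(1, 0)) {
      i <- which(sub$y == cls)
      i <- i[sample.int(length(i))]
      fold[i] <- rep_len(seq_len(nFolds), length(i))
    }
    fold[match(subjects, sub$subject)]
  })
}

#' Fit a per-allele L1-logistic classifier with IPW
#'
#' Maximizes the inverse-probability-weighted L1-penalized log-likelihood
#' (glmnet solver, unpenalized intercept, no standardization of the binary
#' design). The penalty is tuned by maximizing mean out-of-fold AUROC over
#' subject-grouped, label-stratified folds. Exact AUROC ties — common here,
#' because well-separated binary designs hold the out-of-fold AUROC at
#' exactly 1 over a wide penalty plateau — go to the smaller penalty: the
#' denser model keeps the redundant screened features whose overlap is what
#' makes predictions robust in shallow repertoires. The returned model
#' retains only features with nonzero weights. `lambda` is reported on the weighted-objective scale where each
#' class carries total weight 1 (glmnet's internally rescaled penalty is
#' `lambda / 2`).
#'
#' @param X binary samples x features matrix (named columns
#'   `"family|cdr3|mode"` as from [featurize], or arbitrary names).
#' @param y binary labels (>= 2 per class).
#' @param subjects subject ids for leakage-safe folds (default: one subject
#'   per sample).
#' @param lambdaGrid penalty grid (weighted-objective scale).
#' @param nFolds cross-validation folds.
#' @param seed fold-assignment seed.
#' @param allele allele name stored on the model.
#' @param features optional feature table aligned with `colnames(X)`; when
#'   omitted it is parsed from the column names.
#' @return an [AlleleModel-class] (uncalibrated).
#' @export
fitAlleleModel <- function(X, y, subjects = NULL,
                           lambdaGrid = exp(seq(log(1e-3), log(1e2),
                                                length.out = 25)),
                           nFolds = 5L, seed = 1L, allele = "allele",
                           features = NULL) {
  X <- as.matrix(X)
  stopIfNot(all(X %in% c(0, 1)), "X must be binary")
  y <- as.integer(y)
  stopIfNot(length(unique(y)) == 2, "y must contain both classes")
  stopIfNot(sum(y == 1) >= 2 && sum(y == 0) >= 2,
            "need at least 2 samples per class")
  if (is.null(subjects)) subjects <- paste0("sample", seq_len(nrow(X)))
  if (is.null(features)) features <- parseFeatureNames(colnames(X))

  lambdaGrid <- sortC(lambdaGrid) # ascending; glmnet wants descending
  glmLam <- rev(lambdaGrid) / 2
  fold <- makeFolds(y, subjects, nFolds, seed)

  cvAuc <- matrix(NA_real_, nFolds, length(glmLam))
  for (k in seq_len(nFolds)) {
    tr <- fold != k; te <- !tr
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
    fit <- glmnetBinary(X[tr, , drop = FALSE], y[tr], glmLam)
    sc <- predictGlmnetLink(fit, X[te, , drop = FALSE], glmLam)
    cvAuc[k, ] <- apply(sc, 2, auroc, labels = y[te])
  }
  meanAuc <- colMeans(cvAuc, na.rm = TRUE)
  # glmLam is descending; the last index attaining the max is the
  # smallest lambda among exact AUROC ties (densest model)
  best <- max(which(meanAuc == max(meanAuc, na.rm = TRUE)))

  fit <- glmnetBinary(X, y, glmLam)
  cf <- coefGlmnet(fit, glmLam[best], ncol(X))
  beta <- cf$beta; names(beta) <- colnames(X)
  nz <- which(beta != 0)

  new("AlleleModel", allele = allele,
      features = features[nz, , drop = FALSE],
      beta = unname(beta[nz]), intercept = cf$a0,
      lambda = 2 * glmLam[best],
      ipw = c(n1 = sum(y == 1), n0 = sum(y == 0)),
      cv = list(lambdaGrid = 2 * glmLam, meanAuroc = meanAuc,
                foldAuroc = cvAuc, nFolds = as.integer(nFolds),
                seed = as.integer(seed)),
      calibration = list(), version = "1")
}

parseFeatureNames <- function(nm) {
  parts <- strsplit(nm, "|", fixed = TRUE)
  ok <- lengths(parts) == 3
  data.frame(
    trbv_family = ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_),
    cdr3_aa = ifelse(ok, vapply(parts, `[`, "", 2L), nm),
    mode = ifelse(ok, vapply(parts, `[`, "", 3L), "exact"),
    stringsAsFactors = FALSE)
}

# glmnet with IPW weights recomputed on the supplied rows; pads a zero
# column when the design has a single feature (glmnet needs >= 2)
glmnetBinary <- function(X, y, glmLam) {
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, `..pad..` = 0)
  w <- ipwWeights(y)
  fit <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                        lambda = glmLam, standardize = FALSE)
  attr(fit, "pad") <- pad
  fit
}

predictGlmnetLink <- function(fit, X, glmLam) {
  if (isTRUE(attr(fit, "pad"))) X <- cbind(X, `..pad..` = 0)
  predict(fit, newx = X, s = glmLam, type = "link", exact = FALSE)
}

coefGlmnet <- function(fit, s, p) {
  cf <- as.matrix(predict(fit, s = s, type = "coefficients", exact = FALSE))
  beta <- cf[-1, 1]
  if (isTRUE(attr(fit, "pad"))) beta <- beta[seq_len(p)]
  list(a0 = unname(cf[1, 1]), beta = unname(beta))
}

#' Decision score of an allele model
#'
#' `f(x) = a0 + x' beta` over the model's retained features. The intercept
#' is included; Platt recalibration absorbs any affine shift, so
#' downstream probabilities are unaffected by that convention.
#'
#' @param model an [AlleleModel-class].
#' @param X binary matrix (or vector) over the model's feature columns; if
#'   `X` has column names they are matched against the model's
#'   `"family|cdr3|mode"` ids, or against the plain column names the model
#'   was fit on when the design was arbitrarily named.
#' @return numeric score vector.
#' @export
decisionScore <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  ids <- paste(model@features$trbv_family, model@features$cdr3_aa,
               model@features$mode, sep = "|")
  if (!is.null(colnames(X))) {
    if (all(ids %in% colnames(X))) X <- X[, ids, drop = FALSE]
    else if (all(model@features$cdr3_aa %in% colnames(X)))
      X <- X[, model@features$cdr3_aa, drop = FALSE]
  }
  stopIfNot(ncol(X) == length(model@beta),
            "feature dimension mismatch with model")
  as.numeric(model@intercept + X %*% model@beta)
}

#' Write / read an allele model as JSON
#'
#' Doubles are serialized at 17 significant digits, so a write/read cycle
#' reproduces the model bit-exactly and repeated runs with the same seed
#' produce byte-identical files.
#'
#' @param model an [AlleleModel-class].
#' @param path JSON file path.
#' @return `path` invisibly; `readAlleleModel` returns the model.
#' @export
writeAlleleModel <- function(model, path) {
  cv <- model@cv
  if (!is.null(cv$foldAuroc)) cv$foldAuroc <- as.matrix(cv$foldAuroc)
  obj <- list(format_version = model@version, allele = model@allele,
              features = model@features, beta = model@beta,
              intercept = model@intercept, lambda = model@lambda,
              ipw = as.list(setNames(model@ipw, c("n1", "n0"))),
              cv = cv, calibration = lapply(model@calibration, as.list))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname writeAlleleModel
#' @export
readAlleleModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cv <- obj$cv
  if (!is.null(cv$foldAuroc)) cv$foldAuroc <- as.matrix(cv$foldAuroc)
  if (!is.null(cv$nFolds)) cv$nFolds <- as.integer(cv$nFolds)
  if (!is.null(cv$seed)) cv$seed <- as.integer(cv$seed)
  calib <- lapply(obj$calibration, function(v) {
    nm <- names(v); v <- as.numeric(v); names(v) <- nm; v
  })
  new("AlleleModel", allele = obj$allele,
      features = as.data.frame(obj$features),
      beta = as.numeric(obj$beta), intercept = as.numeric(obj$intercept),
      lambda = as.numeric(obj$lambda),
      ipw = c(n1 = as.numeric(obj$ipw$n1), n0 = as.numeric(obj$ipw$n0)),
      cv = cv, calibration = calib, version = obj$format_version)
}
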