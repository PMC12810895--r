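#' Calibration parameter container
#'
#' @param A,B Platt slope and offset.
#' @param C1,C2 coefficients of the first- and second-degree terms in
#'   `u = log10(unique clones)`; zero in standard mode.
#' @param mode `"standard"` or `"high_sensitivity"`.
#' @return a `calibration_params` list.
#' @export
calibrationParams <- function(A, B, C1 = 0, C2 = 0,
                              mode = c("standard", "high_sensitivity")) {
  mode <- match.arg(mode)
  stopIfNot(all(is.finite(c(A, B, C1, C2))),
            "calibration parameters must be finite")
  structure(list(mode = mode, A = A, B = B, C1 = C1, C2 = C2),
            class = "calibration_params")
}

# penalized logistic log-likelihood maximized by both calibration fits;
# the tiny ridge keeps the optimum finite under perfect separation
fitSigmoid <- function(Z, y, ridge = 1e-6, init = NULL) {
  if (is.null(init)) init <- rep(0, ncol(Z))
  nll <- function(th) {
    eta <- as.numeric(Z %*% th)
    -sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE)) +
      ridge * sum(th^2)
  }
  grd <- function(th) {
    eta <- as.numeric(Z %*% th)
    as.numeric(crossprod(Z, plogis(eta) - y)) + 2 * ridge * th
  }
  opt <- optim(init, nll, grd, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt$par
}

#' Fit standard Platt scaling
#'
#' Maximum-likelihood sigmoid `sigma(A f + B)` mapping decision scores to
#' probabilities, fit by unweighted logistic likelihood with a ridge term
#' `1e-6` on `(A, B)` that guarantees a finite optimum under perfectly
#' separated scores. `A` is positive when higher scores indicate the
#' positive class.
#'
#' @param scores decision scores `f`.
#' @param labels binary labels (both classes present).
#' @param ridge ridge coefficient.
#' @return a `calibration_params` list, mode `"standard"`.
#' @export
fitPlatt <- function(scores, labels, ridge = 1e-6) {
  stopIfNot(length(unique(labels)) == 2, "both classes required")
  th <- fitSigmoid(cbind(scores, 1), as.integer(labels), ridge,
                   init = c(1, 0))
  calibrationParams(A = th[1], B = th[2], mode = "standard")
}

#' Fit the high-sensitivity (diversity-adjusted) calibration
#'
#' Four-parameter sigmoid `sigma(A f + B + C1 u + C2 u^2)` with
#' `u = log10(U)`, `U` the number of unique clonotypes above frequency
#' 2e-6; `(A, B, C1, C2)` are fit jointly, intended for the repeatedly
#' downsampled calibration set from [buildCalibrationSet]. When `u` is
#' constant the ridge keeps the fit defined and the result behaves like
#' standard Platt scaling.
#'
#' @param scores decision scores `f`.
#' @param labels binary labels.
#' @param u `log10(unique clones)` per sample, finite.
#' @param ridge ridge coefficient.
#' @return a `calibration_params` list, mode `"high_sensitivity"`.
#' @export
fitHsCalibration <- function(scores, labels, u, ridge = 1e-6) {
  stopIfNot(length(unique(labels)) == 2, "both classes required")
  stopIfNot(all(is.finite(u)), "u must be finite (log10 of unique clones)")
  th <- fitSigmoid(cbind(scores, 1, u, u^2), as.integer(labels), ridge,
                   init = c(1, 0, 0, 0))
  calibrationParams(A = th[1], B = th[2], C1 = th[3], C2 = th[4],
                    mode = "high_sensitivity")
}

#' Map a decision score to a calibrated probability
#'
#' @param f decision score(s).
#' @param u `log10(unique clones)`; required in high-sensitivity mode,
#'   ignored in standard mode.
#' @param params a `calibration_params` list.
#' @return probabilities in (0, 1).
#' @export
calibrate <- function(f, u = NULL, params) {
  eta <- params$A * f + params$B
  if (params$mode == "high_sensitivity") {
    stopIfNot(!is.null(u), "high-sensitivity mode needs u = log10(U)")
    eta <- eta + params$C1 * u + params$C2 * u^2
  }
  plogis(eta)
}

#' Confidence gate on calibrated probabilities
#'
#' Retains only high-confidence predictions: `p < low` (confident negative)
#' or `p > high` (confident positive); anything in `[low, high]`, including
#' the boundaries, is masked.
#'
#' @param p probabilities.
#' @param low,high gate bounds (defaults 0.1 and 0.9).
#' @return logical vector: retained.
#' @export
gatePredictions <- function(p, low = 0.1, high = 0.9) {
  stopIfNot(low < high, "gate bounds must satisfy low < high")
  p < low | p > high
}

#' Expected calibration error
#'
#' Mean absolute gap between predicted probability and empirical positive
#' rate over equal-width probability bins, weighted by bin occupancy.
#'
#' @param p probabilities; `y` binary labels.
#' @param y binary labels.
#' @param bins number of equal-width bins.
#' @return scalar ECE.
#' @export
expectedCalibrationError <- function(p, y, bins = 10L) {
  b <- pmin(pmax(ceiling(p * bins), 1L), bins)
  ece <- 0
  for (k in seq_len(bins)) {
    i <- which(b == k)
    if (!length(i)) next
    ece <- ece + length(i) / length(p) * abs(mean(y[i]) - mean(p[i]))
  }
  ece
}

#' Attach fitted calibrations to an allele model
#'
#' Fits standard Platt scaling on the supplied (typically full training)
#' scores, and — when `hsData` is given — the high-sensitivity calibration
#' jointly on the downsampled replicates.
#'
#' @param model an [AlleleModel-class].
#' @param scores,labels training decision scores and labels.
#' @param hsData optional list with `scores`, `labels`, `u` from the
#'   downsampled calibration set.
#' @return the model with its `calibration` slot populated.
#' @export
calibrateModel <- function(model, scores, labels, hsData = NULL) {
  cal <- model@calibration
  ps <- fitPlatt(scores, labels)
  cal$standard <- c(A = ps$A, B = ps$B)
  if (!is.null(hsData)) {
    ph <- fitHsCalibration(hsData$scores, hsData$labels, hsData$u)
    cal$high_sensitivity <- c(A = ph$A, B = ph$B, C1 = ph$C1, C2 = ph$C2)
  }
  model@calibration <- cal
  model
}

modelCalibration <- function(model, mode) {
  key <- if (mode == "standard") "standard" else "high_sensitivity"
  v <- model@calibration[[key]]
  if (is.null(v)) return(NULL)
  calibrationParams(A = v[["A"]], B = v[["B"]],
                    C1 = if (key == "standard") 0 else v[["C1"]],
                    C2 = if (key == "standard") 0 else v[["C2"]],
                    mode = key)
}

#' Predict HLA genotype probabilities for repertoires
#'
#' Featurizes each repertoire against the model (detection at productive
#' frequency above `freqThreshold`; the richness covariate `U` is
#' recomputed from the clonotypes at prediction time, never read from file
#' metadata), scores it, applies the requested calibration, thresholds at
#' 0.5 and gates by confidence.
#'
#' @param model a calibrated [AlleleModel-class].
#' @param repertoires list of [TcrRepertoire-class].
#' @param calibration `"standard"` or `"high_sensitivity"`.
#' @param freqThreshold detection threshold.
#' @param gate numeric(2) confidence gate `(low, high)`.
#' @return data.frame: `sample_id`, `subject_id`, `allele`, `n_exact_hits`,
#'   `n_edit1_hits`, `f`, `U`, `u`, `p_standard`, `p_hs`, `p`, `call`,
#'   `retained`, `calibration_mode`.
#' @export
predictGenotype <- function(model, repertoires,
                            calibration = c("standard", "high_sensitivity"),
                            freqThreshold = 2e-6, gate = c(0.1, 0.9)) {
  calibration <- match.arg(calibration)
  ids <- vapply(repertoires, sampleId, "")
  det <- rbindlist(lapply(repertoires, function(r)
    cbind(sample_id = sampleId(r), detectionSet(r, freqThreshold))))
  X <- featurize(det, model@features, sampleIds = ids)
  f <- decisionScore(model, X)
  U <- vapply(repertoires, uniqueClones, 0L, freqThreshold = freqThreshold)
  u <- log10(pmax(U, 1L))

  pstd <- phs <- rep(NA_real_, length(ids))
  cs <- modelCalibration(model, "standard")
  if (!is.null(cs)) pstd <- calibrate(f, params = cs)
  ch <- modelCalibration(model, "high_sensitivity")
  if (!is.null(ch)) phs <- calibrate(f, u = u, params = ch)
  p <- if (calibration == "standard") pstd else phs
  stopIfNot(!all(is.na(p)),
            paste("model lacks", calibration, "calibration"))

  data.frame(sample_id = ids,
             subject_id = vapply(repertoires, subjectId, ""),
             allele = model@allele,
             n_exact_hits = rowSums(X[, model@features$mode == "exact",
                                      drop = FALSE]),
             n_edit1_hits = rowSums(X[, model@features$mode == "edit1",
                                      drop = FALSE]),
             f = f, U = U, u = u, p_standard = pstd, p_hs = phs, p = p,
             call = as.integer(p > 0.5),
             retained = gatePredictions(p, gate[1], gate[2]),
             calibration_mode = calibration,
             stringsAsFactors = FALSE, row.names = NULL)
}
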