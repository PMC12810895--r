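#' TcrRepertoire: one sample's productive TCR-beta clonotypes
#'
#' Container for a single repertoire sample: one row per clonotype with the
#' raw TRBV gene call, its normalized IMGT family, the CDR3 amino-acid
#' sequence, the template (molecule) count and the productive frequency
#' (templates / total productive templates of the sample).
#'
#' @slot sampleId character(1), unique within a cohort.
#' @slot subjectId character(1); one subject may own several samples.
#' @slot clonotypes data.frame with columns `trbv_gene`, `trbv_family`,
#'   `cdr3_aa`, `templates`, `productive_frequency`.
#' @slot metadata named list of free-form annotations (age group, cohort tag,
#'   rows dropped at parse time, ...).
#'
#' @examples
#' rep <- TcrRepertoire("s1", "subj1",
#'   data.frame(trbv_gene = "TRBV9*01", trbv_family = "TRBV9",
#'              cdr3_aa = "CASSLGETQYF", templates = 4L,
#'              productive_frequency = 1))
#' uniqueClones(rep)
#' @export
setClass("TcrRepertoire",
  representation(sampleId = "character", subjectId = "character",
                 clonotypes = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("TcrRepertoire", function(object) {
  cl <- object@clonotypes
  need <- c("trbv_family", "cdr3_aa", "templates", "productive_frequency")
  msgs <- character()
  if (!all(need %in% names(cl)))
    msgs <- c(msgs, paste("clonotypes must have columns:",
                          paste(setdiff(need, names(cl)), collapse = ", ")))
  else if (nrow(cl)) {
    if (any(cl$templates < 1)) msgs <- c(msgs, "templates must be >= 1")
    if (!all(grepl(CDR3_REGEX, cl$cdr3_aa)))
      msgs <- c(msgs, "cdr3_aa must contain only the 20 standard amino acids")
    if (abs(sum(cl$productive_frequency) - 1) > 1e-9)
      msgs <- c(msgs, "productive_frequency must sum to 1 over the sample")
  }
  if (length(object@sampleId) != 1L) msgs <- c(msgs, "sampleId must be length 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TcrRepertoire-class
#' @param sampleId,subjectId sample and subject identifiers.
#' @param clonotypes clonotype data.frame (see slots).
#' @param metadata named list.
#' @export
TcrRepertoire <- function(sampleId, subjectId = sampleId, clonotypes,
                          metadata = list()) {
  clonotypes <- as.data.frame(clonotypes)
  new("TcrRepertoire", sampleId = as.character(sampleId),
      subjectId = as.character(subjectId), clonotypes = clonotypes,
      metadata = metadata)
}

#' Edit1Index: position-masked string index for edit-distance-1 lookup
#'
#' Locality-sensitive index over the CDR3 sequences of one TRBV family.
#' Each indexed string is keyed by (i) its raw sequence, (ii) every
#' single-position masked pattern (length and masked position are part of
#' the key so patterns never collide across lengths), and (iii) every
#' single-deletion variant. Queries recover all indexed strings within one
#' substitution, insertion or deletion — and nothing else: deletion-variant
#' tables are only ever joined against raw strings, so two same-length
#' strings sharing a deletion variant (e.g. "AB"/"BA") can never meet.
#'
#' @slot family TRBV family label shared by every indexed string.
#' @slot strings the indexed CDR3 sequences (unique).
#' @slot subs data.table (key, cdr3): masked substitution patterns.
#' @slot dels data.table (variant, cdr3): single-deletion variants.
#' @export
setClass("Edit1Index",
  representation(family = "character", strings = "character",
                 subs = "data.frame", dels = "data.frame"))

#' AlleleModel: a fitted per-allele HLA genotype classifier
#'
#' Sparse L1-logistic model over binary exact and edit-1 anchor feature
#' detections, with inverse-probability class weights, the cross-validation
#' trace used to pick the penalty, and both calibration parameter sets
#' (standard Platt `(A, B)` and high-sensitivity `(A, B, C1, C2)` where the
#' extra terms are a polynomial in `u = log10(unique clones)`).
#'
#' @slot allele HLA allele name, e.g. `"A*02:01"`.
#' @slot features data.frame with columns `trbv_family`, `cdr3_aa`,
#'   `mode` (`"exact"` or `"edit1"`), ordered as the weight vector.
#' @slot beta numeric weight vector, one per feature.
#' @slot intercept numeric(1), unpenalized.
#' @slot lambda numeric(1): selected L1 penalty (on the weighted-objective
#'   scale where each class carries total weight 1).
#' @slot ipw numeric(2) `c(n1, n0)`: class counts behind the weights.
#' @slot cv list: `lambdaGrid`, `meanAuroc`, `foldAuroc`, `nFolds`, `seed`.
#' @slot calibration list with elements `standard` = c(A, B) and
#'   `high_sensitivity` = c(A, B, C1, C2) (either may be absent before
#'   calibration).
#' @slot version model file format version.
#' @export
setClass("AlleleModel",
  representation(allele = "character", features = "data.frame",
                 beta = "numeric", intercept = "numeric", lambda = "numeric",
                 ipw = "numeric", cv = "list", calibration = "list",
                 version = "character"),
  prototype(cv = list(), calibration = list(), version = "1"))

setValidity("AlleleModel", function(object) {
  msgs <- character()
  if (nrow(object@features) != length(object@beta))
    msgs <- c(msgs, "length(beta) must equal nrow(features)")
  if (!all(object@features$mode %in% c("exact", "edit1")))
    msgs <- c(msgs, "feature mode must be 'exact' or 'edit1'")
  if (length(object@lambda) == 1 && !is.na(object@lambda) &&
      object@lambda <= 0)
    msgs <- c(msgs, "lambda must be > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TcrRepertoire", function(object) {
  cat(sprintf("TcrRepertoire '%s' (subject '%s'): %d clonotypes, %d templates\n",
              object@sampleId, object@subjectId, nrow(object@clonotypes),
              sum(object@clonotypes$templates)))
  cat(sprintf("  unique clones above 2e-6: %d\n", uniqueClones(object)))
})

setMethod("show", "Edit1Index", function(object) {
  cat(sprintf("Edit1Index [%s]: %d CDR3 sequences, %d masked patterns, %d deletion variants\n",
              object@family, length(object@strings), nrow(object@subs),
              nrow(object@dels)))
})

setMethod("show", "AlleleModel", function(object) {
  nz <- sum(object@beta != 0)
  cat(sprintf("AlleleModel for %s: %d features (%d exact, %d edit1), %d nonzero weights\n",
              object@allele, nrow(object@features),
              sum(object@features$mode == "exact"),
              sum(object@features$mode == "edit1"), nz))
  cat(sprintf("  lambda = %.4g; class counts n1 = %d, n0 = %d\n",
              object@lambda, object@ipw[1], object@ipw[2]))
  if (length(object@calibration))
    cat("  calibration:", paste(names(object@calibration), collapse = ", "), "\n")
})

#' @describeIn TcrRepertoire-class sample identifier
#' @param x a TcrRepertoire.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn TcrRepertoire-class subject identifier
#' @export
subjectId <- function(x) x@subjectId

#' @describeIn TcrRepertoire-class clonotype table
#' @export
clonotypes <- function(x) x@clonotypes

#' @describeIn AlleleModel-class ordered model feature table
#' @param object an AlleleModel.
#' @export
modelFeatures <- function(object) object@features

#' @describeIn AlleleModel-class weight vector (named by feature id)
#' @export
modelWeights <- function(object) {
  setNames(object@beta,
           featureId(object@features$trbv_family, object@features$cdr3_aa))
}

# canonical feature identifier used throughout: "<family>|<cdr3>"
featureId <- function(family, cdr3) paste(family, cdr3, sep = "|")
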