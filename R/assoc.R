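#' Screen configuration for feature discovery
#'
#' Bundles the association-screen thresholds: Fisher p below `pThreshold`,
#' odds ratio above `orThreshold`, detection in at least `minPublicity`
#' repertoires, and detection in fewer than `maxNegRate` of HLA-mismatched
#' (allele-negative) repertoires — i.e. absent in more than 90% of them at
#' the default. `freqThreshold` is the per-sample detection rule and
#' `minTemplates` the expanded-clone restriction on the candidate feature
#' space (clones seen in more than one template).
#'
#' @param pThreshold Fisher p cutoff (default `1e-8`).
#' @param orThreshold odds-ratio cutoff, strict (default 1).
#' @param maxNegRate maximum allele-negative detection fraction (default 0.10).
#' @param minPublicity minimum number of detecting repertoires (default 5).
#' @param freqThreshold productive-frequency detection threshold (default 2e-6).
#' @param minTemplates template floor for the candidate universe (default 2).
#' @return a `screen_config` list carrying its own provenance hash.
#' @export
screenConfig <- function(pThreshold = 1e-8, orThreshold = 1,
                         maxNegRate = 0.10, minPublicity = 5L,
                         freqThreshold = 2e-6, minTemplates = 2L) {
  stopIfNot(all(c(pThreshold, orThreshold, maxNegRate, minPublicity,
                  freqThreshold, minTemplates) > 0),
            "all screen thresholds must be positive")
  cfg <- list(pThreshold = pThreshold, orThreshold = orThreshold,
              maxNegRate = maxNegRate, minPublicity = as.integer(minPublicity),
              freqThreshold = freqThreshold,
              minTemplates = as.integer(minTemplates))
  cfg$hash <- configHash(cfg)
  class(cfg) <- "screen_config"
  cfg
}

#' Fisher's exact test on 2x2 tables, vectorized
#'
#' Exact conditional test with both margins fixed: the two-sided p-value
#' sums hypergeometric probabilities no greater than that of the observed
#' table (with the customary 1 + 1e-7 relative slack for ties). The odds
#' ratio is the sample ratio `a*d / (b*c)`, `+Inf` when `b*c = 0` with
#' `a*d > 0`, and `NA` (flagged) when both products vanish, including the
#' all-zero table whose p is 1 by convention.
#'
#' @param a,b,c,d non-negative integer vectors: `a` detected & allele+,
#'   `b` detected & allele-, `c` undetected & allele+, `d` undetected &
#'   allele-.
#' @return data.frame with columns `odds_ratio`, `p_value`, `flagged`.
#' @examples
#' fisherExact2x2(5, 0, 0, 5)  # p = 2/252
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  stopIfNot(all(c(a, b, c, d) >= 0), "counts must be non-negative")

  key <- paste(a, b, c, d)
  uk <- !duplicated(key)
  pOne <- function(a, b, c, d) {
    N <- a + b + c + d
    if (N == 0) return(1)
    K <- a + c          # allele-positive margin
    m <- a + b          # detected margin
    lo <- max(0, m - (N - K)); hi <- min(m, K)
    x <- lo:hi
    px <- dhyper(x, K, N - K, m)
    sum(px[px <= px[x == a] * (1 + 1e-7)])
  }
  pu <- mapply(pOne, a[uk], b[uk], c[uk], d[uk])
  p <- unname(pu[match(key, key[uk])])

  ad <- a * d; bc <- b * c
  or <- ifelse(bc > 0, ad / bc, ifelse(ad > 0, Inf, NA_real_))
  data.frame(odds_ratio = or, p_value = p, flagged = is.na(or))
}

#' Tabulate feature occurrence across samples
#'
#' Builds the binary samples x features detection matrix in either mode:
#' `"exact"` marks a sample iff the `(trbv_family, cdr3_aa)` pair is in its
#' detection set; `"edit1"` marks it iff any same-family clonotype within
#' one substitution, insertion or deletion (including the exact sequence)
#' is detected. The edit-1 matrix therefore dominates the exact matrix
#' elementwise.
#'
#' @param detections data.table of detections with columns `sample_id`,
#'   `trbv_family`, `cdr3_aa` (e.g. rbind of [detectionSet] outputs).
#' @param features data.frame of candidate features (`trbv_family`,
#'   `cdr3_aa`).
#' @param mode `"exact"` or `"edit1"`.
#' @param sampleIds row universe; defaults to the samples present in
#'   `detections`.
#' @return sparse [Matrix::sparseMatrix] (dgCMatrix, 0/1) with sample rows
#'   and `"family|cdr3"` feature columns.
#' @export
buildOccurrence <- function(detections, features, mode = c("exact", "edit1"),
                            sampleIds = NULL) {
  mode <- match.arg(mode)
  det <- as.data.table(detections)
  feats <- unique(as.data.table(features)[, c("trbv_family", "cdr3_aa")])
  if (is.null(sampleIds)) sampleIds <- sortC(unique(det$sample_id))
  fid <- featureId(feats$trbv_family, feats$cdr3_aa)

  if (mode == "exact") {
    hits <- det[feats, on = c("trbv_family", "cdr3_aa"), nomatch = 0L]
    hi <- match(hits$sample_id, sampleIds)
    hj <- match(featureId(hits$trbv_family, hits$cdr3_aa), fid)
  } else {
    pieces <- list()
    for (fam in sortC(unique(feats$trbv_family))) {
      fs <- feats[feats$trbv_family == fam]
      ds <- det[det$trbv_family == fam]
      if (!nrow(ds)) next
      idx <- buildEdit1Index(fs$cdr3_aa, fam)
      pairs <- queryEdit1Many(idx, unique(ds$cdr3_aa))
      if (!nrow(pairs)) next
      m <- merge(ds, pairs, by.x = "cdr3_aa", by.y = "query",
                 allow.cartesian = TRUE)
      pieces[[fam]] <- data.table(sample_id = m$sample_id,
                                  fid = featureId(fam, m$neighbor))
    }
    hits <- unique(rbindlist(pieces))
    hi <- match(hits$sample_id, sampleIds)
    hj <- match(hits$fid, fid)
  }
  keep <- !is.na(hi) & !is.na(hj)
  Matrix::sparseMatrix(i = hi[keep], j = hj[keep], x = 1,
                       dims = c(length(sampleIds), length(fid)),
                       dimnames = list(sampleIds, fid), use.last.ij = TRUE)
}

# per-feature 2x2 counts against one binary label vector (NA labels drop
# the sample from this allele's table only)
associationCounts <- function(occurrence, y) {
  stopIfNot(length(y) == nrow(occurrence),
            "label vector must align with occurrence rows")
  pos <- which(!is.na(y) & y == 1)
  neg <- which(!is.na(y) & y == 0)
  a <- Matrix::colSums(occurrence[pos, , drop = FALSE])
  b <- Matrix::colSums(occurrence[neg, , drop = FALSE])
  data.table(feature_id = colnames(occurrence),
             a = as.numeric(a), b = as.numeric(b),
             c = length(pos) - as.numeric(a),
             d = length(neg) - as.numeric(b),
             publicity = as.numeric(Matrix::colSums(occurrence)))
}

#' Screen features for HLA association
#'
#' Applies the association screen for one allele: detection in at least
#' `minPublicity` repertoires, odds ratio above `orThreshold`, Fisher p
#' below `pThreshold`, and allele-negative detection rate below
#' `maxNegRate`. Fisher p-values are only computed for features surviving
#' the count-based filters (the others cannot pass). Missing labels drop a
#' sample from this allele's table only.
#'
#' @param occurrence samples x features matrix from [buildOccurrence].
#' @param y per-sample binary labels aligned with `rownames(occurrence)`
#'   (NA allowed).
#' @param config a [screenConfig].
#' @param allele allele name stamped on the results.
#' @param mode occurrence mode stamped on the results.
#' @return data.frame of passing features, sorted by p ascending (ties by
#'   feature id), with columns `feature_id`, `trbv_family`, `cdr3_aa`,
#'   `allele`, `mode`, `a`..`d`, `odds_ratio`, `p_value`, `publicity`,
#'   `neg_detection_rate` and the screen-config hash.
#' @export
discoverFeatures <- function(occurrence, y, config = screenConfig(),
                             allele = NA_character_,
                             mode = NA_character_) {
  if (sum(y == 1, na.rm = TRUE) == 0) {
    warning("no allele-positive samples for ", allele, "; skipping")
    return(emptyAssociation(config))
  }
  ct <- associationCounts(occurrence, y)
  ct[, neg_detection_rate := ifelse(b + d > 0, b / (b + d), 0)]
  ct[, odds_ratio := ifelse(b * c > 0, (a * d) / (b * c),
                            ifelse(a * d > 0, Inf, NA_real_))]
  cand <- ct[ct$publicity >= config$minPublicity &
             !is.na(ct$odds_ratio) & ct$odds_ratio > config$orThreshold &
             ct$neg_detection_rate < config$maxNegRate]
  if (!nrow(cand)) return(emptyAssociation(config))
  ft <- fisherExact2x2(cand$a, cand$b, cand$c, cand$d)
  cand[, p_value := ft$p_value]
  out <- cand[cand$p_value < config$pThreshold]
  if (!nrow(out)) return(emptyAssociation(config))
  out <- out[orderC(out$p_value, out$feature_id)]
  parts <- strsplit(out$feature_id, "|", fixed = TRUE)
  data.frame(feature_id = out$feature_id,
             trbv_family = vapply(parts, `[`, "", 1L),
             cdr3_aa = vapply(parts, `[`, "", 2L),
             allele = allele, mode = mode,
             a = out$a, b = out$b, c = out$c, d = out$d,
             odds_ratio = out$odds_ratio, p_value = out$p_value,
             publicity = out$publicity,
             neg_detection_rate = out$neg_detection_rate,
             screen_hash = config$hash, stringsAsFactors = FALSE)
}

emptyAssociation <- function(config) {
  data.frame(feature_id = character(), trbv_family = character(),
             cdr3_aa = character(), allele = character(), mode = character(),
             a = numeric(), b = numeric(), c = numeric(), d = numeric(),
             odds_ratio = numeric(), p_value = numeric(),
             publicity = numeric(), neg_detection_rate = numeric(),
             screen_hash = character(), stringsAsFactors = FALSE)
}

#' Prune features lacking exact-sequence enrichment
#'
#' Edit-1 screening can admit sequences whose neighborhood is HLA-enriched
#' while the sequence itself is not (a spurious-feature mode); such nodes
#' are pruned when their exact-mode odds ratio is below 1. An exact OR of
#' exactly 1 is kept (the rule is strict). Features with zero exact
#' detections among labeled samples have an undefined exact OR; whether
#' that counts as lacking enrichment is configurable and defaults to prune.
#'
#' @param candidates data.frame from [discoverFeatures] (edit-1 screen).
#' @param exactOr named numeric vector: exact-mode odds ratio per
#'   `feature_id` (NA = undefined).
#' @param keepUndefined keep features whose exact OR is undefined
#'   (default FALSE).
#' @return the surviving subset of `candidates`.
#' @export
pruneNonenriched <- function(candidates, exactOr, keepUndefined = FALSE) {
  if (!nrow(candidates)) return(candidates)
  or <- exactOr[candidates$feature_id]
  keep <- ifelse(is.na(or), keepUndefined, or >= 1)
  candidates[keep, , drop = FALSE]
}
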