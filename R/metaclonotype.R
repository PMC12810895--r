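#' Exclude candidates similar to reference features
#'
#' Removes candidate TCRs that share a TRBV family with any reference
#' feature and differ by at most one amino-acid substitution, insertion or
#' deletion in the CDR3 — i.e. everything the reference models could
#' already see through their edit-1 neighborhoods. Cross-family near-
#' matches are kept. Idempotent.
#'
#' @param candidates data.frame with `trbv_family`, `cdr3_aa` (extra
#'   columns pass through).
#' @param referenceFeatures data.frame with `trbv_family`, `cdr3_aa`.
#' @return the novel subset of `candidates`.
#' @export
excludeReferenceLike <- function(candidates, referenceFeatures) {
  if (!nrow(candidates) || !nrow(referenceFeatures)) return(candidates)
  drop <- rep(FALSE, nrow(candidates))
  for (fam in unique(candidates$trbv_family)) {
    refs <- referenceFeatures$cdr3_aa[referenceFeatures$trbv_family == fam]
    if (!length(refs)) next
    i <- which(candidates$trbv_family == fam)
    idx <- buildEdit1Index(refs, fam)
    hit <- queryEdit1Many(idx, candidates$cdr3_aa[i])
    drop[i] <- candidates$cdr3_aa[i] %in% hit$query
  }
  candidates[!drop, , drop = FALSE]
}

#' Discover novel HLA-associated features under imputed genotypes
#'
#' Runs the association screen against confidence-gated (imputed) allele
#' labels — samples masked by the gate carry `NA` and drop out of every
#' 2x2 table — then removes candidates within edit distance 1 of any
#' same-family reference feature.
#'
#' @param occurrence samples x features matrix from [buildOccurrence].
#' @param y gated per-sample labels: 0/1 for retained predictions, NA for
#'   masked samples.
#' @param config a [screenConfig].
#' @param referenceFeatures reference feature table (`trbv_family`,
#'   `cdr3_aa`).
#' @param allele,mode annotations stamped on the results.
#' @return data.frame of novel passing features (see [discoverFeatures]).
#' @export
discoverNovel <- function(occurrence, y, config = screenConfig(),
                          referenceFeatures = NULL,
                          allele = NA_character_, mode = "edit1") {
  if (sum(y == 1, na.rm = TRUE) < 5) {
    warning("fewer than 5 gated-positive samples for ", allele,
            "; skipping")
    return(emptyAssociation(config))
  }
  res <- discoverFeatures(occurrence, y, config, allele = allele, mode = mode)
  if (!is.null(referenceFeatures) && nrow(res))
    res <- excludeReferenceLike(res, referenceFeatures)
  res
}

# minimal-cost placement of a single contiguous gap of length g when
# aligning a short string to a long one; returns the split point k
# (positions 1..k align left of the gap) and per-position alignment
bestGapSplit <- function(shortV, longV, g) {
  m <- length(shortV)
  bestK <- 0L; bestCost <- Inf
  for (k in 0:m) {
    idx <- c(seq_len(k), if (k < m) (k + g + 1):(m + g) else integer())
    cost <- sum(shortV != longV[idx])
    if (cost < bestCost) { bestCost <- cost; bestK <- k }
  }
  bestK
}

#' Build a CDR3 regex motif for a meta-clonotype
#'
#' Aligns every member to the anchor: equal-length members contribute
#' per-position residue classes (a single observed residue stays a
#' literal, several become a character class); members shorter by `g`
#' replace their gapped anchor positions with an optional wildcard
#' `.{0,1}` (placed at the minimal-mismatch gap position); members longer
#' by `g` insert an optional `.{0,g}` group there. The regex is anchored
#' at both ends, and by construction the anchor and all members
#' full-match it.
#'
#' @param anchorCdr3 the anchor CDR3.
#' @param memberCdr3s character vector of member CDR3s (may be empty).
#' @return anchored regex string, e.g. `"^CASS[LV]APGATNEKLFF$"`.
#' @examples
#' clusterRegex("CASSLAPGATNEKLFF", "CASSVAPGATNEKLFF")
#' @export
clusterRegex <- function(anchorCdr3, memberCdr3s = character()) {
  av <- strsplit(anchorCdr3, "")[[1]]
  L <- length(av)
  classes <- lapply(av, identity)           # residue sets per anchor position
  optionalPos <- logical(L)                 # positions gapped by short members
  insAfter <- integer(L + 1)                # .{0,g} inserted after position k

  for (mem in memberCdr3s) {
    mv <- strsplit(mem, "")[[1]]
    g <- length(mv) - L
    if (g == 0) {
      for (i in seq_len(L)) classes[[i]] <- union(classes[[i]], mv[i])
    } else if (g < 0) {                     # member shorter: gap in member
      k <- bestGapSplit(mv, av, -g)
      optionalPos[(k + 1):(k - g)] <- TRUE
      for (i in seq_len(k)) classes[[i]] <- union(classes[[i]], mv[i])
      if (k < length(mv))
        for (i in (k + 1):length(mv))
          classes[[i - g]] <- union(classes[[i - g]], mv[i])
    } else {                                # member longer: gap in anchor
      k <- bestGapSplit(av, mv, g)
      insAfter[k + 1L] <- max(insAfter[k + 1L], g)
      for (i in seq_len(k)) classes[[i]] <- union(classes[[i]], mv[i])
      if (k < L)
        for (i in (k + 1):L) classes[[i]] <- union(classes[[i]], mv[i + g])
    }
  }

  tok <- character(0)
  for (i in 0:L) {
    if (i >= 1) {
      if (optionalPos[i]) tok <- c(tok, ".{0,1}")
      else {
        cls <- sortC(classes[[i]])
        tok <- c(tok, if (length(cls) == 1) cls
                      else paste0("[", paste(cls, collapse = ""), "]"))
      }
    }
    if (insAfter[i + 1L] > 0)
      tok <- c(tok, sprintf(".{0,%d}", insAfter[i + 1L]))
  }
  paste0("^", paste(tok, collapse = ""), "$")
}

#' Cluster novel features into meta-clonotypes
#'
#' Builds the TCRdist similarity graph over the features (radius 14 by
#' default), runs the greedy maximum-degree anchor selection, and turns
#' each anchor plus its first-degree neighbors at selection time into one
#' meta-clonotype with a CDR3 regex motif. Membership is frozen when an
#' anchor is selected: removed neighbors can never join a second cluster.
#' Degree-0/1 features that are never anchored are returned as singletons.
#'
#' @param features data.frame with `trbv_family`, `cdr3_aa` and optionally
#'   `allele`, `publicity`, `odds_ratio`, `p_value`.
#' @param radius TCRdist cutoff.
#' @param params a [tcrdistParams] list.
#' @return list with `metaclonotypes` (data.frame: `id`, `allele`,
#'   `trbv_family`, `anchor_cdr3`, `n_members`, `regex`, plus a `members`
#'   list-column of member CDR3s) and `singletons` (character feature ids).
#' @export
buildMetaclonotypes <- function(features, radius = 14,
                                params = tcrdistParams()) {
  features <- unique(as.data.frame(features))
  empty <- list(metaclonotypes = data.frame(id = character(),
                                            allele = character(),
                                            trbv_family = character(),
                                            anchor_cdr3 = character(),
                                            n_members = integer(),
                                            regex = character()),
                singletons = character())
  if (!nrow(features)) return(empty)
  g <- buildGraph(features, radius = radius, params = params)
  sel <- greedyAnchors(g)
  if (!nrow(sel$anchors)) {
    empty$singletons <- sortC(igraph::V(g)$name)
    return(empty)
  }
  nm <- igraph::V(g)$name
  fam <- setNames(igraph::V(g)$trbv_family, nm)
  cdr <- setNames(igraph::V(g)$cdr3_aa, nm)
  alle <- if ("allele" %in% names(features))
    setNames(features$allele, nm) else setNames(rep(NA_character_,
                                                    length(nm)), nm)
  mc <- sel$anchors
  out <- data.frame(
    id = sprintf("mc_%03d", seq_len(nrow(mc))),
    allele = unname(alle[mc$anchor]),
    trbv_family = unname(fam[mc$anchor]),
    anchor_cdr3 = unname(cdr[mc$anchor]),
    n_members = mc$n_neighbors,
    regex = vapply(seq_len(nrow(mc)), function(i)
      clusterRegex(cdr[[mc$anchor[i]]], unname(cdr[mc$members[[i]]])), ""),
    stringsAsFactors = FALSE)
  out$members <- lapply(mc$members, function(m) unname(cdr[m]))
  list(metaclonotypes = out, singletons = sel$residuals)
}

#' Meta-clonotype prevalence by exposure and genotype strata
#'
#' A sample detects a meta-clonotype iff it carries at least one clonotype
#' of the anchor's TRBV family whose CDR3 full-matches the motif regex at
#' productive frequency above the threshold. Prevalence is the detected
#' fraction within each (exposure, allele) stratum; empty strata are
#' flagged with an undefined fraction.
#'
#' @param metaclonotypes data.frame from [buildMetaclonotypes].
#' @param repertoires list of [TcrRepertoire-class].
#' @param strata data.frame with `sample_id`, `exposed` (logical) and
#'   `allele_pos` (0/1/NA; NA samples are dropped).
#' @param freqThreshold detection threshold.
#' @return data.frame: `id`, `stratum`, `n_samples`, `n_detected`,
#'   `fraction`, `flagged`.
#' @export
screenPrevalence <- function(metaclonotypes, repertoires, strata,
                             freqThreshold = 2e-6) {
  ids <- vapply(repertoires, sampleId, "")
  det <- rbindlist(lapply(repertoires, function(r)
    cbind(sample_id = sampleId(r), detectionSet(r, freqThreshold))))
  strata <- strata[!is.na(strata$allele_pos), , drop = FALSE]
  strata$stratum <- paste0(ifelse(strata$exposed, "+Ex", "-Ex"), "/",
                           ifelse(strata$allele_pos == 1, "+HLA", "-HLA"))
  levs <- c("+Ex/+HLA", "+Ex/-HLA", "-Ex/+HLA", "-Ex/-HLA")

  out <- list()
  for (i in seq_len(nrow(metaclonotypes))) {
    mc <- metaclonotypes[i, ]
    dfam <- det[det$trbv_family == mc$trbv_family]
    hitSamples <- unique(dfam$sample_id[grepl(mc$regex, dfam$cdr3_aa)])
    for (st in levs) {
      ss <- strata$sample_id[strata$stratum == st]
      ss <- intersect(ss, ids)
      n <- length(ss); nd <- sum(ss %in% hitSamples)
      out[[length(out) + 1L]] <- data.frame(
        id = mc$id, stratum = st, n_samples = n, n_detected = nd,
        fraction = if (n > 0) nd / n else NA_real_, flagged = n == 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
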