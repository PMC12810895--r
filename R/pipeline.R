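#' Pooled detection table for a cohort
#'
#' @param repertoires list of [TcrRepertoire-class].
#' @param freqThreshold detection threshold.
#' @return data.table: `sample_id`, `trbv_family`, `cdr3_aa`.
#' @export
cohortDetections <- function(repertoires, freqThreshold = 2e-6) {
  rbindlist(lapply(repertoires, function(r)
    cbind(sample_id = sampleId(r), detectionSet(r, freqThreshold))))
}

#' Candidate feature universe for discovery
#'
#' All `(trbv_family, cdr3_aa)` features observed in more than
#' `minTemplates - 1` templates in at least one repertoire — the
#' expanded-clone restriction that limits the feature space before
#' association testing.
#'
#' @param repertoires list of [TcrRepertoire-class].
#' @param minTemplates template floor (default 2, i.e. >1 template).
#' @return data.table: `trbv_family`, `cdr3_aa` (unique).
#' @export
candidateFeatures <- function(repertoires, minTemplates = 2L) {
  cl <- rbindlist(lapply(repertoires, function(r)
    as.data.table(clonotypes(r))[, c("trbv_family", "cdr3_aa", "templates")]))
  unique(cl[cl$templates >= minTemplates, c("trbv_family", "cdr3_aa")])
}

# per-sample label vector for one allele, via each sample's subject
sampleLabels <- function(repertoires, labels, allele) {
  subj <- vapply(repertoires, subjectId, "")
  y <- labels[subj, allele]
  as.integer(y)
}

#' Discover HLA-associated features across a labeled cohort
#'
#' For every allele: screens the edit-1 occurrence matrix (odds ratio,
#' Fisher p, publicity and mismatch-detection filters), prunes edit-1 hits
#' lacking exact-sequence enrichment (exact OR < 1; undefined exact OR
#' prunes by default), and separately screens the exact occurrence matrix
#' for public exact features.
#'
#' @param repertoires list of [TcrRepertoire-class].
#' @param labels subject x allele binary data.frame.
#' @param alleles allele names to screen (default: all label columns).
#' @param config a [screenConfig].
#' @param keepUndefinedExact keep edit-1 features with undefined exact OR.
#' @return list: `exact` and `edit1` association data.frames (the edit-1
#'   table is post-pruning), `detections`, `candidates`, `occurrence`
#'   (list of the two matrices).
#' @export
runDiscovery <- function(repertoires, labels, alleles = names(labels),
                         config = screenConfig(),
                         keepUndefinedExact = FALSE) {
  det <- cohortDetections(repertoires, config$freqThreshold)
  cand <- candidateFeatures(repertoires, config$minTemplates)
  ids <- vapply(repertoires, sampleId, "")
  occE <- buildOccurrence(det, cand, "exact", sampleIds = ids)
  occN <- buildOccurrence(det, cand, "edit1", sampleIds = ids)

  exacts <- list(); edits <- list()
  for (al in alleles) {
    y <- sampleLabels(repertoires, labels, al)
    if (sum(y == 1, na.rm = TRUE) == 0) {
      warning("allele ", al, " has no positive samples; skipped")
      next
    }
    ex <- discoverFeatures(occE, y, config, allele = al, mode = "exact")
    ed <- discoverFeatures(occN, y, config, allele = al, mode = "edit1")
    if (nrow(ed)) {
      cts <- associationCounts(occE[, ed$feature_id, drop = FALSE], y)
      exOr <- setNames(ifelse(cts$b * cts$c > 0,
                              (cts$a * cts$d) / (cts$b * cts$c),
                              ifelse(cts$a * cts$d > 0, Inf, NA_real_)),
                       cts$feature_id)
      ed <- pruneNonenriched(ed, exOr, keepUndefined = keepUndefinedExact)
    }
    exacts[[al]] <- ex; edits[[al]] <- ed
  }
  list(exact = do.call(rbind, unname(exacts)),
       edit1 = do.call(rbind, unname(edits)),
       detections = det, candidates = cand,
       occurrence = list(exact = occE, edit1 = occN))
}

#' Select non-redundant edit-1 anchor features per allele
#'
#' Builds the radius-14 TCRdist graph over each allele's pruned edit-1
#' features and applies the greedy maximum-degree reduction; anchors enter
#' the classifier as edit-1 features, residual degree-<=1 nodes do not
#' (they remain usable as exact features if independently screened in).
#'
#' @param edit1Results pruned edit-1 association table from [runDiscovery].
#' @param radius TCRdist cutoff.
#' @param params a [tcrdistParams] list.
#' @return data.frame: `allele`, `trbv_family`, `cdr3_aa`, `n_neighbors`,
#'   `members` (semicolon-joined CDR3s).
#' @export
selectAnchors <- function(edit1Results, radius = 14,
                          params = tcrdistParams()) {
  out <- list()
  if (is.null(edit1Results) || !nrow(edit1Results))
    return(data.frame(allele = character(), trbv_family = character(),
                      cdr3_aa = character(), n_neighbors = integer(),
                      members = character(), stringsAsFactors = FALSE))
  for (al in sortC(unique(edit1Results$allele))) {
    fe <- edit1Results[edit1Results$allele == al, , drop = FALSE]
    g <- buildGraph(fe, radius = radius, params = params)
    sel <- greedyAnchors(g)
    if (!nrow(sel$anchors)) next
    cdr <- setNames(igraph::V(g)$cdr3_aa, igraph::V(g)$name)
    fam <- setNames(igraph::V(g)$trbv_family, igraph::V(g)$name)
    out[[al]] <- data.frame(
      allele = al, trbv_family = unname(fam[sel$anchors$anchor]),
      cdr3_aa = unname(cdr[sel$anchors$anchor]),
      n_neighbors = sel$anchors$n_neighbors,
      members = vapply(sel$anchors$members, function(m)
        paste(unname(cdr[m]), collapse = ";"), ""),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(allele = character(), trbv_family = character(),
                      cdr3_aa = character(), n_neighbors = integer(),
                      members = character(), stringsAsFactors = FALSE))
  do.call(rbind, unname(out))
}

#' Assemble the classifier feature list for one allele
#'
#' Union of screened exact features (`mode = "exact"`) and greedy edit-1
#' anchors (`mode = "edit1"`), C-locale sorted for reproducibility.
#'
#' @param exactResults exact association table (may be NULL).
#' @param anchors anchor table from [selectAnchors] (may be NULL).
#' @param allele allele name.
#' @return data.frame: `trbv_family`, `cdr3_aa`, `mode`.
#' @export
assembleModelFeatures <- function(exactResults, anchors, allele) {
  ex <- if (!is.null(exactResults) && nrow(exactResults))
    exactResults[exactResults$allele == allele,
                 c("trbv_family", "cdr3_aa"), drop = FALSE]
  else data.frame(trbv_family = character(), cdr3_aa = character())
  an <- if (!is.null(anchors) && nrow(anchors))
    anchors[anchors$allele == allele,
            c("trbv_family", "cdr3_aa"), drop = FALSE]
  else data.frame(trbv_family = character(), cdr3_aa = character())
  ex <- unique(ex); an <- unique(an)
  ex$mode <- rep("exact", nrow(ex)); an$mode <- rep("edit1", nrow(an))
  fe <- rbind(ex, an)
  fe <- fe[orderC(fe$mode, fe$trbv_family, fe$cdr3_aa), , drop = FALSE]
  rownames(fe) <- NULL
  fe
}

#' Partition alleles into common / rare / excluded model targets
#'
#' Common alleles exceed the prevalence cut (default 4%), rare alleles sit
#' inside the band (default 1-4%), anything below the band is excluded.
#' Heterodimer targets are synthesized from DQA1xDQB1 and DPA1xDPB1 pairs
#' whose constituent alleles are both above the cut, and classified by the
#' prevalence of the derived co-occurrence label.
#'
#' @param labels subject x allele binary data.frame.
#' @param prevalenceCut common-allele cut.
#' @param rareBand numeric(2) rare-allele prevalence band.
#' @return list: `common`, `rare`, `excluded` (character vectors) and
#'   `labels` (with heterodimer columns appended).
#' @export
selectTargets <- function(labels, prevalenceCut = 0.04,
                          rareBand = c(0.01, 0.04)) {
  base <- names(labels)
  prev <- colMeans(labels, na.rm = TRUE)
  hdCandidates <- character()
  for (pre in list(c("DQA1\\*", "DQB1\\*"), c("DPA1\\*", "DPB1\\*"))) {
    a <- base[grepl(pre[1], base) & prev[base] > prevalenceCut]
    b <- base[grepl(pre[2], base) & prev[base] > prevalenceCut]
    if (length(a) && length(b))
      hdCandidates <- c(hdCandidates, as.vector(outer(a, b, paste, sep = "/")))
  }
  labels <- deriveHeterodimerLabels(labels, hdCandidates)
  prev <- colMeans(labels, na.rm = TRUE)
  nm <- names(labels)
  list(common = sortC(nm[prev > prevalenceCut]),
       rare = sortC(nm[prev >= rareBand[1] & prev <= rareBand[2]]),
       excluded = sortC(nm[prev < rareBand[1]]),
       labels = labels)
}

#' Pipeline configuration
#'
#' @param outDir artifact directory.
#' @param sim a [simulationConfig] (the cohort the pipeline runs on).
#' @param screen a [screenConfig].
#' @param tcrdist a [tcrdistParams] list.
#' @param radius TCRdist graph radius.
#' @param lambdaGrid,nFolds classifier tuning controls.
#' @param calibrationMode `"standard"` or `"high_sensitivity"`.
#' @param gate confidence gate bounds.
#' @param drawsList downsampling draw counts for the HS calibration set.
#' @param nCalibSources number of training repertoires downsampled.
#' @param prevalenceCut,rareBand model-target prevalence rules.
#' @param seed master seed; every stage derives its randomness from it.
#' @return a `pipeline_config` list with its provenance hash.
#' @export
pipelineConfig <- function(outDir, sim = simulationConfig(),
                           screen = screenConfig(),
                           tcrdist = tcrdistParams(), radius = 14,
                           lambdaGrid = exp(seq(log(1e-3), log(1e2),
                                                length.out = 25)),
                           nFolds = 5L,
                           calibrationMode = "standard",
                           gate = c(0.1, 0.9),
                           drawsList = c(50, 100, 250, 500, 1000, 2500, 5000),
                           nCalibSources = 50L,
                           prevalenceCut = 0.04, rareBand = c(0.01, 0.04),
                           seed = 1L) {
  cfg <- list(outDir = outDir, sim = sim, screen = screen,
              tcrdist = tcrdist, radius = radius, lambdaGrid = lambdaGrid,
              nFolds = as.integer(nFolds), calibrationMode = calibrationMode,
              gate = gate, drawsList = drawsList,
              nCalibSources = as.integer(nCalibSources),
              prevalenceCut = prevalenceCut, rareBand = rareBand,
              seed = as.integer(seed))
  cfg$hash <- configHash(cfg[setdiff(names(cfg), "outDir")])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> discover -> anchors -> train -> calibrate -> predict, with
#' every artifact written under `config$outDir` and a manifest recording
#' the config hash, seed and md5 of each artifact. A rerun with an
#' unchanged config hash and intact artifacts is skipped; any config
#' change regenerates everything downstream. Fixed seed + config give
#' byte-identical model JSONs and manifests.
#'
#' @param config a [pipelineConfig].
#' @param force rerun even when artifacts are up to date.
#' @return invisible list: `models`, `predictions`, `features`, `anchors`,
#'   `manifest`.
#' @export
runAll <- function(config, force = FALSE) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  manPath <- file.path(config$outDir, "manifest.json")

  if (!force && file.exists(manPath)) {
    old <- jsonlite::read_json(manPath, simplifyVector = TRUE)
    if (identical(old$config_hash, config$hash) &&
        all(file.exists(file.path(config$outDir, names(old$artifacts))))) {
      message("artifacts up to date for config ", config$hash, "; skipping")
      return(invisible(readPipelineArtifacts(config$outDir)))
    }
  }

  # --- simulate ----------------------------------------------------------
  sim <- config$sim
  sim$seed <- config$seed
  cohort <- generateCohort(sim)
  labelsPath <- file.path(config$outDir, "labels.tsv")
  fwrite(cbind(subject_id = rownames(cohort$labels), cohort$labels),
         labelsPath, sep = "\t")
  fwrite(cohort$truth, file.path(config$outDir, "truth.tsv"), sep = "\t")

  # --- discover ----------------------------------------------------------
  alleles <- names(cohort$labels)
  disc <- runDiscovery(cohort$repertoires, cohort$labels, alleles,
                       config$screen)
  featPath <- file.path(config$outDir, "features.tsv")
  featTab <- rbind(disc$exact, disc$edit1)
  fwrite(if (is.null(featTab)) emptyAssociation(config$screen) else featTab,
         featPath, sep = "\t")

  # --- anchors -----------------------------------------------------------
  anchors <- selectAnchors(disc$edit1, config$radius, config$tcrdist)
  fwrite(anchors, file.path(config$outDir, "anchors.tsv"), sep = "\t")

  # --- train + calibrate -------------------------------------------------
  calSrc <- cohort$repertoires[seq_len(min(config$nCalibSources,
                                           length(cohort$repertoires)))]
  calib <- buildCalibrationSet(calSrc, config$drawsList,
                               seed = config$seed + 1L)
  calDet <- cohortDetections(calib$repertoires, config$screen$freqThreshold)
  calU <- vapply(calib$repertoires, uniqueClones, 0L,
                 freqThreshold = config$screen$freqThreshold)

  models <- list(); preds <- list()
  for (al in alleles) {
    feats <- assembleModelFeatures(disc$exact, anchors, al)
    if (nrow(feats) < 1) {
      warning("no features survived discovery for ", al, "; no model built")
      next
    }
    ids <- vapply(cohort$repertoires, sampleId, "")
    X <- featurize(disc$detections, feats, sampleIds = ids)
    y <- sampleLabels(cohort$repertoires, cohort$labels, al)
    subj <- vapply(cohort$repertoires, subjectId, "")
    ok <- !is.na(y)
    model <- fitAlleleModel(X[ok, , drop = FALSE], y[ok], subj[ok],
                            lambdaGrid = config$lambdaGrid,
                            nFolds = config$nFolds,
                            seed = config$seed, allele = al,
                            features = feats)
    f <- decisionScore(model, X[ok, , drop = FALSE])
    Xc <- featurize(calDet, model@features,
                    sampleIds = vapply(calib$repertoires, sampleId, ""))
    yc <- as.integer(cohort$labels[calib$info$subject_id, al])
    fc <- decisionScore(model, Xc)
    okc <- !is.na(yc)
    model <- calibrateModel(model, f, y[ok],
                            hsData = list(scores = fc[okc],
                                          labels = yc[okc],
                                          u = log10(pmax(calU[okc], 1))))
    safe <- gsub("[^A-Za-z0-9._-]", "_", al)
    writeAlleleModel(model, file.path(config$outDir,
                                      paste0("model_", safe, ".json")))
    models[[al]] <- model
    preds[[al]] <- predictGenotype(model, cohort$repertoires,
                                   calibration = config$calibrationMode,
                                   freqThreshold = config$screen$freqThreshold,
                                   gate = config$gate)
  }
  predTab <- rbindlist(preds)
  fwrite(predTab, file.path(config$outDir, "predictions.tsv"), sep = "\t")

  # --- manifest ----------------------------------------------------------
  arts <- sortC(setdiff(list.files(config$outDir), "manifest.json"))
  manifest <- list(
    config_hash = config$hash, seed = config$seed,
    package_version = as.character(packageVersion("tcrHLA")),
    artifacts = as.list(setNames(
      unname(tools::md5sum(file.path(config$outDir, arts))), arts)))
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = I(17))

  invisible(list(models = models, predictions = as.data.frame(predTab),
                 features = featTab, anchors = anchors, manifest = manifest))
}

readPipelineArtifacts <- function(outDir) {
  mods <- list.files(outDir, pattern = "^model_.*\\.json$",
                     full.names = TRUE)
  models <- lapply(mods, readAlleleModel)
  names(models) <- vapply(models, function(m) m@allele, "")
  list(models = models,
       predictions = as.data.frame(fread(file.path(outDir,
                                                   "predictions.tsv"))),
       features = as.data.frame(fread(file.path(outDir, "features.tsv"))),
       anchors = as.data.frame(fread(file.path(outDir, "anchors.tsv"))),
       manifest = jsonlite::read_json(file.path(outDir, "manifest.json"),
                                      simplifyVector = TRUE))
}
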