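#' Configuration for the synthetic cohort generator
#'
#' Describes a labeled synthetic cohort: subjects receive independent
#' Bernoulli allele labels; each repertoire is a background of random
#' CDR3 clonotypes plus planted allele-linked features. Planted features
#' come in two kinds mirroring the statistical structure the discovery
#' screen assumes: `exact_public` features appear verbatim in carriers,
#' while `quasi_public` carriers usually emit an edit-distance-1 variant
#' (substitution with probability `subProb`, otherwise an indel, uniform
#' position/residue) and only rarely the planted sequence itself
#' (`quasiExactProb`), so exact publicity stays low while the neighborhood
#' is public enough to power an association. Template counts are
#' `1 + Geometric` with the given mean so that both the >1-template
#' candidate restriction and the 2e-6 frequency rule bind.
#'
#' @param nSubjects subjects (one repertoire each).
#' @param alleles data.frame with `name`, `prevalence`.
#' @param nExactPublic,nQuasiPublic planted features per allele.
#' @param penetrancePos probability an allele-positive repertoire carries a
#'   planted feature (or an edit-1 variant of it).
#' @param leakNeg same probability for allele-negative repertoires.
#' @param nBackground background clonotypes per repertoire.
#' @param templateMean mean template count (counts are 1 + Geometric).
#' @param quasiExactProb probability a quasi-public carrier emits the
#'   planted sequence rather than a variant.
#' @param subProb probability a variant is a substitution (else indel).
#' @param cassPrefix start background/planted CDR3s with "CASS".
#' @param lenRange CDR3 length range (uniform).
#' @param families TRBV family labels to draw from.
#' @param features optional preset feature table (columns `allele`,
#'   `trbv_family`, `cdr3_aa`, `type`, optional `penetrance_pos`,
#'   `leak_neg`); overrides the per-allele counts when given.
#' @param cohort cohort tag stored in repertoire metadata.
#' @param exposed cohort-level exposure flag (for prevalence screening).
#' @param seed integer; fully determines the cohort.
#' @return a `sim_config` list.
#' @export
simulationConfig <- function(nSubjects = 100L,
                             alleles = data.frame(name = "A*02:01",
                                                  prevalence = 0.3),
                             nExactPublic = 10L, nQuasiPublic = 10L,
                             penetrancePos = 0.6, leakNeg = 0.02,
                             nBackground = 500L, templateMean = 3,
                             quasiExactProb = 0.1, subProb = 0.8,
                             cassPrefix = TRUE, lenRange = c(10L, 18L),
                             families = paste0("TRBV", c(2:7, 9:16, 18:20,
                                                         23:25, 27:30)),
                             features = NULL, cohort = "synthetic",
                             exposed = FALSE, seed = 1L) {
  stopIfNot(all(alleles$prevalence >= 0 & alleles$prevalence <= 1),
            "prevalences must lie in [0,1]")
  stopIfNot(penetrancePos >= 0 && penetrancePos <= 1 &&
            leakNeg >= 0 && leakNeg <= 1, "penetrances must lie in [0,1]")
  stopIfNot(penetrancePos > leakNeg,
            "penetrancePos must exceed leakNeg for planted features")
  if (all(alleles$prevalence %in% c(0, 1)))
    warning("degenerate config: every allele has prevalence 0 or 1")
  structure(list(nSubjects = as.integer(nSubjects), alleles = alleles,
                 nExactPublic = as.integer(nExactPublic),
                 nQuasiPublic = as.integer(nQuasiPublic),
                 penetrancePos = penetrancePos, leakNeg = leakNeg,
                 nBackground = as.integer(nBackground),
                 templateMean = templateMean,
                 quasiExactProb = quasiExactProb, subProb = subProb,
                 cassPrefix = cassPrefix, lenRange = as.integer(lenRange),
                 families = families, features = features, cohort = cohort,
                 exposed = exposed, seed = as.integer(seed)),
            class = "sim_config")
}

# vectorized random CDR3s: uniform length, uniform residues, optional
# CASS prefix
randomCdr3 <- function(n, lenRange, cassPrefix) {
  lens <- sample(seq(lenRange[1], lenRange[2]), n, replace = TRUE)
  out <- character(n)
  pre <- if (cassPrefix) "CASS" else ""
  npre <- nchar(pre)
  for (l in unique(lens)) {
    i <- which(lens == l)
    tail <- l - npre
    m <- matrix(sample(AA_ALPHABET, length(i) * tail, replace = TRUE),
                nrow = length(i))
    out[i] <- paste0(pre, do.call(paste0, as.data.frame(m)))
  }
  out
}

# one random edit-1 variant of a CDR3 (substitution / insertion / deletion)
mutate1 <- function(cdr3, subProb = 0.8) {
  L <- nchar(cdr3)
  if (runif(1) < subProb) {
    p <- sample.int(L, 1)
    old <- substr(cdr3, p, p)
    new <- sample(setdiff(AA_ALPHABET, old), 1)
    paste0(substr(cdr3, 1, p - 1), new, substr(cdr3, p + 1, L))
  } else if (runif(1) < 0.5 && L > 2) {
    p <- sample.int(L, 1)                       # deletion
    paste0(substr(cdr3, 1, p - 1), substr(cdr3, p + 1, L))
  } else {
    p <- sample.int(L + 1, 1) - 1L              # insertion after position p
    paste0(substr(cdr3, 1, p), sample(AA_ALPHABET, 1),
           substr(cdr3, p + 1, L))
  }
}

# 1 + Geometric template counts with the configured mean
rTemplates <- function(n, mean) 1L + rgeom(n, prob = 1 / max(mean, 1))

#' Generate a labeled synthetic cohort
#'
#' @param config a [simulationConfig].
#' @return list with `repertoires` (list of [TcrRepertoire-class]),
#'   `labels` (subject x allele binary data.frame, rownames = subject_id)
#'   and `truth` (planted feature table: `allele`, `trbv_family`,
#'   `cdr3_aa`, `type`).
#' @export
generateCohort <- function(config) {
  withSeed(config$seed, {
    ns <- config$nSubjects
    subjects <- sprintf("%s_S%04d", config$cohort, seq_len(ns))
    labels <- as.data.frame(lapply(seq_len(nrow(config$alleles)), function(k)
      rbinom(ns, 1, config$alleles$prevalence[k])))
    names(labels) <- config$alleles$name
    rownames(labels) <- subjects

    truth <- config$features
    if (is.null(truth)) {
      nf <- (config$nExactPublic + config$nQuasiPublic) * nrow(config$alleles)
      cd <- unique(randomCdr3(2L * nf + 10L, config$lenRange,
                              config$cassPrefix))[seq_len(nf)]
      truth <- data.frame(
        allele = rep(config$alleles$name,
                     each = config$nExactPublic + config$nQuasiPublic),
        trbv_family = sample(config$families, nf, replace = TRUE),
        cdr3_aa = cd,
        type = rep(rep(c("exact_public", "quasi_public"),
                       c(config$nExactPublic, config$nQuasiPublic)),
                   nrow(config$alleles)),
        stringsAsFactors = FALSE)
    }
    if (is.null(truth$penetrance_pos))
      truth$penetrance_pos <- rep(config$penetrancePos, nrow(truth))
    if (is.null(truth$leak_neg))
      truth$leak_neg <- rep(config$leakNeg, nrow(truth))

    reps <- vector("list", ns)
    for (i in seq_len(ns)) {
      bg <- data.table(
        trbv_family = sample(config$families, config$nBackground,
                             replace = TRUE),
        cdr3_aa = randomCdr3(config$nBackground, config$lenRange,
                             config$cassPrefix),
        templates = rTemplates(config$nBackground, config$templateMean))
      planted <- list()
      for (f in seq_len(nrow(truth))) {
        lab <- labels[i, truth$allele[f]]
        pr <- if (isTRUE(lab == 1)) truth$penetrance_pos[f] else truth$leak_neg[f]
        if (runif(1) >= pr) next
        cd <- truth$cdr3_aa[f]
        if (truth$type[f] == "quasi_public" &&
            runif(1) >= config$quasiExactProb)
          cd <- mutate1(cd, config$subProb)
        planted[[length(planted) + 1L]] <- data.table(
          trbv_family = truth$trbv_family[f], cdr3_aa = cd,
          templates = rTemplates(1L, config$templateMean))
      }
      cl <- rbindlist(c(list(bg), planted))
      cl <- cl[, list(templates = sum(templates)),
               by = c("trbv_family", "cdr3_aa")]
      cl[, trbv_gene := trbv_family]
      cl[, productive_frequency := templates / sum(templates)]
      reps[[i]] <- TcrRepertoire(subjects[i], subjects[i],
                                 as.data.frame(cl),
                                 metadata = list(cohort = config$cohort,
                                                 exposed = config$exposed))
    }
    list(repertoires = reps, labels = labels,
         truth = truth[, c("allele", "trbv_family", "cdr3_aa", "type")])
  })
}

#' Downsample a repertoire by multinomial template draws
#'
#' Draws `nDraws` templates with replacement, weighted by the original
#' template counts; surviving clonotypes keep their draw counts as new
#' template counts, frequencies are renormalized, and the unique-clone
#' count is implicitly recomputed under the 2e-6 rule by downstream
#' accessors. This is the primitive behind the high-sensitivity
#' calibration set.
#'
#' @param x a [TcrRepertoire-class].
#' @param nDraws number of template draws (>= 1).
#' @param seed integer seed.
#' @return a downsampled [TcrRepertoire-class]; metadata records `n_draws`
#'   and the source sample.
#' @export
downsampleRepertoire <- function(x, nDraws, seed = 1L) {
  stopIfNot(nDraws >= 1, "nDraws must be >= 1")
  cl <- as.data.table(clonotypes(x))
  stopIfNot(nrow(cl) > 0, "cannot downsample an empty repertoire")
  withSeed(seed, {
    cnt <- as.integer(rmultinom(1, nDraws, prob = cl$templates))
    keep <- cnt > 0
    out <- cl[keep]
    out[, templates := cnt[keep]]
    out[, productive_frequency := templates / sum(templates)]
    md <- x@metadata
    md$n_draws <- as.integer(nDraws)
    md$source_sample <- sampleId(x)
    TcrRepertoire(paste0(sampleId(x), "_ds", nDraws), subjectId(x),
                  as.data.frame(out), metadata = md)
  })
}

#' Build the repeated-downsampling calibration set
#'
#' One downsampled replicate per (source repertoire, draw count) pair,
#' inheriting the source subject's labels. The default draw list is
#' 1, 5, 10, 25, 50, 100 and 500 thousand draws.
#'
#' @param repertoires list of [TcrRepertoire-class] sources.
#' @param drawsList integer vector of draw counts.
#' @param seed integer seed (one stream across all replicates).
#' @return list with `repertoires` (replicates) and `info` data.frame
#'   (`sample_id`, `source_id`, `subject_id`, `n_draws`).
#' @export
buildCalibrationSet <- function(repertoires,
                                drawsList = c(1, 5, 10, 25, 50, 100, 500) * 1000,
                                seed = 1L) {
  stopIfNot(length(repertoires) > 0 && length(drawsList) > 0,
            "non-empty inputs required")
  stopIfNot(all(drawsList >= 1), "draws must be >= 1")
  grid <- expand.grid(src = seq_along(repertoires), nd = drawsList,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max, nrow(grid)))
  reps <- vector("list", nrow(grid))
  info <- data.frame(sample_id = character(nrow(grid)),
                     source_id = character(nrow(grid)),
                     subject_id = character(nrow(grid)),
                     n_draws = integer(nrow(grid)),
                     stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    src <- repertoires[[grid$src[r]]]
    reps[[r]] <- downsampleRepertoire(src, grid$nd[r], seed = seeds[r])
    info$sample_id[r] <- sampleId(reps[[r]])
    info$source_id[r] <- sampleId(src)
    info$subject_id[r] <- subjectId(src)
    info$n_draws[r] <- as.integer(grid$nd[r])
  }
  list(repertoires = reps, info = info)
}

#' Generate a planted feature cluster for meta-clonotype benchmarks
#'
#' One anchor CDR3 plus `nMembers - 1` single-substitution variants, all in
#' one TRBV family — a star in the radius-14 TCRdist graph. Attach the
#' result to a [simulationConfig] `features` table (with an allele and
#' penetrances) to plant an exposure-linked novel cluster.
#'
#' @param nMembers cluster size including the anchor.
#' @param family TRBV family label.
#' @param allele allele the cluster is linked to.
#' @param lenRange,cassPrefix anchor CDR3 shape (see [simulationConfig]).
#' @param seed integer seed.
#' @return data.frame: `allele`, `trbv_family`, `cdr3_aa`, `type`
#'   (`"exact_public"`).
#' @export
syntheticClusterFeatures <- function(nMembers = 5L, family = "TRBV9",
                                     allele = "A*02:01",
                                     lenRange = c(12L, 16L),
                                     cassPrefix = TRUE, seed = 1L) {
  withSeed(seed, {
    anchor <- randomCdr3(1L, lenRange, cassPrefix)
    members <- anchor
    while (length(members) < nMembers) {
      v <- mutate1(anchor, subProb = 1)  # substitutions only: stays in radius
      if (!v %in% members) members <- c(members, v)
    }
    data.frame(allele = allele, trbv_family = family, cdr3_aa = members,
               type = "exact_public", stringsAsFactors = FALSE)
  })
}

#' Simulate a binary occurrence matrix directly
#'
#' Occurrence-level counterpart of [generateCohort] for classifier
#' benchmarks: labels are Bernoulli(`prevalence`); informative feature
#' columns fire with probability `penetrance` in positives and `leak` in
#' negatives; decoy columns fire at label-independent base rates drawn
#' uniformly from `decoyRateRange`.
#'
#' @param nSamples,nInformative,nDecoy dimensions.
#' @param prevalence,penetrance,leak generative probabilities.
#' @param decoyRateRange range of decoy base rates.
#' @param seed integer seed.
#' @return list with `X` (binary matrix), `y` (0/1 vector), `informative`
#'   (column indices of planted features).
#' @export
simulateFeatureMatrix <- function(nSamples = 300L, nInformative = 30L,
                                  nDecoy = 100L, prevalence = 0.3,
                                  penetrance = 0.6, leak = 0.02,
                                  decoyRateRange = c(0.02, 0.3), seed = 1L) {
  withSeed(seed, {
    y <- rbinom(nSamples, 1, prevalence)
    Xi <- matrix(rbinom(nSamples * nInformative, 1,
                        ifelse(rep(y, nInformative) == 1, penetrance, leak)),
                 nrow = nSamples)
    rates <- runif(nDecoy, decoyRateRange[1], decoyRateRange[2])
    Xd <- matrix(rbinom(nSamples * nDecoy, 1, rep(rates, each = nSamples)),
                 nrow = nSamples)
    X <- cbind(Xi, Xd)
    colnames(X) <- c(sprintf("planted_%02d", seq_len(nInformative)),
                     sprintf("decoy_%03d", seq_len(nDecoy)))
    list(X = X, y = y, informative = seq_len(nInformative))
  })
}
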