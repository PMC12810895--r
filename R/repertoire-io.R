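#' Normalize TRBV gene calls to IMGT family labels
#'
#' Collapses allele- and gene-level TRBV calls from either sequencing dialect
#' onto the IMGT V-gene family that partitions all neighbor searches:
#' `"TRBV12-3*01"` and the immunoSEQ-style `"TCRBV12-03"` both become
#' `"TRBV12"`. Multi-gene calls whose members share one family collapse to
#' that family; calls spanning distinct families are unresolvable.
#'
#' @param geneCall character vector of raw gene calls.
#' @param onAmbiguous `"error"` to stop at the first call resolving to more
#'   than one family, `"na"` to return `NA` for such calls (callers then
#'   drop the row).
#' @return character vector of family labels, e.g. `"TRBV9"`.
#' @examples
#' normalizeTrbvFamily(c("TRBV9*01", "TCRBV09-01", "TRBV12-3/12-4*01"))
#' @export
normalizeTrbvFamily <- function(geneCall, onAmbiguous = c("error", "na")) {
  onAmbiguous <- match.arg(onAmbiguous)
  one <- function(call) {
    if (is.na(call) || !nzchar(call)) return(NA_character_)
    x <- sub("\\*.*$", "", call)            # strip allele designation
    toks <- strsplit(x, "[/,]")[[1]]
    fams <- vapply(toks, function(tok) {
      tok <- sub("^TCRBV", "TRBV", toupper(trimws(tok)))
      # bare continuation tokens like "12-4" inherit the TRBV prefix
      if (grepl("^[0-9]", tok)) tok <- paste0("TRBV", tok)
      m <- regmatches(tok, regexec("^TRBV0*([0-9]+)", tok))[[1]]
      if (length(m) < 2) NA_character_ else paste0("TRBV", m[2])
    }, character(1))
    fams <- unique(fams[!is.na(fams)])
    if (length(fams) == 1L) return(fams)
    if (length(fams) == 0L) return(NA_character_)
    if (onAmbiguous == "error")
      stop("gene call resolves to multiple TRBV families: ", call,
           call. = FALSE)
    NA_character_
  }
  vapply(geneCall, one, character(1), USE.NAMES = FALSE)
}

#' Parse one repertoire file
#'
#' Reads a tab-separated repertoire in either the AIRR-C rearrangement
#' dialect (`v_call`, `junction_aa`, `duplicate_count`, `productive`) or the
#' immunoSEQ-style export dialect (`aminoAcid`, `vGeneName`/`vFamilyName`,
#' `count (templates/reads)`, `sequenceStatus`). Only productive, in-frame
#' rows with a parseable CDR3 (standard amino acids only) and a resolvable
#' TRBV family are retained; productive frequencies are recomputed from the
#' retained template counts rather than trusted from input columns, which
#' guards against dialect-specific denominator conventions. Gzip files are
#' read transparently.
#'
#' @param path path to a TSV (optionally `.gz`).
#' @param dialect `"airr"` or `"immunoseq"`.
#' @param minTemplates drop clonotypes with fewer templates (default 1 keeps
#'   everything; discovery uses 2, i.e. clones seen in more than one
#'   template).
#' @param sampleId,subjectId identifiers; default to the file base name.
#' @return a [TcrRepertoire-class]. `metadata(x)$dropped` counts rows
#'   removed for non-standard residues or unresolvable gene calls.
#' @export
parseRepertoire <- function(path, dialect = c("airr", "immunoseq"),
                            minTemplates = 1L,
                            sampleId = sub("\\.(tsv|txt)(\\.gz)?$", "",
                                           basename(path)),
                            subjectId = sampleId) {
  dialect <- match.arg(dialect)
  stopIfNot(file.exists(path), paste("file not found:", path))
  df <- readTsv(path)

  needCol <- function(cands, what) {
    hit <- intersect(cands, names(df))
    if (!length(hit))
      stop(sprintf("%s dialect: missing required column '%s'", dialect, what),
           call. = FALSE)
    hit[1]
  }

  if (dialect == "airr") {
    vcol <- needCol("v_call", "v_call")
    acol <- needCol("junction_aa", "junction_aa")
    ccol <- needCol("duplicate_count", "duplicate_count")
    pcol <- needCol("productive", "productive")
    prod <- tolower(as.character(df[[pcol]])) %in% c("t", "true", "1")
  } else {
    vcol <- needCol(c("vGeneName", "vFamilyName"), "vGeneName/vFamilyName")
    acol <- needCol("aminoAcid", "aminoAcid")
    ccol <- needCol(c("count (templates/reads)", "count", "templates"),
                    "count (templates/reads)")
    pcol <- needCol("sequenceStatus", "sequenceStatus")
    prod <- tolower(as.character(df[[pcol]])) %in% c("in", "in-frame")
  }

  cdr3 <- toupper(as.character(df[[acol]]))
  templates <- suppressWarnings(as.integer(df[[ccol]]))
  okSeq <- !is.na(cdr3) & grepl(CDR3_REGEX, cdr3)
  fam <- rep(NA_character_, nrow(df))
  fam[prod & okSeq] <- normalizeTrbvFamily(as.character(df[[vcol]])[prod & okSeq],
                                           onAmbiguous = "na")
  keep <- prod & okSeq & !is.na(fam) & !is.na(templates) & templates >= 1L
  droppedMalformed <- sum(prod & !(okSeq & !is.na(fam)))
  if (minTemplates > 1L) keep <- keep & templates >= minTemplates

  if (!any(keep))
    stop("empty repertoire after filtering: ", path, call. = FALSE)

  cl <- data.table(trbv_gene = as.character(df[[vcol]])[keep],
                   trbv_family = fam[keep], cdr3_aa = cdr3[keep],
                   templates = templates[keep])
  # collapse duplicate (gene, cdr3) rows that differ only in nucleotides
  cl <- cl[, list(templates = sum(templates)),
           by = c("trbv_gene", "trbv_family", "cdr3_aa")]
  cl[, productive_frequency := templates / sum(templates)]

  TcrRepertoire(sampleId, subjectId, as.data.frame(cl),
                metadata = list(path = path, dialect = dialect,
                                dropped = droppedMalformed,
                                min_templates = as.integer(minTemplates)))
}

#' Write a repertoire to disk
#'
#' @param x a [TcrRepertoire-class].
#' @param path output TSV path.
#' @param dialect `"normalized"` (sample_id, subject_id, trbv_family,
#'   cdr3_aa, templates, productive_frequency) or `"airr"` (re-parseable
#'   with [parseRepertoire]).
#' @return `path`, invisibly.
#' @export
writeRepertoire <- function(x, path, dialect = c("normalized", "airr")) {
  dialect <- match.arg(dialect)
  cl <- as.data.table(clonotypes(x))
  out <- if (dialect == "normalized") {
    data.table(sample_id = sampleId(x), subject_id = subjectId(x),
               trbv_family = cl$trbv_family, cdr3_aa = cl$cdr3_aa,
               templates = cl$templates,
               productive_frequency = cl$productive_frequency)
  } else {
    data.table(v_call = if ("trbv_gene" %in% names(cl)) cl$trbv_gene
                        else cl$trbv_family,
               junction_aa = cl$cdr3_aa, duplicate_count = cl$templates,
               productive = "T")
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Count unique clonotypes above the detection threshold
#'
#' The repertoire-richness covariate `U` of the high-sensitivity
#' calibration: the number of unique clonotypes whose productive frequency
#' strictly exceeds `freqThreshold`.
#'
#' @param x a [TcrRepertoire-class].
#' @param freqThreshold detection threshold (default `2e-6`).
#' @return integer count.
#' @export
uniqueClones <- function(x, freqThreshold = 2e-6) {
  sum(clonotypes(x)$productive_frequency > freqThreshold)
}

#' Compute a sample's detection set
#'
#' Reduces a repertoire to the set of `(trbv_family, cdr3_aa)` pairs with at
#' least one clonotype at productive frequency strictly greater than the
#' threshold — the boundary is exclusive, so a clone at exactly `2e-6` is
#' not detected. Pairs reached from several gene-level calls collapse to one
#' element.
#'
#' @inheritParams uniqueClones
#' @return data.table with columns `trbv_family`, `cdr3_aa` (unique rows).
#' @export
detectionSet <- function(x, freqThreshold = 2e-6) {
  cl <- as.data.table(clonotypes(x))
  det <- cl[cl$productive_frequency > freqThreshold,
            c("trbv_family", "cdr3_aa")]
  unique(det)
}

#' Read a subject-by-allele label table
#'
#' @param path TSV with a `subject_id` column and one column per allele,
#'   values in {0, 1, NA}.
#' @return data.frame with rownames = subject_id and binary allele columns.
#' @export
readCohortLabels <- function(path) {
  df <- as.data.frame(readTsv(path), check.names = FALSE)
  stopIfNot("subject_id" %in% names(df), "labels file needs a subject_id column")
  rn <- as.character(df$subject_id)
  df <- df[, setdiff(names(df), "subject_id"), drop = FALSE]
  bad <- !vapply(df, function(v) all(v %in% c(0, 1, NA)), logical(1))
  if (any(bad))
    stop("non-binary label column(s): ", paste(names(df)[bad], collapse = ", "))
  rownames(df) <- rn
  df
}

#' Derive heterodimer labels from class II allele pairs
#'
#' A heterodimer target such as `"DQA1*05:01/DQB1*03:01"` is positive for a
#' subject iff both constituent alleles are positive (cis/trans pairing
#' ambiguity is ignored; the pairing is a label-level construct).
#'
#' @param labels subject x allele binary data.frame.
#' @param pairs character vector of `"<alpha>/<beta>"` names; by default all
#'   DQA1xDQB1 and DPA1xDPB1 combinations present in `labels`.
#' @return `labels` with the heterodimer columns appended.
#' @export
deriveHeterodimerLabels <- function(labels, pairs = NULL) {
  if (is.null(pairs)) {
    mk <- function(apre, bpre) {
      a <- grep(paste0("^", apre), names(labels), value = TRUE)
      b <- grep(paste0("^", bpre), names(labels), value = TRUE)
      as.vector(outer(a, b, paste, sep = "/"))
    }
    pairs <- c(mk("DQA1\\*", "DQB1\\*"), mk("DPA1\\*", "DPB1\\*"))
  }
  for (p in pairs) {
    ab <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (!all(ab %in% names(labels))) next
    labels[[p]] <- as.integer(labels[[ab[1]]] == 1 & labels[[ab[2]]] == 1)
  }
  labels
}
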