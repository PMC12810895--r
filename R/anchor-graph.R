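.pkgCache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkgCache$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$b62 <- e$BLOSUM62
  }
  .pkgCache$b62
}

#' TCRdist parameter set (CDR3-beta, family-partitioned)
#'
#' Self-contained variant of the TCRdist metric restricted to the CDR3-beta
#' loop: substitution cost `min(4, 4 - BLOSUM62(x, y))` (0 for identity,
#' floored at 0), CDR3 weight 3, gap penalty 4 per indel position (applied
#' before weighting, so one indel contributes 12 after weighting),
#' N-terminal trim 3 and C-terminal trim 2 residues before comparison, and
#' an infinite cross-family penalty (all graph construction happens within
#' TRBV family partitions). With these constants a single substitution
#' scores at most 12, so radius-14 clusters join TCRs differing by 1-2
#' conservative CDR3 substitutions or one indel.
#'
#' @param subCostCap cap on the per-position substitution cost.
#' @param cdr3Weight multiplier applied to the CDR3 mismatch score.
#' @param gapPenalty per-position indel cost (pre-weighting).
#' @param trimN,trimC residues trimmed from either end before comparison.
#' @return a `tcrdist_params` list.
#' @export
tcrdistParams <- function(subCostCap = 4, cdr3Weight = 3, gapPenalty = 4,
                          trimN = 3L, trimC = 2L) {
  structure(list(subCostCap = subCostCap, cdr3Weight = cdr3Weight,
                 gapPenalty = gapPenalty, trimN = as.integer(trimN),
                 trimC = as.integer(trimC)),
            class = "tcrdist_params")
}

# substitution cost between two aligned residue vectors
subCosts <- function(x, y, params) {
  b62 <- blosum62()
  cost <- pmax(0, pmin(params$subCostCap,
                       params$subCostCap - b62[cbind(x, y)]))
  cost[x == y] <- 0
  cost
}

trimCdr3 <- function(s, params) {
  L <- nchar(s)
  if (L > params$trimN + params$trimC)
    substr(s, params$trimN + 1L, L - params$trimC)
  else
    s  # too short to trim; compared untrimmed
}

#' TCRdist between two TCR-beta features
#'
#' `+Inf` when the TRBV families differ; otherwise
#' `cdr3Weight * (sum of substitution costs + gapPenalty * |length diff|)`
#' over the trimmed CDR3s, with unequal lengths aligned by the single
#' contiguous gap placement minimizing total cost. CDR3s too short to trim
#' (<= 5 residues) are compared untrimmed and flagged with a warning.
#'
#' @param cdr3A,cdr3B CDR3 amino-acid strings.
#' @param familyA,familyB TRBV family labels (omit both to skip the
#'   family gate).
#' @param params a [tcrdistParams] list.
#' @return non-negative number, possibly `Inf`.
#' @examples
#' tcrdistBeta("CASSLAPGATNEKLFF", "CASSLAPGATNEKLFF")  # 0
#' @export
tcrdistBeta <- function(cdr3A, cdr3B, familyA = NULL, familyB = NULL,
                        params = tcrdistParams()) {
  if (!is.null(familyA) && !is.null(familyB) && familyA != familyB)
    return(Inf)
  if (nchar(cdr3A) <= params$trimN + params$trimC ||
      nchar(cdr3B) <= params$trimN + params$trimC)
    warning("CDR3 too short to trim; compared untrimmed")
  s <- trimCdr3(cdr3A, params); t <- trimCdr3(cdr3B, params)
  if (nchar(s) > nchar(t)) { tmp <- s; s <- t; t <- tmp }
  sv <- strsplit(s, "")[[1]]; tv <- strsplit(t, "")[[1]]
  m <- length(sv); n <- length(tv); g <- n - m
  if (g == 0) {
    core <- sum(subCosts(sv, tv, params))
  } else {
    # single contiguous gap: try every split point of the shorter string
    best <- Inf
    for (k in 0:m) {
      idx <- c(seq_len(k), if (k < m) (k + g + 1):n else integer())
      cost <- sum(subCosts(sv, tv[idx], params))
      if (cost < best) best <- cost
    }
    core <- best + params$gapPenalty * g
  }
  params$cdr3Weight * core
}

#' Pairwise TCRdist matrix over a feature table
#'
#' @param features data.frame with `trbv_family`, `cdr3_aa`.
#' @param params a [tcrdistParams] list.
#' @return symmetric numeric matrix (`Inf` across families).
#' @export
tcrdistMatrix <- function(features, params = tcrdistParams()) {
  n <- nrow(features)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- suppressWarnings(
      tcrdistBeta(features$cdr3_aa[i], features$cdr3_aa[j],
                  features$trbv_family[i], features$trbv_family[j], params))
  }
  D
}

#' Build a TCRdist similarity graph over features
#'
#' Undirected graph with one vertex per feature row and edges exactly where
#' the pairwise TCRdist is at most `radius` (default 14; set
#' `strict = TRUE` for a strictly-less-than rule, which differs only at
#' integer distance exactly 14). No self-loops; edges never cross TRBV
#' families.
#'
#' @param features data.frame with `trbv_family`, `cdr3_aa` and optionally
#'   `publicity` (used by the greedy tie-break).
#' @param radius distance cutoff.
#' @param params a [tcrdistParams] list.
#' @param strict use `< radius` instead of `<= radius`.
#' @return an [igraph::graph] with vertex attributes `name`
#'   (`family|cdr3`, made unique), `trbv_family`, `cdr3_aa`, `publicity`.
#' @export
buildGraph <- function(features, radius = 14, params = tcrdistParams(),
                       strict = FALSE) {
  features <- as.data.frame(features)
  D <- tcrdistMatrix(features, params)
  adj <- if (strict) D < radius else D <= radius
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  nm <- make.unique(featureId(features$trbv_family, features$cdr3_aa),
                    sep = "#")
  igraph::V(g)$name <- nm
  igraph::V(g)$trbv_family <- features$trbv_family
  igraph::V(g)$cdr3_aa <- features$cdr3_aa
  igraph::V(g)$publicity <- if ("publicity" %in% names(features))
    features$publicity else 0
  g
}

#' Greedy maximum-degree anchor selection
#'
#' Iteratively selects the highest-degree vertex as an anchor, records its
#' first-degree neighbors at selection time, deletes the closed
#' neighborhood, and repeats until no vertex of degree greater than 1
#' remains. Ties break by larger publicity, then lexicographically smallest
#' vertex name, making the selection order reproducible regardless of
#' vertex insertion order. Surviving degree-<=1 vertices are returned as
#' residual features, not anchors.
#'
#' @param graph an [igraph::graph] from [buildGraph].
#' @param continueDegreeOne also anchor degree-1 components instead of
#'   stopping at the quoted rule (default FALSE).
#' @return list with `anchors` (data.frame: `anchor`, `n_neighbors`,
#'   `members` list-column of neighbor names) and `residuals` (character
#'   vector of unanchored vertex names).
#' @export
greedyAnchors <- function(graph, continueDegreeOne = FALSE) {
  g <- graph
  anchors <- character(); members <- list(); nn <- integer()
  minDeg <- if (continueDegreeOne) 1L else 2L
  repeat {
    if (igraph::vcount(g) == 0) break
    deg <- igraph::degree(g)
    if (max(deg) < minDeg) break
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      pub <- igraph::V(g)$publicity[cand]
      cand <- cand[pub == max(pub)]
      if (length(cand) > 1) {
        nms <- igraph::V(g)$name[cand]
        cand <- cand[orderC(nms)[1]]
      }
    }
    v <- cand[1]
    nbr <- igraph::V(g)$name[igraph::neighbors(g, v)]
    anchors <- c(anchors, igraph::V(g)$name[v])
    members <- c(members, list(sortC(nbr)))
    nn <- c(nn, length(nbr))
    g <- igraph::delete_vertices(g, c(v, igraph::neighbors(g, v)))
  }
  list(anchors = data.frame(anchor = anchors, n_neighbors = nn,
                            stringsAsFactors = FALSE) |>
         (\(df) { df$members <- members; df })(),
       residuals = sortC(igraph::V(g)$name))
}
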