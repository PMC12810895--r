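# Shared fixtures and independent oracles for the test suite. Oracles here
# are written against the definitions (Levenshtein via utils::adist,
# hypergeometric enumeration via lchoose, TCRdist re-derived from BLOSUM62)
# so that package routines are never checked against themselves.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# C-locale (radix) sort, local to the tests
sortC <- function(x) sort(x, method = "radix")

# random CDR3-like strings, generated with base R only
rndCdr3 <- function(n, lenMin = 8, lenMax = 20, prefix = "") {
  lens <- sample(lenMin:lenMax, n, replace = TRUE)
  vapply(lens, function(l) paste0(
    prefix, paste(sample(AA20, l - nchar(prefix), replace = TRUE),
                  collapse = "")), "")
}

# brute-force edit-distance-<=1 neighbor sets via utils::adist
bruteNeighbors <- function(query, universe) {
  d <- drop(adist(query, universe))
  sortC(universe[d <= 1])
}

# full hypergeometric enumeration for the two-sided Fisher p, written with
# lchoose so it shares no code with the dhyper-based implementation
enumFisherP <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) return(1)
  K <- a + c; m <- a + b
  x <- max(0, m - (N - K)):min(m, K)
  lp <- lchoose(K, x) + lchoose(N - K, m - x) - lchoose(N, m)
  p <- exp(lp)
  sum(p[p <= p[x == a] * (1 + 1e-7)])
}

# independent TCRdist oracle: capped-BLOSUM62 substitution cost, x3 CDR3
# weight, gap 4/position, trims 3/2, Inf across families
refTcrdist <- function(cdr3A, cdr3B, famA, famB) {
  if (famA != famB) return(Inf)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  trim <- function(s) if (nchar(s) > 5) substr(s, 4, nchar(s) - 2) else s
  a <- strsplit(trim(cdr3A), "")[[1]]
  b <- strsplit(trim(cdr3B), "")[[1]]
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  m <- length(a); n <- length(b); g <- n - m
  cst <- function(x, y) {
    v <- pmax(0, pmin(4, 4 - B62[cbind(x, y)])); v[x == y] <- 0; v
  }
  if (g == 0) core <- sum(cst(a, b))
  else {
    best <- Inf
    for (k in 0:m) {
      idx <- c(seq_len(k), if (k < m) (k + g + 1):n else integer())
      best <- min(best, sum(cst(a, b[idx])))
    }
    core <- best + 4 * g
  }
  3 * core
}

# minimal repertoire around explicit frequencies (one filler clone absorbs
# the remaining mass so the sum-to-1 invariant holds)
freqRepertoire <- function(sampleId, families, cdr3s, freqs,
                           subjectId = sampleId) {
  filler <- 1 - sum(freqs)
  stopifnot(filler > 0)
  TcrRepertoire(sampleId, subjectId, data.frame(
    trbv_gene = c(families, "TRBV30"),
    trbv_family = c(families, "TRBV30"),
    cdr3_aa = c(cdr3s, "CASSFILLERSINKF"),
    templates = rep(1L, length(cdr3s) + 1L),
    productive_frequency = c(freqs, filler),
    stringsAsFactors = FALSE))
}

# small AIRR-dialect TSV on disk; returns the path
writeAirrFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# an igraph with the vertex attributes greedyAnchors expects
namedGraph <- function(edges, vertices, publicity = NULL) {
  g <- igraph::make_empty_graph(n = length(vertices), directed = FALSE)
  igraph::V(g)$name <- vertices
  igraph::V(g)$trbv_family <- "TRBV9"
  igraph::V(g)$cdr3_aa <- vertices
  igraph::V(g)$publicity <- if (is.null(publicity)) 0 else publicity
  if (length(edges)) g <- igraph::add_edges(g, match(edges, vertices))
  g
}
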