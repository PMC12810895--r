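#' Unit-cost edit distance between amino-acid strings
#'
#' Standard Levenshtein distance (single-character substitutions,
#' insertions and deletions, each costing 1). This is the reference
#' predicate behind "edit-distance-1 neighbor"; the [Edit1Index-class]
#' never computes it, which keeps the two routes independent.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @examples
#' levenshtein("CASSLG", "CASSPG")  # 1
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  as.integer(mapply(function(x, y) adist(x, y), a, b))
}

# masked substitution patterns for a string vector: one row per (string,
# position), key carries (length, position) so patterns never collide
# across lengths or positions
maskKeys <- function(s) {
  L <- nchar(s)
  out <- vector("list", max(L, 0L))
  for (p in seq_len(max(L, 0L))) {
    i <- which(L >= p)
    si <- s[i]
    key <- paste0(L[i], "|", p, "|",
                  substr(si, 1L, p - 1L), ".", substr(si, p + 1L, L[i]))
    out[[p]] <- data.table(pat = key, cdr3 = si)
  }
  rbindlist(out)
}

# all single-deletion variants: one row per (string, deleted position)
delVariants <- function(s) {
  L <- nchar(s)
  out <- vector("list", max(L, 0L))
  for (p in seq_len(max(L, 0L))) {
    i <- which(L >= p)
    si <- s[i]
    out[[p]] <- data.table(
      variant = paste0(substr(si, 1L, p - 1L), substr(si, p + 1L, L[i])),
      cdr3 = si)
  }
  unique(rbindlist(out))
}

#' Build an edit-distance-1 index over one TRBV family's CDR3 set
#'
#' @param cdr3s character vector of CDR3 amino-acid sequences (all from the
#'   same TRBV family; duplicates are collapsed).
#' @param family the family label; queries and downstream joins are only
#'   valid within it — cross-family pairs are never indexed together.
#' @return an [Edit1Index-class].
#' @examples
#' idx <- buildEdit1Index(c("CASSLG", "CASSPG", "CASSLLG"), "TRBV9")
#' queryEdit1(idx, "CASSLG")
#' @export
buildEdit1Index <- function(cdr3s, family) {
  stopIfNot(length(family) == 1L && nzchar(family), "one family label required")
  s <- sortC(unique(cdr3s))
  stopIfNot(all(grepl(CDR3_REGEX, s)) || length(s) == 0L,
            "CDR3s must use the 20 standard amino acids")
  subs <- maskKeys(s)
  dels <- delVariants(s)
  if (nrow(subs)) setkeyv(subs, "pat")
  if (nrow(dels)) setkeyv(dels, "variant")
  new("Edit1Index", family = family, strings = s,
      subs = as.data.frame(subs), dels = as.data.frame(dels))
}

#' Query many strings against an edit-1 index at once
#'
#' Vectorized workhorse behind [queryEdit1] and the occurrence tabulation:
#' returns every (query, indexed string) pair at edit distance <= 1.
#' Substitution matches come from shared masked patterns; insertion and
#' deletion matches from joining raw strings against deletion variants (in
#' both directions). Deletion variants are never joined against deletion
#' variants, so same-length strings that merely share a deletion variant
#' (distance 2, e.g. "AB" vs "BA") are structurally excluded.
#'
#' @param index an [Edit1Index-class].
#' @param cdr3s character vector of query strings.
#' @return data.table with columns `query`, `neighbor` (unique pairs;
#'   includes the query itself when indexed).
#' @export
queryEdit1Many <- function(index, cdr3s) {
  q <- unique(cdr3s)
  empty <- data.table(query = character(), neighbor = character())
  if (!length(q) || !length(index@strings)) return(empty)
  subs <- as.data.table(index@subs)
  dels <- as.data.table(index@dels)

  # exact hits
  exq <- q[q %in% index@strings]
  hits <- list(data.table(query = exq, neighbor = exq))

  # substitution: shared masked pattern, same length by key construction
  qk <- maskKeys(q)
  if (nrow(qk) && nrow(subs)) {
    m <- subs[qk, on = c(pat = "pat"), nomatch = 0L, allow.cartesian = TRUE,
              list(query = i.cdr3, neighbor = cdr3)]
    hits <- c(hits, list(m[m$query != m$neighbor]))
  }

  # indexed string is one insertion longer: its deletion variant equals q
  if (nrow(dels)) {
    m <- dels[data.table(variant = q), on = "variant", nomatch = 0L,
              list(query = variant, neighbor = cdr3)]
    hits <- c(hits, list(m))
  }

  # indexed string is one deletion shorter: q's deletion variant equals it
  qd <- delVariants(q)
  if (nrow(qd)) {
    m <- qd[qd$variant %in% index@strings,
            list(query = cdr3, neighbor = variant)]
    hits <- c(hits, list(m))
  }

  out <- unique(rbindlist(hits))
  if (!nrow(out)) empty else out
}

#' Edit-distance-1 neighborhood of one CDR3
#'
#' Returns every indexed string within one substitution, insertion or
#' deletion of `cdr3`, including `cdr3` itself when indexed (the
#' neighborhood indicator downstream counts exact occurrences too).
#'
#' @param index an [Edit1Index-class].
#' @param cdr3 a single CDR3 string.
#' @return character vector of neighbors, C-locale sorted.
#' @export
queryEdit1 <- function(index, cdr3) {
  stopIfNot(length(cdr3) == 1L, "queryEdit1 takes a single string")
  sortC(queryEdit1Many(index, cdr3)$neighbor)
}
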