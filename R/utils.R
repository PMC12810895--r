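#' @import methods
#' @importFrom stats dhyper optim plogis qlogis rbinom rgeom runif rmultinom
#'   setNames quantile predict
#' @importFrom utils adist head read.delim write.table packageVersion
#' @importFrom data.table data.table setDT setkeyv rbindlist fread fwrite
#'   as.data.table := .N .SD
NULL

# the 20 standard amino acids; the CDR3 alphabet everywhere in the package
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CDR3_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so package randomness never leaks into (or depends
#' on) the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# locale-independent ordering (radix = C collation); used wherever output
# ordering must be byte-reproducible across machines
sortC <- function(x) sort(x, method = "radix")

orderC <- function(...) order(..., method = "radix")

# stable hash of an R object via serialization; used for config provenance
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version 2 serialization is stable across the R versions we support
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# read a TSV, transparently handling gzip (fread lacks gz support without
# R.utils, so fall back to base connections there)
readTsv <- function(path) {
  if (grepl("\\.gz$", path)) {
    df <- read.delim(gzfile(path), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE)
    setDT(df)
    df
  } else {
    fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  }
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
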