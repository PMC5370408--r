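# Internal helpers shared across modules.

.DNA <- c("A", "C", "G", "T")
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run `expr` under a private RNG stream so callers' global RNG state is
# untouched and identical seeds give identical draws.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.randDna <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

.randAa <- function(n, exclude = character()) {
  paste(sample(setdiff(.AA20, exclude), n, replace = TRUE), collapse = "")
}

# Point-mutate a character vector at unconstrained positions; replacements
# are drawn uniformly from `alphabet` (so a draw may silently restore the
# original letter).
.mutateChars <- function(ch, rate, constrained = integer(), alphabet = .DNA) {
  if (rate <= 0) return(ch)
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, constrained)
  if (length(hit))
    ch[hit] <- sample(alphabet, length(hit), replace = TRUE)
  ch
}

# rbind data.frames with differing columns, filling with NA.
.rbindFill <- function(dfs) {
  dfs <- dfs[vapply(dfs, NROW, 0L) > 0L]
  if (!length(dfs)) return(data.frame())
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[, cols, drop = FALSE]
  }))
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
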